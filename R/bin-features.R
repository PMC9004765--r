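#' Assign detections to 5-minute bins
#'
#' Adds a `bin_start` column placing each detection in a half-open bin
#' `[start, start + bin_length_s)` aligned to multiples of the bin length
#' from time zero (midnight UTC when times are seconds-of-day).
#'
#' @param detections Tibble with a `time_s` column.
#' @param bin_length_s Bin length in seconds, default 300 (5 minutes).
#' @return The input tibble with a `bin_start` column prepended.
#' @examples
#' assign_bins(tibble::tibble(time_s = c(299.9, 300)))$bin_start
#' @export
assign_bins <- function(detections, bin_length_s = 300) {
  dplyr::mutate(detections,
                bin_start = floor(.data$time_s / bin_length_s) * bin_length_s,
                .before = 1)
}

#' Min-max normalize a dB spectrum
#'
#' Affine rescaling setting the minimum amplitude to zero and the maximum
#' to one. Constant spectra carry no shape information and are rejected.
#'
#' @param spectrum_db Numeric vector of dB values.
#' @return Numeric vector with min 0 and max 1; names preserved.
#' @examples
#' normalize_spectrum(c(-60, -40, -50))
#' @export
normalize_spectrum <- function(spectrum_db) {
  rng <- range(spectrum_db)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    stopf("cannot normalize a constant (or non-finite) spectrum")
  }
  (spectrum_db - rng[1]) / (rng[2] - rng[1])
}

#' Inter-click-interval distribution of a click sequence
#'
#' Histograms the successive time differences of a sorted click sequence,
#' discarding gaps longer than `max_ici_s` (0.6 s covers the modal ICIs
#' of all target types), and normalizes the histogram to sum to one.
#' Sequences with fewer than two clicks, or whose gaps all exceed the
#' truncation limit, yield an all-zero histogram.
#'
#' @param times_s Sorted numeric vector of click times in seconds.
#' @param max_ici_s Truncation limit in seconds.
#' @param bin_width_s Histogram bin width in seconds.
#' @return Numeric vector of bin probabilities (sum 1, or all zero).
#' @examples
#' h <- ici_distribution(c(0, 0.1, 0.25, 1.0))
#' sum(h)
#' @export
ici_distribution <- function(times_s, max_ici_s = ici_max_s(), bin_width_s = 0.01) {
  breaks <- seq(0, max_ici_s, by = bin_width_s)
  if (length(times_s) < 2) return(numeric(length(breaks) - 1))
  gaps <- diff(times_s)
  gaps <- gaps[gaps <= max_ici_s & gaps > 0]
  if (!length(gaps)) return(numeric(length(breaks) - 1))
  counts <- graphics::hist(gaps, breaks = breaks, plot = FALSE)$counts
  counts / sum(counts)
}

#' Fit a Gaussian to an ICI histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) of a Gaussian curve to
#' the histogram heights, initialized at the argmax bin and the empirical
#' spread, with the mode bounded to the histogram support. Returns the
#' fitted mode (the Gaussian mean) and standard deviation. Degenerate
#' histograms (< 3 nonzero bins) or failed fits fall back to the argmax
#' bin center with `fit_ok = FALSE`.
#'
#' @param ici_hist Numeric vector of bin probabilities from
#'   [ici_distribution()].
#' @param bin_centers Bin centers in seconds; defaults to the standard
#'   60-bin grid of [ici_bin_centers()].
#' @return One-row tibble: `modal_ici_s`, `ici_sd_s`, `fit_ok`.
#' @export
fit_ici_gaussian <- function(ici_hist, bin_centers = NULL) {
  if (is.null(bin_centers)) {
    bin_centers <- seq(0.005, by = 0.01, length.out = length(ici_hist))
  }
  fallback <- function() {
    mode <- if (any(ici_hist > 0)) bin_centers[which.max(ici_hist)] else NA_real_
    tibble::tibble(modal_ici_s = mode, ici_sd_s = NA_real_, fit_ok = FALSE)
  }
  if (sum(ici_hist > 0) < 3) return(fallback())
  x <- bin_centers
  y <- ici_hist
  mu0 <- x[which.max(y)]
  m <- sum(x * y) / sum(y)
  s0 <- max(0.01, sqrt(sum(y * (x - m)^2) / sum(y)))
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
    start = list(a = max(y), mu = mu0, s = s0),
    lower = c(a = 0, mu = 0, s = 1e-4),
    upper = c(a = Inf, mu = max(x) + 0.005, s = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )), silent = TRUE)
  if (inherits(fit, "try-error")) return(fallback())
  cf <- stats::coef(fit)
  tibble::tibble(modal_ici_s = unname(cf["mu"]), ici_sd_s = abs(unname(cf["s"])),
                 fit_ok = TRUE)
}

#' Locate spectral peaks and their -3 dB bandwidths
#'
#' Finds local maxima of a spectrum on the common frequency grid, ranks
#' them by amplitude, and measures each peak's -3 dB bandwidth as the
#' frequency span over which the spectrum stays within 3 dB of the peak,
#' bounded by the adjacent valleys, with linear interpolation of the
#' crossing points. A monotone spectrum yields its higher endpoint as a
#' single peak with the bandwidth flagged (`bw_flagged = TRUE`).
#'
#' @param spectrum_db Numeric vector on the grid of [click_freq_grid()]
#'   (any equally spaced grid works; supply `freq_khz` otherwise).
#' @param max_peaks Maximum number of peaks returned.
#' @param freq_khz Frequencies corresponding to `spectrum_db`.
#' @param min_prominence_db Minimum height above the deeper adjacent
#'   valley for a local maximum to count as a peak.
#' @param min_level_rel_db Peaks more than this far (dB) below the
#'   strongest peak are ignored (suppresses window sidelobes).
#' @return Tibble ordered by descending amplitude: `peak_khz`, `bw_khz`,
#'   `level_db`, `bw_flagged`.
#' @examples
#' tpl <- hawaii_click_templates("Cuvier's beaked whale")[[1]]
#' s <- click_spectrum(synth_click_waveform(tpl, seed = 3), 200000)
#' spectral_peaks(s)
#' @export
spectral_peaks <- function(spectrum_db, max_peaks = 3, freq_khz = NULL,
                           min_prominence_db = 3, min_level_rel_db = -20) {
  y <- as.numeric(spectrum_db)
  n <- length(y)
  if (is.null(freq_khz)) {
    freq_khz <- if (!is.null(names(spectrum_db))) {
      as.numeric(names(spectrum_db))
    } else {
      click_freq_grid()[seq_len(n)]
    }
  }
  # local maxima (plateau-tolerant)
  is_max <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    y[i] > l && y[i] >= r
  }, logical(1))
  cand <- which(is_max)
  monotone <- length(cand) == 1 && cand %in% c(1L, n)
  if (!length(cand)) {
    cand <- which.max(y)
    monotone <- TRUE
  }
  rows <- purrr::map(cand, function(i) {
    # adjacent valleys
    lo <- i
    while (lo > 1 && y[lo - 1] <= y[lo]) lo <- lo - 1
    hi <- i
    while (hi < n && y[hi + 1] <= y[hi]) hi <- hi + 1
    prom <- y[i] - max(min(y[lo:i]), min(y[i:hi]))
    thr <- y[i] - 3
    flagged <- FALSE
    # left -3 dB crossing, interpolated
    l <- i
    while (l > lo && y[l - 1] >= thr) l <- l - 1
    f_lo <- if (l > lo && y[l - 1] < thr) {
      freq_khz[l - 1] + (thr - y[l - 1]) / (y[l] - y[l - 1]) * (freq_khz[l] - freq_khz[l - 1])
    } else {
      flagged <- TRUE
      freq_khz[lo]
    }
    r <- i
    while (r < hi && y[r + 1] >= thr) r <- r + 1
    f_hi <- if (r < hi && y[r + 1] < thr) {
      freq_khz[r] + (y[r] - thr) / (y[r] - y[r + 1]) * (freq_khz[r + 1] - freq_khz[r])
    } else {
      flagged <- TRUE
      freq_khz[hi]
    }
    tibble::tibble(peak_khz = freq_khz[i], bw_khz = max(f_hi - f_lo, diff(freq_khz)[1]),
                   level_db = y[i], prominence_db = prom,
                   bw_flagged = flagged || monotone)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(out, (.data$prominence_db >= min_prominence_db &
                               .data$level_db >= max(.data$level_db) + min_level_rel_db) |
                         dplyr::row_number() == which.max(out$level_db))
  out <- dplyr::arrange(out, dplyr::desc(.data$level_db))
  dplyr::select(utils::head(out, max_peaks), -"prominence_db")
}

#' Summarize the descriptors of one click type
#'
#' Builds the descriptor row used in type tables: per-click spectral
#' peaks are pooled across clicks, grouped into the type's peak set by
#' one-dimensional k-means on frequency (k chosen as the modal per-click
#' peak count), and each group is summarized by its median and 10th/90th
#' percentiles of peak frequency plus the median -3 dB bandwidth.
#' Separately, a Gaussian is fitted to the pooled ICI distribution to
#' give the modal ICI and its spread.
#'
#' @param clicks Tibble with a `spectrum` list-column (normalized or dB
#'   spectra on the common grid) and optionally `time_s` for the ICI fit.
#' @param times_s Optional explicit click times (seconds) for the ICI
#'   distribution; overrides `clicks$time_s`.
#' @param max_peaks Maximum peaks per click considered.
#' @return List with `peaks` (tibble: `peak_khz_median`, `peak_khz_p10`,
#'   `peak_khz_p90`, `bw_khz_median`, ordered by frequency) and `ici`
#'   (tibble from [fit_ici_gaussian()], `NULL` when no times given).
#' @export
summarize_type <- function(clicks, times_s = NULL, max_peaks = 3) {
  if (nrow(clicks) < 100) {
    warnf("summarize_type: only %d clicks; descriptors may be unstable", nrow(clicks))
  }
  per_click <- purrr::map(clicks$spectrum, spectral_peaks, max_peaks = max_peaks)
  k <- as.integer(stats::median(vapply(per_click, nrow, 1L)))
  pooled <- dplyr::bind_rows(per_click)
  if (k <= 1 || nrow(pooled) < 2 * k) {
    grp <- rep(1L, nrow(pooled))
    k <- 1L
  } else {
    centers <- stats::quantile(pooled$peak_khz, probs = (seq_len(k) - 0.5) / k)
    km <- stats::kmeans(pooled$peak_khz, centers = matrix(unique(centers)), iter.max = 50)
    grp <- km$cluster
  }
  peaks <- pooled |>
    dplyr::mutate(group = grp) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      peak_khz_median = stats::median(.data$peak_khz),
      peak_khz_p10 = unname(stats::quantile(.data$peak_khz, 0.1)),
      peak_khz_p90 = unname(stats::quantile(.data$peak_khz, 0.9)),
      bw_khz_median = stats::median(.data$bw_khz),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$peak_khz_median) |>
    dplyr::select(-"group")
  ici <- NULL
  if (is.null(times_s) && "time_s" %in% names(clicks)) times_s <- clicks$time_s
  if (!is.null(times_s) && length(times_s) >= 2) {
    ici <- fit_ici_gaussian(ici_distribution(sort(times_s)))
  }
  list(peaks = peaks, ici = ici)
}
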