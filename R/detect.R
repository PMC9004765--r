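#' Detector parameters
#'
#' Defaults follow the standard configuration for odontocete click
#' detection in high-frequency hydrophone data: a 10 kHz high-pass to
#' exclude low-frequency noise, a 100 kHz low-pass regardless of sampling
#' rate, a 115 dBpp re 1 uPa peak-to-peak amplitude floor, retention of
#' impulses 30--1200 us long, and merging of detections separated by less
#' than 100 us. Spectra use a 2 ms FFT (400 points at fs 200 kHz, 640 at
#' 320 kHz), giving 0.5 kHz resolution at both rates.
#'
#' @param highpass_hz,lowpass_hz Analysis band edges in Hz.
#' @param rl_threshold_dbpp Minimum peak-to-peak received level, dB re 1 uPa.
#' @param min_dur_us,max_dur_us Retained duration band in microseconds.
#' @param merge_gap_us Detections closer than this are merged.
#' @param energy_threshold_db Band-energy trigger above the running median
#'   noise floor, in dB.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(highpass_hz = 10000, lowpass_hz = 100000,
                            rl_threshold_dbpp = 115,
                            min_dur_us = 30, max_dur_us = 1200,
                            merge_gap_us = 100, energy_threshold_db = 6) {
  stopifnot(min_dur_us < max_dur_us, highpass_hz < lowpass_hz)
  structure(
    list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
         rl_threshold_dbpp = rl_threshold_dbpp,
         min_dur_us = min_dur_us, max_dur_us = max_dur_us,
         merge_gap_us = merge_gap_us, energy_threshold_db = energy_threshold_db),
    class = "detector_params"
  )
}

#' Band-pass filter a waveform
#'
#' Zero-phase FIR band-pass (256-tap Hamming-windowed design applied
#' forward and backward), used to restrict analysis to the 10--100 kHz
#' click band. When the upper edge equals the Nyquist frequency the
#' low-pass stage is a no-op and only the high-pass is applied.
#'
#' @param waveform Numeric vector.
#' @param fs_hz Sampling rate in Hz.
#' @param lo_hz,hi_hz Band edges in Hz; `hi_hz` may not exceed Nyquist.
#' @return Filtered waveform, same length.
#' @export
bandpass <- function(waveform, fs_hz, lo_hz = 10000, hi_hz = 100000) {
  nyq <- fs_hz / 2
  if (lo_hz >= hi_hz) stopf("lo_hz must be < hi_hz")
  if (hi_hz > nyq) stopf("hi_hz (%g) exceeds Nyquist (%g)", hi_hz, nyq)
  b <- if (hi_hz == nyq) {
    as.numeric(signal::fir1(256, lo_hz / nyq, type = "high"))
  } else {
    as.numeric(signal::fir1(256, c(lo_hz, hi_hz) / nyq, type = "pass"))
  }
  # apply the linear-phase FIR in the frequency domain and undo its group
  # delay (128 samples), giving a zero-phase result in O(n log n)
  n <- length(waveform)
  nb <- length(b)
  nfft <- stats::nextn(n + nb, c(2, 3, 5))
  x <- c(waveform, numeric(nfft - n))
  B <- stats::fft(c(b, numeric(nfft - nb)))
  y <- Re(stats::fft(stats::fft(x) * B, inverse = TRUE)) / nfft
  y[(nb - 1) / 2 + seq_len(n)]
}

#' Click spectrum on the common frequency grid
#'
#' Hann-windowed FFT of a snippet centered on the click peak: 400 points
#' at fs 200 kHz or 640 points at 320 kHz (2 ms either way, hence 0.5 kHz
#' bin spacing for both rates), magnitude in dB, cropped to the common
#' 10--100 kHz grid of [click_freq_grid()]. Snippets shorter than the FFT
#' length are zero-padded.
#'
#' @param snippet Numeric waveform containing the click peak.
#' @param fs_hz Sampling rate, 200000 or 320000 Hz.
#' @return Numeric vector of 181 dB values named by frequency in kHz.
#' @export
click_spectrum <- function(snippet, fs_hz) {
  check_fs(fs_hz)
  nfft <- as.integer(fs_hz * 0.002)
  # place the click's peak-amplitude sample at the window center
  x <- numeric(nfft)
  pk <- which.max(abs(snippet))
  dst <- (nfft %/% 2 + 1) - pk
  src <- seq_along(snippet)
  ok <- src + dst >= 1 & src + dst <= nfft
  x[src[ok] + dst] <- snippet[src[ok]]
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  mag <- Mod(stats::fft(x * w))
  f_khz <- (0:(nfft - 1)) * fs_hz / nfft / 1000
  keep <- which(f_khz >= 10 & f_khz <= 100)
  out <- 20 * log10(mag[keep] + 1e-12)
  names(out) <- format(f_khz[keep], trim = TRUE)
  out
}

#' Detect echolocation clicks in a waveform
#'
#' Two-stage energy detector: the waveform is band-passed to the analysis
#' band, band energy (1 ms smoothed squared envelope) is compared against
#' a running-median noise floor, and triggered periods are searched for
#' impulses. Each impulse's duration is the span where the analytic
#' envelope stays above -10 dB of its peak; detections closer than the
#' merge gap are merged (keeping the earliest onset and largest
#' peak-to-peak amplitude); detections outside the duration band or below
#' the received-level floor are discarded.
#'
#' @param waveform Numeric vector (counts).
#' @param fs_hz Sampling rate, 200000 or 320000 Hz.
#' @param params A [detector_params].
#' @param calibration_db Flat counts-to-uPa calibration in dB, so that
#'   `rl_dbpp = 20*log10(p2p counts) + calibration_db`.
#' @return Tibble with one row per detection, sorted by time: `time_s`
#'   (onset), `peak_time_s`, `rl_dbpp`, `duration_us`, and list-columns
#'   `spectrum` (181 dB values on the common grid) and `envelope`
#'   (100-point max-normalized analytic envelope over 1.5 ms).
#' @examples
#' tpl <- hawaii_click_templates("Blainville's beaked whale")[[1]]
#' sc <- scene_config(duration_s = 4,
#'   trains = list(list(template = tpl, start_s = 0.4, n_clicks = 6,
#'                      rl_dbpp = c(132, 136))), seed = 2)
#' out <- render_scene(sc)
#' det <- detect_clicks(out$waveform, out$fs_hz, calibration_db = out$calibration_db)
#' nrow(det)
#' @export
detect_clicks <- function(waveform, fs_hz, params = detector_params(),
                          calibration_db = 120) {
  check_fs(fs_hz)
  if (length(waveform) == 0 || anyNA(waveform)) {
    stopf("waveform must be non-empty and free of NA")
  }
  bp <- bandpass(waveform, fs_hz, params$highpass_hz,
                 min(params$lowpass_hz, fs_hz / 2))
  env <- Mod(analytic_signal(bp))
  k1ms <- as.integer(fs_hz * 0.001)
  energy <- moving_average(env^2, k1ms)

  # running median noise floor on a 0.5 ms decimated energy series
  dec <- as.integer(fs_hz * 5e-4)
  e_dec <- energy[seq(1, length(energy), by = dec)]
  kmed <- min(length(e_dec) - (1 - length(e_dec) %% 2), 2001L)
  if (kmed %% 2 == 0) kmed <- kmed - 1L
  floor_dec <- if (kmed >= 3) stats::runmed(e_dec, kmed) else e_dec
  noise_floor <- rep(floor_dec, each = dec, length.out = length(energy))

  mask <- energy > noise_floor * 10^(params$energy_threshold_db / 10)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  if (!nrow(regions)) return(empty_detections())

  # search each triggered period for impulses: iteratively take the
  # strongest unclaimed envelope peak, delimit it at -10 dB of its own
  # peak, and repeat while unclaimed samples still exceed the trigger
  margin <- as.integer(fs_hz * 0.0015)
  events <- purrr::map(seq_len(nrow(regions)), function(i) {
    i0 <- max(1L, regions[i, 1] - margin)
    i1 <- min(length(env), regions[i, 2] + margin)
    idx <- i0:i1
    seg_env <- env[idx]
    trigger <- sqrt(noise_floor[idx] * 10^(params$energy_threshold_db / 10))
    # candidate peaks must lie inside the triggered period itself
    open <- logical(length(idx))
    open[(regions[i, 1]:regions[i, 2]) - i0 + 1L] <- TRUE
    found <- list()
    for (rep_i in seq_len(500)) {
      if (!any(open)) break
      pk <- which.max(ifelse(open, seg_env, -Inf))
      if (seg_env[pk] <= trigger[pk]) break
      thr <- seg_env[pk] * 10^(-10 / 20)
      ceiling_env <- seg_env[pk] * 10^(1 / 20)
      # expand to the -10 dB points of this peak, stopping if the
      # envelope climbs >1 dB above the peak (a neighbouring impulse)
      lo <- pk
      while (lo > 1L && seg_env[lo - 1L] > thr &&
             seg_env[lo - 1L] <= ceiling_env) lo <- lo - 1L
      hi <- pk
      while (hi < length(seg_env) && seg_env[hi + 1L] > thr &&
             seg_env[hi + 1L] <= ceiling_env) hi <- hi + 1L
      found[[length(found) + 1]] <-
        c(lo = i0 - 1L + lo, hi = i0 - 1L + hi, pk = i0 - 1L + pk)
      # claim the rest of this impulse's decaying flanks so they cannot
      # respawn as fragment events
      clo <- lo
      while (clo > 1L && seg_env[clo - 1L] <= seg_env[clo] * 1.02) clo <- clo - 1L
      chi <- hi
      while (chi < length(seg_env) && seg_env[chi + 1L] <= seg_env[chi] * 1.02) {
        chi <- chi + 1L
      }
      open[clo:chi] <- FALSE
    }
    found
  })
  ev <- do.call(rbind, purrr::flatten(events))
  if (is.null(ev) || !nrow(ev)) return(empty_detections())
  ev <- ev[order(ev[, "lo"]), , drop = FALSE]

  # impulse criteria (duration band, received-level floor) are applied to
  # candidate events first, so low-level band-edge tails around strong
  # clicks cannot chain onto real detections in the merge step
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    dur_us <- (ev[i, "hi"] - ev[i, "lo"] + 1) / fs_hz * 1e6
    if (dur_us < params$min_dur_us || dur_us > params$max_dur_us) return(FALSE)
    seg <- bp[ev[i, "lo"]:ev[i, "hi"]]
    rl <- 20 * log10(max(seg) - min(seg)) + calibration_db
    rl >= params$rl_threshold_dbpp
  }, TRUE)
  ev <- ev[keep, , drop = FALSE]
  if (!nrow(ev)) return(empty_detections())

  # merge retained detections separated by less than merge_gap_us; keep
  # the earliest onset, the larger-envelope peak, and the union span as
  # the recomputed duration
  gap_n <- params$merge_gap_us * 1e-6 * fs_hz
  merged <- list()
  cur <- ev[1, ]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      nxt <- ev[i, ]
      if (nxt["lo"] - cur["hi"] < gap_n) {
        cur["hi"] <- max(cur["hi"], nxt["hi"])
        if (env[nxt["pk"]] > env[cur["pk"]]) cur["pk"] <- nxt["pk"]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- nxt
      }
    }
  }
  merged[[length(merged) + 1]] <- cur
  mg <- do.call(rbind, merged)

  half_snip <- as.integer(fs_hz * 0.001)
  half_env <- as.integer(fs_hz * 0.00075)
  rows <- purrr::map(seq_len(nrow(mg)), function(i) {
    lo <- unname(mg[i, "lo"]); hi <- unname(mg[i, "hi"]); pk <- unname(mg[i, "pk"])
    dur_us <- (hi - lo + 1) / fs_hz * 1e6
    if (dur_us < params$min_dur_us || dur_us > params$max_dur_us) return(NULL)
    seg <- bp[lo:hi]
    rl <- 20 * log10(max(seg) - min(seg)) + calibration_db
    if (rl < params$rl_threshold_dbpp) return(NULL)
    s0 <- max(1L, pk - half_snip)
    s1 <- min(length(bp), pk + half_snip - 1L)
    spec <- click_spectrum(bp[s0:s1], fs_hz)
    e0 <- max(1L, pk - half_env)
    e1 <- min(length(env), pk + half_env - 1L)
    envlp <- resample_vector(env[e0:e1], n_envelope_points())
    envlp <- envlp / max(envlp)
    tibble::tibble(
      time_s = (lo - 1) / fs_hz, peak_time_s = (pk - 1) / fs_hz,
      rl_dbpp = rl, duration_us = dur_us,
      spectrum = list(spec), envelope = list(envlp)
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (!nrow(out)) return(empty_detections())
  dplyr::arrange(out, .data$time_s)
}

empty_detections <- function() {
  tibble::tibble(time_s = numeric(), peak_time_s = numeric(),
                 rl_dbpp = numeric(), duration_us = numeric(),
                 spectrum = list(), envelope = list())
}

#' Write / read a detections table as CSV
#'
#' Widens the `spectrum` and `envelope` list-columns into `spec_*` /
#' `env_*` columns so detection tables round-trip through plain CSV.
#'
#' @param detections Tibble from [detect_clicks()].
#' @param path File path.
#' @return `read_detections()` returns the detections tibble.
#' @export
write_detections <- function(detections, path) {
  spec <- do.call(rbind, detections$spectrum)
  env <- do.call(rbind, detections$envelope)
  flat <- dplyr::select(detections, -"spectrum", -"envelope")
  if (!is.null(spec)) {
    colnames(spec) <- paste0("spec_", seq_len(ncol(spec)))
    colnames(env) <- paste0("env_", seq_len(ncol(env)))
    flat <- dplyr::bind_cols(flat, tibble::as_tibble(spec), tibble::as_tibble(env))
  }
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  flat <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  spec_cols <- grep("^spec_", names(flat))
  env_cols <- grep("^env_", names(flat))
  out <- flat[setdiff(seq_along(flat), c(spec_cols, env_cols))]
  if (length(spec_cols)) {
    smat <- as.matrix(flat[spec_cols])
    emat <- as.matrix(flat[env_cols])
    grid_names <- format(click_freq_grid(), trim = TRUE)
    out$spectrum <- purrr::map(seq_len(nrow(smat)), function(i) {
      v <- as.numeric(smat[i, ]); names(v) <- grid_names; v
    })
    out$envelope <- purrr::map(seq_len(nrow(emat)), function(i) as.numeric(emat[i, ]))
  }
  out
}
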