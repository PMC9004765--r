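#' Synthesize one echolocation click waveform
#'
#' Generates a transient as a sum of Gaussian-envelope tone pulses, one
#' per spectral peak of the template. A Gaussian envelope of standard
#' deviation `sqrt(ln 2) / (pi * bw)` gives the component a Gaussian
#' amplitude spectrum whose -3 dB width equals the requested bandwidth,
#' with tails that decay fast enough to keep the click inside the
#' 10--100 kHz analysis band (an exponentially damped pulse would carry
#' heavy Lorentzian tails across the band edges). Component amplitudes
#' are scaled so spectral peak heights follow the template's relative
#' amplitudes, and the sum is tapered with a Tukey window to the
#' requested duration. Each call draws a random phase per component and
#' a small (sd 0.25 kHz, clipped at +/-0.6 kHz) center-frequency jitter
#' so that repeated clicks of one type vary realistically while keeping
#' the realized spectral peak within 1 kHz of the template value.
#'
#' @param template A [click_template].
#' @param duration_us Click duration in microseconds, within 30--1200
#'   (the duration band retained by the detector). Defaults to the
#'   template's typical duration.
#' @param fs_hz Sampling rate in Hz, 200000 or 320000.
#' @param seed Integer seed; equal seeds give identical waveforms.
#' @return Numeric waveform of `round(duration_us * 1e-6 * fs_hz)` samples,
#'   normalized to unit peak amplitude.
#' @examples
#' tpl <- hawaii_click_templates("Kogia spp.")[[1]]
#' w <- synth_click_waveform(tpl, seed = 1)
#' length(w)
#' @export
synth_click_waveform <- function(template, duration_us = template$duration_us,
                                 fs_hz = 200000, seed = 1) {
  if (!inherits(template, "click_template")) stopf("`template` must be a click_template")
  if (duration_us < 30 || duration_us > 1200) {
    stopf("duration_us must be within [30, 1200] microseconds, got %g", duration_us)
  }
  check_fs(fs_hz)
  n <- max(2L, as.integer(round(duration_us * 1e-6 * fs_hz)))
  with_seed(seed, {
    t <- (0:(n - 1)) / fs_hz
    tc <- 0.4 * duration_us * 1e-6  # envelope peak sits early in the click
    taper <- tukey_window(n, 0.25)
    # components are assembled in the frequency domain on a long grid and
    # only bins up to Nyquist are populated, so the sampled click is
    # band-limited by construction and near-Nyquist peaks (93.5 kHz at
    # fs 200 kHz) suffer no spectral fold-back
    nfft <- stats::nextn(max(8L * n, 2048L), 2)
    fk <- (0:(nfft %/% 2)) * fs_hz / nfft
    # spectrum convention: Hann window (2 ms) centered on the click peak;
    # weight each component by the inverse of its effective windowed gain
    # so realized spectral peak heights follow the template amplitudes
    spec_win <- pmax(0, cos(pi / 2 * pmin(abs(t - tc) / 0.001, 1)))^2
    X <- complex(real = numeric(length(fk)), imaginary = numeric(length(fk)))
    for (i in seq_len(nrow(template$peaks))) {
      bw_hz <- template$peaks$bw_khz[i] * 1000
      jitter <- max(-0.6, min(0.6, stats::rnorm(1, 0, 0.25)))
      f0_hz <- (template$peaks$freq_khz[i] + jitter) * 1000
      sigma_t <- sqrt(log(2)) / (pi * bw_hz)
      phase <- stats::runif(1, 0, 2 * pi)
      envelope <- exp(-(t - tc)^2 / (2 * sigma_t^2))
      # fraction of the component the taper and measurement window retain
      gain <- sum(envelope * taper * spec_win) / sum(envelope)
      # amplitude spectrum whose half-power width is bw
      mag <- exp(-(log(2) / 2) * ((fk - f0_hz) / (bw_hz / 2))^2)
      X <- X + (template$peaks$amp[i] / gain) * mag * exp(1i * phase)
    }
    # linear phase places the envelope peak at sample round(tc * fs)
    shift <- round(tc * fs_hz)
    X <- X * exp(-2i * pi * fk * shift / fs_hz)
    full <- c(X, Conj(X[(nfft %/% 2):2]))
    x <- Re(stats::fft(full, inverse = TRUE)) / nfft
    x <- x[seq_len(n)] * taper
    x / max(abs(x))
  })
}

#' Simulate a click train's onset times
#'
#' Successive inter-click gaps are drawn from a Gaussian centered on the
#' template's modal ICI (or from a two-Gaussian mixture for bimodal types
#' such as the false killer whale), truncated below at 5 ms by rejection.
#'
#' @param template A [click_template].
#' @param n_clicks Number of clicks, at least 2.
#' @param seed Integer seed.
#' @param start_s Time of the first click in seconds.
#' @return Strictly increasing numeric vector of `n_clicks` onset times (s).
#' @examples
#' tpl <- hawaii_click_templates("Cuvier's beaked whale")[[1]]
#' diff(synth_click_train(tpl, 5, seed = 1))
#' @export
synth_click_train <- function(template, n_clicks, seed = 1, start_s = 0) {
  if (!inherits(template, "click_template")) stopf("`template` must be a click_template")
  if (n_clicks < 2) stopf("n_clicks must be >= 2, got %s", n_clicks)
  n_gaps <- n_clicks - 1
  gaps <- with_seed(seed, {
    draw <- function(m) {
      if (!is.na(template$ici_mode2_s)) {
        from2 <- stats::runif(m) < template$ici_weight2
        ifelse(from2,
               stats::rnorm(m, template$ici_mode2_s, template$ici_sd2_s),
               stats::rnorm(m, template$modal_ici_s, template$ici_sd_s))
      } else {
        stats::rnorm(m, template$modal_ici_s, template$ici_sd_s)
      }
    }
    g <- draw(n_gaps)
    while (any(bad <- g <= 0.005)) g[bad] <- draw(sum(bad))
    g
  })
  start_s + cumsum(c(0, gaps))
}

check_fs <- function(fs_hz) {
  if (!fs_hz %in% c(200000, 320000)) {
    stopf("fs_hz must be 200000 or 320000, got %s", fs_hz)
  }
  invisible(fs_hz)
}
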