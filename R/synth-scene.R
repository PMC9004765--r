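#' Configure a synthetic acoustic scene
#'
#' A scene is a single-channel pressure time series containing zero or
#' more echolocation click trains plus interfering noise: Gaussian
#' background, optional band-limited low-frequency "ship" energy, and
#' optional periodic narrowband echosounder pings. Received levels are
#' peak-to-peak, `rl_dBpp = 20 * log10(p2p counts) + calibration_db`,
#' with a single flat calibration constant.
#'
#' @param fs_hz Sampling rate, 200000 or 320000 Hz.
#' @param duration_s Scene length in seconds.
#' @param trains List of train specs, each a list with elements
#'   `template` ([click_template]), `start_s`, `n_clicks`, and `rl_dbpp`
#'   (length-2 range within \[100, 160\] from which each click's level is
#'   drawn uniformly).
#' @param background_rms RMS of the Gaussian background, in counts.
#' @param ship_level Peak count amplitude of low-frequency (< 8 kHz)
#'   ship-like band noise; 0 disables it.
#' @param echosounder `NULL`, or a list with `interval_s`, `freq_khz` and
#'   optionally `level` (count amplitude) describing periodic 2 ms pings.
#' @param calibration_db Flat counts-to-micropascal conversion in dB.
#' @param seed Integer seed (mandatory; scenes are fully reproducible).
#' @return A `scene_config` object.
#' @export
scene_config <- function(fs_hz = 200000, duration_s = 10, trains = list(),
                         background_rms = 0.001, ship_level = 0,
                         echosounder = NULL, calibration_db = 120, seed) {
  check_fs(fs_hz)
  if (missing(seed)) stopf("scene_config() requires an explicit seed")
  if (duration_s <= 0) stopf("duration_s must be > 0")
  for (tr in trains) {
    stopifnot(inherits(tr$template, "click_template"))
    if (length(tr$rl_dbpp) != 2 || any(tr$rl_dbpp < 100) || any(tr$rl_dbpp > 160)) {
      stopf("train rl_dbpp must be a range within [100, 160] dBpp")
    }
  }
  structure(
    list(fs_hz = fs_hz, duration_s = duration_s, trains = trains,
         background_rms = background_rms, ship_level = ship_level,
         echosounder = echosounder, calibration_db = calibration_db,
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' Render a synthetic scene to audio plus ground truth
#'
#' Produces the scene waveform (in counts) and a tibble listing every
#' injected click. Each click is scaled so its peak-to-peak amplitude
#' equals its drawn received level under the scene calibration. Clicks
#' from different trains may overlap in time (multiple animals).
#'
#' @param config A [scene_config].
#' @return List with `waveform` (numeric), `fs_hz`, `calibration_db`, and
#'   `truth`: a tibble with columns `time_s` (click onset), `type`,
#'   `rl_dbpp`, `duration_us`.
#' @examples
#' tpl <- hawaii_click_templates("Cuvier's beaked whale")[[1]]
#' sc <- scene_config(duration_s = 5,
#'   trains = list(list(template = tpl, start_s = 0.5, n_clicks = 8,
#'                      rl_dbpp = c(130, 135))), seed = 7)
#' out <- render_scene(sc)
#' nrow(out$truth)
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  fs <- config$fs_hz
  n <- as.integer(round(config$duration_s * fs))
  truth <- list()
  x <- with_seed(derive_seed(config$seed, 1), {
    stats::rnorm(n, 0, config$background_rms)
  })
  if (config$ship_level > 0) {
    x <- x + with_seed(derive_seed(config$seed, 2), {
      raw <- stats::rnorm(n)
      b <- signal::fir1(128, 8000 / (fs / 2), type = "low")
      lf <- signal::fftfilt(b, raw)
      config$ship_level * lf / max(abs(lf))
    })
  }
  if (!is.null(config$echosounder)) {
    es <- config$echosounder
    lvl <- if (is.null(es$level)) 0.5 else es$level
    ping_n <- as.integer(round(0.002 * fs))
    ping <- lvl * sin(2 * pi * es$freq_khz * 1000 * (0:(ping_n - 1)) / fs) *
      tukey_window(ping_n, 0.5)
    starts <- seq(0.1, config$duration_s - 0.003, by = es$interval_s)
    for (s in starts) {
      i0 <- as.integer(round(s * fs)) + 1L
      x[i0:(i0 + ping_n - 1L)] <- x[i0:(i0 + ping_n - 1L)] + ping
    }
  }
  for (k in seq_along(config$trains)) {
    tr <- config$trains[[k]]
    tseed <- derive_seed(config$seed, 10 + k)
    onsets <- synth_click_train(tr$template, tr$n_clicks, seed = tseed,
                                start_s = tr$start_s)
    onsets <- onsets[onsets * fs + 2 * tr$template$duration_us * 1e-6 * fs < n - 1]
    per_click <- with_seed(derive_seed(tseed, 1), {
      tibble::tibble(
        rl = stats::runif(length(onsets), tr$rl_dbpp[1], tr$rl_dbpp[2]),
        dur = round(tr$template$duration_us * stats::runif(length(onsets), 0.9, 1.1)),
        wseed = sample.int(1e6, length(onsets))
      )
    })
    per_click$dur <- pmax(30, pmin(1200, per_click$dur))
    for (i in seq_along(onsets)) {
      w <- synth_click_waveform(tr$template, per_click$dur[i], fs,
                                seed = per_click$wseed[i])
      p2p_target <- 10^((per_click$rl[i] - config$calibration_db) / 20)
      w <- w * p2p_target / (max(w) - min(w))
      i0 <- as.integer(round(onsets[i] * fs)) + 1L
      idx <- i0:(i0 + length(w) - 1L)
      x[idx] <- x[idx] + w
    }
    truth[[k]] <- tibble::tibble(
      time_s = onsets, type = tr$template$name,
      rl_dbpp = per_click$rl, duration_us = per_click$dur
    )
  }
  truth <- if (length(truth)) {
    dplyr::arrange(dplyr::bind_rows(truth), .data$time_s)
  } else {
    tibble::tibble(time_s = numeric(), type = character(),
                   rl_dbpp = numeric(), duration_us = numeric())
  }
  list(waveform = x, fs_hz = fs, calibration_db = config$calibration_db,
       truth = truth)
}
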