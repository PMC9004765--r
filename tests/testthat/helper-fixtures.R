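# Shared fixtures built in code. Scene rendering is the slow step, so the
# one scene several detection tests share is cached per session.

single_peak_template <- function(freq_khz = 40, bw_khz = 5, ici = 0.2, sd = 0.05) {
  click_template("test type",
                 data.frame(freq_khz = freq_khz, bw_khz = bw_khz, amp = 1),
                 modal_ici_s = ici, ici_sd_s = sd)
}

# detections table built straight from synthetic click waveforms (no scene
# audio), for clustering tests: n clicks of each template, times interleaved
# within one 5-minute bin; each click carries a realistic ~25 dB SNR floor
make_detections <- function(templates, n_each, seed = 1, rl_dbpp = 135,
                            t0 = 0, fs_hz = 200000, snr_db = 25) {
  rows <- purrr::imap(templates, function(tpl, i) {
    idx <- which(vapply(templates, `[[`, "", "name") == tpl$name)
    times <- synth_click_train(tpl, n_each, seed = seed + 100 * idx,
                               start_s = t0 + 0.05 * idx)
    purrr::map(seq_len(n_each), function(j) {
      w <- synth_click_waveform(tpl, fs_hz = fs_hz,
                                seed = seed + 1000 * idx + j)
      w <- w + withr::with_seed(seed + 5000 * idx + j,
                                rnorm(length(w), 0, 10^(-snr_db / 20)))
      env <- Mod(echoclick:::analytic_signal(w))
      env <- echoclick:::resample_vector(env, 100)
      tibble::tibble(
        time_s = times[j], peak_time_s = times[j],
        rl_dbpp = rl_dbpp, duration_us = tpl$duration_us,
        spectrum = list(click_spectrum(w, fs_hz)),
        envelope = list(env / max(env)),
        type = tpl$name
      )
    }) |>
      dplyr::bind_rows()
  })
  dplyr::arrange(dplyr::bind_rows(rows), time_s)
}

# one cached high-SNR two-type scene reused by the detection tests
shared_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tpls <- hawaii_click_templates(c("Kogia spp.", "Cuvier's beaked whale"))
      sc <- scene_config(
        duration_s = 12,
        trains = list(
          list(template = tpls[[1]], start_s = 0.5, n_clicks = 60,
               rl_dbpp = c(130, 136)),
          list(template = tpls[[2]], start_s = 1.0, n_clicks = 20,
               rl_dbpp = c(130, 136))
        ),
        background_rms = 0.001, seed = 42
      )
      out <- render_scene(sc)
      out$detections <- detect_clicks(out$waveform, out$fs_hz,
                                      calibration_db = out$calibration_db)
      cache <<- out
    }
    cache
  }
})

# place a scaled waveform at given onset times in a quiet track
toy_track <- function(bursts, duration_s = 1, fs_hz = 200000,
                      background_rms = 1e-5, seed = 7) {
  n <- as.integer(duration_s * fs_hz)
  x <- withr::with_seed(seed, rnorm(n, 0, background_rms))
  for (b in bursts) {
    i0 <- as.integer(round(b$time_s * fs_hz)) + 1L
    w <- b$waveform
    x[i0:(i0 + length(w) - 1L)] <- x[i0:(i0 + length(w) - 1L)] + w
  }
  x
}

# constant-envelope tone burst whose -10 dB envelope span tracks its
# nominal duration; p2p in counts
tone_burst <- function(duration_us, freq_khz = 40, p2p = 1, fs_hz = 200000) {
  n <- max(2L, as.integer(round(duration_us * 1e-6 * fs_hz)))
  t <- (0:(n - 1)) / fs_hz
  (p2p / 2) * sin(2 * pi * freq_khz * 1000 * t + pi / 4) *
    echoclick:::tukey_window(n, 0.2)
}

rl_to_p2p <- function(rl_dbpp, calibration_db = 120) 10^((rl_dbpp - calibration_db) / 20)
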