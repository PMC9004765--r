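test_that("bandpass keeps the click band and rejects out-of-band tones", {
  fs <- 200000
  t <- (0:199999) / fs
  tone5 <- sin(2 * pi * 5000 * t)
  tone50 <- sin(2 * pi * 50000 * t)
  expect_lt(sd(bandpass(tone5, fs)) / sd(tone5), 0.01)
  expect_gt(sd(bandpass(tone50, fs)) / sd(tone50), 0.9)
  expect_lt(sd(bandpass(tone50, fs)) / sd(tone50), 1.1)
  expect_error(bandpass(tone5, fs, 10000, 110000), "Nyquist")
  expect_error(bandpass(tone5, fs, 50000, 20000), "lo_hz")
})

test_that("bandpass energy split matches a periodogram oracle on white noise", {
  fs <- 320000
  x <- withr::with_seed(3, rnorm(2^17))
  y <- bandpass(x, fs, 10000, 100000)
  # oracle: periodogram mass of the input inside the passband
  P <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  half <- f <= fs / 2
  frac_in <- sum(P[half & f >= 10000 & f <= 100000]) / sum(P[half])
  expect_equal(sum(y^2) / sum(x^2), frac_in, tolerance = 0.1)
})

test_that("click spectra use 0.5 kHz bins on the common grid at both rates", {
  tpl <- single_peak_template(93.5, 10)
  for (fs in c(200000, 320000)) {
    w <- synth_click_waveform(tpl, duration_us = 200, fs_hz = fs, seed = 2)
    sp <- click_spectrum(w, fs)
    expect_length(sp, 181)
    freqs <- as.numeric(names(sp))
    expect_equal(unique(round(diff(freqs), 6)), 0.5)
    expect_equal(freqs[1], 10)
    expect_equal(freqs[181], 100)
    expect_lt(abs(freqs[which.max(sp)] - 93.5), 1.1)
  }
  expect_error(click_spectrum(rnorm(100), 96000), "fs_hz")
})

test_that("spectra of one template agree across sampling rates", {
  tpl <- hawaii_click_templates("Stenellid 2")[[1]]
  mean_norm_spec <- function(fs) {
    sp <- vapply(1:40, function(s) {
      normalize_spectrum(click_spectrum(synth_click_waveform(tpl, fs_hz = fs,
                                                             seed = s), fs))
    }, numeric(181))
    rowMeans(sp)
  }
  s200 <- mean_norm_spec(200000)
  s320 <- mean_norm_spec(320000)
  # bin-wise agreement after normalization, on a 60 dB display range
  expect_lt(max(abs(s200 - s320)) * 60, 3)
})

test_that("duration band, amplitude floor and merge rule are enforced", {
  fs <- 200000
  p2p130 <- rl_to_p2p(130)
  # three sustained bursts: too short, in-band, too long
  x <- toy_track(list(
    list(time_s = 0.10, waveform = tone_burst(15, p2p = p2p130)),
    list(time_s = 0.30, waveform = tone_burst(100, p2p = p2p130)),
    list(time_s = 0.50, waveform = tone_burst(1500, p2p = p2p130))
  ), duration_s = 0.7)
  det <- detect_clicks(x, fs)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$time_s - 0.30), 5e-4)
  expect_gte(det$duration_us, 30)
  expect_lte(det$duration_us, 1200)

  # amplitude floor at 115 dBpp: 114 rejected, 116 kept
  x <- toy_track(list(
    list(time_s = 0.10, waveform = tone_burst(100, p2p = rl_to_p2p(114))),
    list(time_s = 0.30, waveform = tone_burst(100, p2p = rl_to_p2p(116)))
  ), duration_s = 0.5)
  det <- detect_clicks(x, fs)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$time_s - 0.30), 5e-4)
  expect_gte(det$rl_dbpp, 115)

  # two impulses 50 us apart merge into one detection
  x <- toy_track(list(
    list(time_s = 0.100000, waveform = tone_burst(60, p2p = p2p130)),
    list(time_s = 0.100110, waveform = tone_burst(60, p2p = p2p130))
  ), duration_s = 0.3)
  det <- detect_clicks(x, fs)
  expect_equal(nrow(det), 1)

  # same impulses 500 us apart stay separate
  x <- toy_track(list(
    list(time_s = 0.1000, waveform = tone_burst(60, p2p = p2p130)),
    list(time_s = 0.1006, waveform = tone_burst(60, p2p = p2p130))
  ), duration_s = 0.3)
  det <- detect_clicks(x, fs)
  expect_equal(nrow(det), 2)
  expect_gte(diff(det$time_s) * 1e6, 100)

  expect_error(detect_clicks(numeric(0), fs), "waveform")
  expect_error(detect_clicks(c(1, NA, 2), fs), "waveform")
})

test_that("high-SNR scenes are recovered nearly completely and accurately", {
  out <- shared_scene()
  det <- out$detections
  expect_gt(nrow(det), 0)
  err <- vapply(out$truth$time_s,
                function(tt) min(abs(det$time_s - tt)), 0)
  expect_gte(mean(err < 5e-4), 0.95)
  # every retained detection obeys the invariants
  expect_true(all(det$duration_us >= 30 & det$duration_us <= 1200))
  expect_true(all(det$rl_dbpp >= 115))
  if (nrow(det) > 1) expect_true(all(diff(det$time_s) * 1e6 >= 100))
  expect_true(!is.unsorted(det$time_s))
  # received levels match injected levels for matched clicks
  idx <- vapply(det$time_s,
                function(tt) which.min(abs(out$truth$time_s - tt)), 1L)
  close <- abs(det$time_s - out$truth$time_s[idx]) < 5e-4
  expect_lt(stats::median(abs(det$rl_dbpp[close] - out$truth$rl_dbpp[idx][close])), 0.5)
  # envelopes are max-normalized
  for (e in det$envelope[1:5]) {
    expect_equal(max(e), 1)
    expect_true(all(e >= 0 & e <= 1))
  }
})

test_that("detections round-trip through CSV", {
  out <- shared_scene()
  det <- out$detections[1:5, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, path)
  back <- read_detections(path)
  expect_equal(nrow(back), 5)
  expect_equal(back$time_s, det$time_s)
  expect_equal(back$spectrum[[3]], det$spectrum[[3]], tolerance = 1e-6)
  expect_equal(back$envelope[[2]], det$envelope[[2]], tolerance = 1e-6)
})
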