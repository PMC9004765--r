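test_that("template constructor enforces descriptor invariants", {
  pk <- data.frame(freq_khz = 40, bw_khz = 5, amp = 1)
  expect_s3_class(click_template("ok", pk, 0.2, 0.05), "click_template")
  expect_error(click_template("bad", data.frame(freq_khz = 5, bw_khz = 5, amp = 1),
                              0.2, 0.05), "10, 100")
  expect_error(click_template("bad", data.frame(freq_khz = 40, bw_khz = 0, amp = 1),
                              0.2, 0.05), "bandwidth")
  expect_error(click_template("bad", data.frame(freq_khz = 40, bw_khz = 5, amp = 1.5),
                              0.2, 0.05), "amplitude")
  expect_error(click_template("bad", pk, 0.7, 0.05), "modal ICI")
  expect_length(hawaii_click_templates(), 10)
})

test_that("click waveforms have the requested length and are reproducible", {
  tpl <- single_peak_template()
  w <- synth_click_waveform(tpl, duration_us = 30, fs_hz = 200000, seed = 1)
  expect_length(w, 6)  # 30 us at 200 kHz
  expect_true(all(is.finite(w)))
  w2 <- synth_click_waveform(tpl, duration_us = 300, fs_hz = 200000, seed = 5)
  expect_identical(w2, synth_click_waveform(tpl, duration_us = 300,
                                            fs_hz = 200000, seed = 5))
  expect_false(identical(w2, synth_click_waveform(tpl, duration_us = 300,
                                                  fs_hz = 200000, seed = 6)))
  expect_error(synth_click_waveform(tpl, duration_us = 20), "30, 1200")
  expect_error(synth_click_waveform(tpl, duration_us = 1500), "30, 1200")
})

test_that("Kogia-type waveforms put their spectral peak at 93.5 kHz", {
  tpl <- hawaii_click_templates("Kogia spp.")[[1]]
  peaks <- vapply(1:25, function(s) {
    sp <- click_spectrum(synth_click_waveform(tpl, seed = s), 200000)
    as.numeric(names(sp)[which.max(sp)])
  }, 0)
  expect_true(all(peaks >= 92.5 & peaks <= 94.5))
})

test_that("click energy is confined to the 10-100 kHz band", {
  for (nm in c("Tt/Pe", "Short-finned pilot whale 2", "Kogia spp.")) {
    tpl <- hawaii_click_templates(nm)[[1]]
    w <- synth_click_waveform(tpl, fs_hz = 320000, seed = 3)
    P <- Mod(stats::fft(w))^2
    f <- (seq_along(w) - 1) * 320000 / length(w)
    half <- f <= 160000
    frac_out <- 1 - sum(P[half & f >= 10000 & f <= 100000]) / sum(P[half])
    expect_lt(frac_out, 0.05)
  }
})

test_that("click train gaps follow the template's truncated Gaussian", {
  cuvier <- hawaii_click_templates("Cuvier's beaked whale")[[1]]
  gaps <- diff(synth_click_train(cuvier, 5001, seed = 2))
  # Monte-Carlo band for the sample mean of N(0.433, 0.059) at n = 5000
  expect_gt(mean(gaps), 0.427)
  expect_lt(mean(gaps), 0.439)
  expect_true(all(gaps > 0.005))

  t2 <- synth_click_train(cuvier, 2, seed = 1)
  expect_length(diff(t2), 1)
  expect_gt(diff(t2), 0)
  expect_error(synth_click_train(cuvier, 1), "n_clicks")
  expect_identical(synth_click_train(cuvier, 10, seed = 9),
                   synth_click_train(cuvier, 10, seed = 9))
})

test_that("the false killer whale train is bimodal in its gap histogram", {
  fkw <- hawaii_click_templates("False killer whale")[[1]]
  gaps <- diff(synth_click_train(fkw, 60001, seed = 4))
  h <- graphics::hist(gaps[gaps <= 0.6], breaks = seq(0, 0.6, 0.01),
                      plot = FALSE)
  nb <- length(h$counts)
  smoothed <- vapply(seq_len(nb), function(i) {
    mean(h$counts[max(1, i - 2):min(nb, i + 2)])
  }, 0)
  inner <- 2:(nb - 1)
  local_max <- inner[vapply(inner, function(i) {
    lo <- max(1, i - 2)
    hi <- min(nb, i + 2)
    smoothed[i] >= max(smoothed[lo:hi])
  }, TRUE)]
  modes <- h$mids[local_max]
  expect_gte(length(modes), 2)
  expect_true(any(abs(modes - 0.0284) < 0.02))
  expect_true(any(abs(modes - 0.166) < 0.05))
})

test_that("rendered scenes honour received levels and ground truth", {
  expect_error(scene_config(duration_s = 5), "seed")
  empty <- render_scene(scene_config(duration_s = 0.5, seed = 3))
  expect_equal(nrow(empty$truth), 0)

  tpl <- single_peak_template()
  sc <- scene_config(duration_s = 3,
                     trains = list(list(template = tpl, start_s = 0.3,
                                        n_clicks = 10, rl_dbpp = c(132, 132))),
                     background_rms = 1e-5, seed = 8)
  out <- render_scene(sc)
  expect_identical(out$waveform, render_scene(sc)$waveform)
  expect_equal(nrow(out$truth), 10)
  # peak-to-peak of an isolated click matches its drawn received level
  i0 <- round(out$truth$time_s[1] * out$fs_hz)
  seg <- out$waveform[i0:(i0 + 400)]
  rl_realized <- 20 * log10(max(seg) - min(seg)) + out$calibration_db
  expect_equal(rl_realized, out$truth$rl_dbpp[1], tolerance = 0.01)
  expect_error(scene_config(duration_s = 1, seed = 1,
                            trains = list(list(template = tpl, start_s = 0,
                                               n_clicks = 5, rl_dbpp = c(90, 95)))),
               "100, 160")
})

test_that("labelled bin generation is balanced, junk-aware and seeded", {
  tpls <- hawaii_click_templates(c("Kogia spp.", "Stenellid 1"))
  bins <- synth_labelled_bins(tpls, 10, seed = 5)
  expect_equal(nrow(bins), 30)  # 2 classes + junk
  expect_setequal(unique(bins$class_label),
                  c("Kogia spp.", "Stenellid 1", "junk"))
  expect_true(all(table(bins$class_label) == 10))
  for (i in seq_len(nrow(bins))) {
    expect_equal(range(bins$mean_spectrum[[i]]), c(0, 1))
    h <- bins$ici_hist[[i]]
    expect_true(abs(sum(h) - 1) < 1e-9 || all(h == 0))
    expect_equal(max(bins$mean_envelope[[i]]), 1)
  }
  # junk energy sits below 20 kHz (first 21 grid bins, 10-20 kHz)
  junk <- bins[bins$class_label == "junk", ]
  low_heavy <- vapply(junk$mean_spectrum, function(s) {
    mean(s[1:21]) > mean(s[22:181])
  }, TRUE)
  expect_true(mean(low_heavy) >= 0.9)
  expect_identical(bins, synth_labelled_bins(tpls, 10, seed = 5))
  expect_error(synth_labelled_bins(tpls, 0), "n_bins_per_class")
})

test_that("scene WAV files round-trip", {
  tpl <- single_peak_template()
  sc <- scene_config(duration_s = 0.3,
                     trains = list(list(template = tpl, start_s = 0.05,
                                        n_clicks = 3, rl_dbpp = c(130, 132))),
                     background_rms = 1e-4, seed = 12)
  out <- render_scene(sc)
  path <- withr::local_tempfile(fileext = ".wav")
  scale <- write_scene_wav(out$waveform, path, out$fs_hz)
  back <- read_scene_wav(path, scale = scale)
  expect_equal(back$fs_hz, out$fs_hz)
  expect_equal(back$waveform, out$waveform, tolerance = 1e-3)
})
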