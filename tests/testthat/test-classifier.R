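test_that("training-set construction balances, splits and confines augmentation", {
  # full-scale defaults mirror the published training construction
  cfg_default <- network_config()
  expect_equal(cfg_default$examples_per_class, 5000)
  expect_equal(cfg_default$split, c(70, 20, 10))
  expect_equal(cfg_default$hidden_layers, rep(512, 4))
  expect_equal(cfg_default$dropout, 0.5)
  expect_error(network_config(split = c(70, 20, 20)), "sum to 100")
  expect_error(network_config(dropout = 1), "dropout")

  tpls <- hawaii_click_templates(c("Kogia spp.", "Stenellid 1"))
  bins <- synth_labelled_bins(tpls, 120, seed = 7, include_junk = FALSE)
  # abundant class: subsample, no augmentation (target 100 of 120)
  cfg <- network_config(examples_per_class = 100, seed = 3)
  ts <- build_training_set(bins, cfg)
  expect_equal(nrow(ts$train), 2 * 70)
  expect_equal(nrow(ts$test), 2 * 20)
  expect_equal(nrow(ts$validation), 2 * 10)
  expect_equal(sum(ts$train$augmented), 0)

  # scarce class: 60 originals to target 100 -> 40 augmented, train only
  scarce <- dplyr::bind_rows(
    bins[bins$class_label == "Kogia spp.", ],
    bins[bins$class_label == "Stenellid 1", ][1:60, ]
  )
  ts2 <- build_training_set(scarce, cfg)
  by_class <- table(ts2$train$class_label)
  expect_true(all(by_class == 70))
  expect_equal(sum(ts2$train$augmented[ts2$train$class_label == "Stenellid 1"]), 40)
  expect_equal(sum(ts2$test$augmented), 0)
  expect_equal(sum(ts2$validation$augmented), 0)
  expect_true(all(table(ts2$test$class_label) == 20))

  # determinism and empty-class error
  ts3 <- build_training_set(bins, cfg)
  expect_identical(ts3$train$bin_id, ts$train$bin_id)
  expect_error(build_training_set(bins[0, ], cfg), "class")
})

test_that("spectrum/envelope augmentation adds bounded low-amplitude noise", {
  bins <- synth_labelled_bins(hawaii_click_templates("Kogia spp."), 2,
                              seed = 9, include_junk = FALSE)
  ex <- bins[1, ]
  same <- augment_spectrum_envelope(ex, noise_sd = 0)
  expect_equal(same$mean_spectrum[[1]], ex$mean_spectrum[[1]])
  expect_equal(same$mean_envelope[[1]], ex$mean_envelope[[1]])
  expect_true(same$augmented)
  cors <- withr::with_seed(4, vapply(1:50, function(i) {
    aug <- augment_spectrum_envelope(ex)
    s <- aug$mean_spectrum[[1]]
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(aug$mean_envelope[[1]] >= 0 & aug$mean_envelope[[1]] <= 1))
    cor(s, ex$mean_spectrum[[1]])
  }, 0))
  expect_gt(min(cors), 0.9)
})

test_that("ICI augmentation perturbs gently and conserves mass", {
  bins <- synth_labelled_bins(hawaii_click_templates("Tt/Pe"), 30,
                              seed = 11, include_junk = FALSE)
  pool <- colMeans(do.call(rbind, bins$ici_hist))
  ex <- bins[1, ]
  ident <- augment_ici(ex, pool, perturb_frac = 0)
  expect_equal(ident$ici_hist[[1]], ex$ici_hist[[1]])
  kl <- withr::with_seed(5, vapply(1:50, function(i) {
    aug <- augment_ici(ex, pool)
    h <- aug$ici_hist[[1]]
    expect_equal(sum(h), 1)
    keep <- ex$ici_hist[[1]] > 0 & h > 0
    sum(ex$ici_hist[[1]][keep] *
          log(ex$ici_hist[[1]][keep] / h[keep]))
  }, 0))
  expect_lt(mean(kl), 0.1)
  expect_warning(augment_ici(ex, numeric(0)), "empty")
})

test_that("the network overfits a tiny separable set and outputs a simplex", {
  tpls <- hawaii_click_templates(c("Kogia spp.", "Stenellid 1"))
  bins <- synth_labelled_bins(tpls, 25, seed = 13, include_junk = FALSE)
  cfg <- network_config(epochs = 60, patience = Inf, batch_size = 25,
                        seed = 2)
  net <- train_click_net(bins, config = cfg)
  P <- predict(net, bins)
  expect_equal(unname(rowSums(P)), rep(1, nrow(bins)), tolerance = 1e-6)
  acc <- mean(net$classes[max.col(P)] == bins$class_label)
  expect_equal(acc, 1)
  # history and summaries
  expect_s3_class(tidy(net), "tbl_df")
  g <- glance(net)
  expect_equal(g$n_classes, 2)
  expect_gt(g$n_parameters, 9e5)
  expect_error(predict(net, matrix(0, 2, 10)), "dimension")
})

test_that("bin classification labels everything with calibrated confidence", {
  tpls <- hawaii_click_templates(c("Kogia spp.", "Stenellid 1", "Tt/Pe"))
  bins <- synth_labelled_bins(tpls, 40, seed = 17)
  cfg <- network_config(examples_per_class = 30, epochs = 25, patience = 10,
                        seed = 5)
  sets <- build_training_set(bins, cfg)
  net <- train_click_net(sets$train, sets$validation, cfg)
  labelled <- classify_bins(net, sets$test)
  expect_equal(nrow(labelled), nrow(sets$test))
  expect_true(all(labelled$confidence >= 1 / length(net$classes)))
  expect_true(all(labelled$confidence <= 1))
  expect_gt(mean(labelled$label == labelled$class_label), 0.9)
  empty <- classify_bins(net, sets$test[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("label", "confidence") %in% names(empty)))
})

test_that("models round-trip through the text serialization", {
  tpls <- hawaii_click_templates(c("Kogia spp.", "Stenellid 1"))
  bins <- synth_labelled_bins(tpls, 10, seed = 19, include_junk = FALSE)
  cfg <- network_config(hidden_layers = c(16, 16), epochs = 3, seed = 1)
  net <- train_click_net(bins, config = cfg)
  base <- file.path(withr::local_tempdir(), "model")
  write_click_net(net, base)
  back <- read_click_net(base)
  expect_equal(back$classes, net$classes)
  X <- bin_features_matrix(bins)
  expect_equal(predict(back, X), predict(net, X), tolerance = 1e-8)
})
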