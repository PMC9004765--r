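# brute-force NMI oracle, written independently of the package version
nmi_oracle <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  n <- length(a)
  mi <- 0
  for (i in ua) {
    for (j in ub) {
      nij <- sum(a == i & b == j)
      if (nij > 0) mi <- mi + (nij / n) * log((nij / n) / ((sum(a == i) / n) * (sum(b == j) / n)))
    }
  }
  ha <- -sum(sapply(ua, function(i) (sum(a == i) / n) * log(sum(a == i) / n)))
  hb <- -sum(sapply(ub, function(j) (sum(b == j) / n) * log(sum(b == j) / n)))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / sqrt(ha * hb)
}

planted_weights <- function(sizes, p_in = 1, p_out = 0, w_in = 1, w_out = 0.1,
                            seed = 1) {
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        same <- block[i] == block[j]
        p <- if (same) p_in else p_out
        if (runif(1) < p) W[i, j] <- W[j, i] <- if (same) w_in else w_out
      }
    }
    list(W = W, block = block)
  })
}

test_that("correlation distance matches the explicit covariance formula", {
  u <- c(1, 3, 2, 5)
  expect_equal(correlation_distance(u, u), 0)
  expect_equal(correlation_distance(u, -u + 7), 2)
  for (i in 1:20) {
    pair <- withr::with_seed(i, list(a = rnorm(30), b = rnorm(30)))
    a <- pair$a
    b <- pair$b
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(correlation_distance(a, b), 1 - r, tolerance = 1e-12)
  }
  expect_error(correlation_distance(rep(1, 5), 1:5), "constant")
  expect_error(correlation_distance(1:4, 1:5), "equal length")
})

test_that("Chinese Whispers recovers planted cliques and converges", {
  g <- planted_weights(c(30, 30), p_out = 0.02, seed = 3)
  part <- chinese_whispers(g$W, seed = 1)
  expect_equal(part$n_clusters, 2)
  expect_equal(nmi(part$labels, g$block), 1)

  # single node, no edges
  p1 <- chinese_whispers(matrix(0, 1, 1), seed = 1)
  expect_equal(p1$n_clusters, 1)
  # complete graph with equal weights collapses to one cluster
  W <- matrix(1, 20, 20) - diag(20)
  pc <- chinese_whispers(W, seed = 2)
  expect_equal(pc$n_clusters, 1)
  expect_true(pc$converged)
  # empty graph
  p0 <- chinese_whispers(matrix(0, 0, 0), seed = 1)
  expect_equal(p0$n_clusters, 0)
  # every node labelled, ids contiguous
  g3 <- planted_weights(c(15, 15, 15), p_out = 0.05, seed = 4)
  p3 <- chinese_whispers(g3$W, seed = 5)
  expect_length(p3$labels, 45)
  expect_setequal(unique(p3$labels), seq_len(p3$n_clusters))
  # agreement with an independent label-propagation implementation
  skip_if_not_installed("igraph")
  ig <- igraph::graph_from_adjacency_matrix(g$W, mode = "undirected",
                                            weighted = TRUE)
  lp <- igraph::cluster_label_prop(ig)
  expect_equal(nmi(part$labels, igraph::membership(lp)), 1)
})

test_that("NMI behaves like a normalized partition similarity", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, c(9, 9, 4, 4, 7, 7)), 1)  # relabelling invariance
  expect_equal(nmi(rep(1, 5), rep(2, 5)), 1)    # both single-cluster
  expect_equal(nmi(rep(1, 4), c(1, 1, 2, 2)), 0)
  # symmetry, range and oracle agreement on random partitions
  for (i in 1:15) {
    ab <- withr::with_seed(100 + i,
                           list(a = sample(1:4, 40, TRUE), b = sample(1:3, 40, TRUE)))
    expect_equal(nmi(ab$a, ab$b), nmi(ab$b, ab$a))
    expect_gte(nmi(ab$a, ab$b), 0)
    expect_lte(nmi(ab$a, ab$b), 1)
    expect_equal(nmi(ab$a, ab$b), max(0, nmi_oracle(ab$a, ab$b)), tolerance = 1e-12)
  }
  # independent large random partitions score near zero
  ab <- withr::with_seed(9, list(a = sample(1:2, 1000, TRUE),
                                 b = sample(1:2, 1000, TRUE)))
  expect_lt(nmi(ab$a, ab$b), 0.05)
  expect_error(nmi(1:3, 1:4), "node set")
})

test_that("within-bin clustering enforces level floor, caps and size minima", {
  tpls <- hawaii_click_templates(c("Kogia spp.", "Cuvier's beaked whale"))
  # 40 clicks of one type: below the 50-click minimum, no cluster emitted
  d40 <- make_detections(tpls[1], 40, seed = 1)
  expect_equal(nrow(cluster_bins(d40)), 0)
  # detections below 120 dBpp are dropped before clustering
  d <- make_detections(tpls[1], 60, seed = 2)
  d_low <- dplyr::mutate(d, rl_dbpp = 118)
  expect_equal(nrow(cluster_bins(d_low)), 0)
  # 100 + 100 clicks of two well-separated types: two pure clusters
  d2 <- make_detections(tpls, 100, seed = 3)
  bc <- cluster_bins(d2, cluster_params(seed = 11))
  expect_equal(nrow(bc), 2)
  expect_true(all(bc$member_count >= 50))
  expect_equal(sum(bc$member_count), 200)
  # purity via template matching of the two mean spectra
  ref <- vapply(tpls, template_spectrum, numeric(181))
  assigned <- vapply(bc$mean_spectrum, function(s) {
    which.min(apply(ref, 2, function(r) correlation_distance(r, s)))
  }, 1L)
  expect_setequal(assigned, 1:2)
  # subsampling cap: 130 eligible clicks with a cap of 120 -> 120 members
  pcap <- cluster_params(max_nodes_phase1 = 120, min_cluster_size_clicks = 20,
                         seed = 5)
  d3 <- make_detections(tpls[1], 130, seed = 4)
  bc3 <- cluster_bins(d3, pcap)
  expect_equal(sum(bc3$member_count), 120)
  # defaults carry the full-scale caps
  p <- cluster_params()
  expect_equal(p$max_nodes_phase1, 10000)
  expect_equal(p$max_nodes_phase2, 20000)
  expect_equal(p$min_cluster_size_clicks, 50)
  expect_equal(p$min_cluster_size_bins, 25)
  expect_equal(p$min_rl_dbpp, 120)
  expect_equal(p$prune_fraction, 0.01)
})

test_that("type-level clustering separates planted templates and prunes", {
  tpls <- hawaii_click_templates(c("Kogia spp.", "Stenellid 1",
                                   "False killer whale"))
  bins <- synth_labelled_bins(tpls, 40, seed = 21, include_junk = FALSE)
  bc <- dplyr::transmute(bins,
                         bin_start = (dplyr::row_number() - 1) * 300,
                         cluster_id = bin_id, member_count = 60L,
                         modal_ici_s = NA_real_, ici_sd_s = NA_real_,
                         rl_max_dbpp = rl_max_dbpp, mean_nmi = 1,
                         mean_spectrum = mean_spectrum, ici_hist = ici_hist,
                         mean_envelope = mean_envelope,
                         truth = class_label)
  ct <- cluster_types(bc, cluster_params(seed = 31))
  expect_equal(nrow(ct$types), 3)
  purity <- ct$assignments |>
    dplyr::filter(!is.na(type_id)) |>
    dplyr::group_by(type_id) |>
    dplyr::summarise(p = max(table(truth)) / dplyr::n())
  expect_true(all(purity$p >= 0.95))
  # 1% pruning: floor(0.01 * 40) = 0 per 40-bin cluster, so none pruned here;
  # with a 100-bin cluster exactly one node is pruned
  one <- synth_labelled_bins(tpls[1], 100, seed = 22, include_junk = FALSE)
  bc1 <- dplyr::transmute(one,
                          bin_start = (dplyr::row_number() - 1) * 300,
                          cluster_id = bin_id, member_count = 60L,
                          modal_ici_s = NA_real_, ici_sd_s = NA_real_,
                          rl_max_dbpp = rl_max_dbpp, mean_nmi = 1,
                          mean_spectrum = mean_spectrum, ici_hist = ici_hist,
                          mean_envelope = mean_envelope)
  ct1 <- cluster_types(bc1, cluster_params(seed = 32))
  expect_equal(sum(is.na(ct1$assignments$type_id)), 1)
  expect_equal(ct1$types$n_bins, 99)
  # clusters below 25 bins are discarded
  small <- synth_labelled_bins(tpls[1], 20, seed = 23, include_junk = FALSE)
  bcs <- dplyr::transmute(small,
                          bin_start = (dplyr::row_number() - 1) * 300,
                          cluster_id = bin_id, member_count = 60L,
                          modal_ici_s = NA_real_, ici_sd_s = NA_real_,
                          rl_max_dbpp = rl_max_dbpp, mean_nmi = 1,
                          mean_spectrum = mean_spectrum, ici_hist = ici_hist,
                          mean_envelope = mean_envelope)
  expect_warning(ct_small <- cluster_types(bcs, cluster_params(seed = 33)),
                 "25 bins")
  expect_equal(nrow(ct_small$types), 0)
})

test_that("template matching assigns clusters to the right types", {
  tpls <- hawaii_click_templates(c("Kogia spp.", "Cuvier's beaked whale"))
  bins <- synth_labelled_bins(tpls, 30, seed = 41, include_junk = FALSE)
  types <- tibble::tibble(
    type_id = 1:2,
    mean_spectrum = list(
      colMeans(do.call(rbind, bins$mean_spectrum[bins$class_label == "Kogia spp."])),
      colMeans(do.call(rbind, bins$mean_spectrum[bins$class_label == "Cuvier's beaked whale"]))
    )
  )
  m <- match_templates(types, tpls)
  expect_equal(m$template, c("Kogia spp.", "Cuvier's beaked whale"))
  expect_true(all(m$distance < 0.5))
  # empty template list and zero ceiling
  m0 <- match_templates(types, list())
  expect_true(all(m0$template == "unassigned"))
  m1 <- match_templates(types, tpls, distance_ceiling = 0)
  expect_true(all(m1$template == "unassigned"))
})
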