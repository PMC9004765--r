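#' Correlation distance between two feature vectors
#'
#' `1 - Pearson correlation`, in \[0, 2\]: 0 for perfectly correlated
#' shapes, 2 for perfectly anticorrelated ones. The distance used to
#' compare click spectra and waveform envelopes.
#'
#' @param u,v Numeric vectors of equal length (>= 2), non-constant.
#' @return Distance in \[0, 2\].
#' @examples
#' correlation_distance(1:5, 5:1)
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2) {
    stopf("u and v must have equal length >= 2")
  }
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stopf("correlation distance is undefined for constant vectors")
  }
  1 - stats::cor(u, v)
}

# pairwise correlation distance between rows of a matrix
correlation_distance_matrix <- function(X) {
  1 - stats::cor(t(X))
}

#' Clustering parameters
#'
#' Thresholds for the two-phase clustering: a 120 dBpp received-level
#' floor for phase 1, minimum cluster sizes of 50 clicks (phase 1) and 25
#' bins (phase 2), network-size caps of 10,000 and 20,000 nodes, at most
#' 15 label-propagation iterations, pruning of the 1% least-connected
#' nodes within each phase-2 cluster, and 5 repeated runs per phase with
#' the best partition chosen by average normalized mutual information.
#'
#' @param min_rl_dbpp Received-level floor applied before phase 1.
#' @param min_cluster_size_clicks Minimum clicks per phase-1 cluster.
#' @param max_nodes_phase1 Phase-1 network cap (random subsample beyond it).
#' @param max_cw_iterations Label-propagation iteration cap.
#' @param min_cluster_size_bins Minimum bins per phase-2 cluster.
#' @param max_nodes_phase2 Phase-2 network cap.
#' @param prune_fraction Fraction of least-connected nodes pruned within
#'   each phase-2 cluster, in \[0, 0.1\].
#' @param n_trials_phase1,n_trials_phase2 Repeated runs per phase.
#' @param edge_similarity_threshold Phase-1 edge rule: click pairs with
#'   similarity `1 - distance/2` above this value are connected; the
#'   similarity is the edge weight.
#' @param edge_similarity_threshold_phase2 Same rule for phase 2, where
#'   the nodes are bin-cluster means; tighter than phase 1 because mean
#'   features are far less noisy than single clicks.
#' @param match_distance_ceiling Correlation-distance ceiling above which
#'   [match_templates()] leaves a type cluster unassigned.
#' @param seed Integer seed driving all random node orders and subsamples.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(min_rl_dbpp = 120, min_cluster_size_clicks = 50,
                           max_nodes_phase1 = 10000, max_cw_iterations = 15,
                           min_cluster_size_bins = 25, max_nodes_phase2 = 20000,
                           prune_fraction = 0.01, n_trials_phase1 = 5,
                           n_trials_phase2 = 5, edge_similarity_threshold = 0.75,
                           edge_similarity_threshold_phase2 = 0.9,
                           match_distance_ceiling = 0.5, seed = 1) {
  if (prune_fraction < 0 || prune_fraction > 0.1) {
    stopf("prune_fraction must be in [0, 0.1]")
  }
  structure(
    list(min_rl_dbpp = min_rl_dbpp,
         min_cluster_size_clicks = min_cluster_size_clicks,
         max_nodes_phase1 = max_nodes_phase1,
         max_cw_iterations = max_cw_iterations,
         min_cluster_size_bins = min_cluster_size_bins,
         max_nodes_phase2 = max_nodes_phase2,
         prune_fraction = prune_fraction,
         n_trials_phase1 = n_trials_phase1,
         n_trials_phase2 = n_trials_phase2,
         edge_similarity_threshold = edge_similarity_threshold,
         edge_similarity_threshold_phase2 = edge_similarity_threshold_phase2,
         match_distance_ceiling = match_distance_ceiling,
         seed = as.integer(seed)),
    class = "cluster_params"
  )
}

# distance matrix -> thresholded similarity (weight) matrix, zero diagonal
similarity_graph <- function(D, threshold) {
  S <- 1 - D / 2
  S[S <= threshold] <- 0
  diag(S) <- 0
  S
}

#' Chinese Whispers label propagation
#'
#' Randomized community detection on a weighted undirected graph: every
#' node starts in its own cluster and, visiting nodes in a fresh random
#' order each iteration, adopts the label carrying the maximum summed
#' edge weight among its neighbors (ties broken at random). Stops when an
#' iteration changes no label, or after `max_iterations`.
#'
#' @param weights Symmetric non-negative weight matrix with zero diagonal
#'   (zero = no edge).
#' @param max_iterations Iteration cap.
#' @param seed Integer seed for the visit order and tie-breaks.
#' @return List of class `cw_partition`: `labels` (integer vector,
#'   cluster ids contiguous from 1 in order of first appearance),
#'   `n_clusters`, `converged`, `iterations`.
#' @examples
#' W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- W[3, 4] <- W[4, 3] <- 1
#' chinese_whispers(W, seed = 1)$n_clusters
#' @export
chinese_whispers <- function(weights, max_iterations = 15, seed = 1) {
  n <- nrow(weights)
  if (is.null(n) || n == 0) {
    return(structure(list(labels = integer(0), n_clusters = 0L,
                          converged = TRUE, iterations = 0L),
                     class = "cw_partition"))
  }
  nbrs <- apply(weights, 2, function(w) which(w > 0), simplify = FALSE)
  labels <- seq_len(n)
  converged <- FALSE
  iter <- 0L
  with_seed(seed, {
    for (iter_i in seq_len(max_iterations)) {
      iter <<- iter_i
      changed <- FALSE
      for (i in sample.int(n)) {
        nb <- nbrs[[i]]
        if (!length(nb)) next
        sums <- rowsum(weights[nb, i], labels[nb])
        best <- rownames(sums)[sums == max(sums)]
        new_lab <- if (length(best) == 1) {
          as.integer(best)
        } else {
          as.integer(best[sample.int(length(best), 1)])
        }
        if (new_lab != labels[i]) {
          labels[i] <- new_lab
          changed <- TRUE
        }
      }
      if (!changed) {
        converged <- TRUE
        break
      }
    }
  })
  labels <- match(labels, unique(labels))
  structure(list(labels = labels, n_clusters = length(unique(labels)),
                 converged = converged, iterations = iter),
            class = "cw_partition")
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the label co-occurrence table normalized by
#' `sqrt(H(a) * H(b))`: 1 for partitions identical up to relabelling, 0
#' for independent ones. When both partitions have zero entropy (a single
#' cluster each) the score is 1; when exactly one does, 0.
#'
#' @param a,b Label vectors over the same node set.
#' @return Score in \[0, 1\].
#' @examples
#' nmi(c(1, 1, 2, 2), c(5, 5, 9, 9))
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions must cover the same node set")
  if (!length(a)) return(1)
  ct <- table(a, b)
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  max(0, min(1, mi / sqrt(ha * hb)))
}

# run CW n_runs times; score each run by mean NMI against the others;
# return the best run (ties: fewer clusters, then earlier run)
cw_consensus <- function(weights, n_runs, max_iterations, seed) {
  runs <- purrr::map(seq_len(n_runs), function(r) {
    chinese_whispers(weights, max_iterations, seed = derive_seed(seed, r))
  })
  if (n_runs == 1) {
    runs[[1]]$mean_nmi <- 1
    return(runs[[1]])
  }
  scores <- vapply(seq_len(n_runs), function(r) {
    mean(vapply(setdiff(seq_len(n_runs), r), function(s) {
      nmi(runs[[r]]$labels, runs[[s]]$labels)
    }, 0))
  }, 0)
  sizes <- vapply(runs, `[[`, 0L, "n_clusters")
  best <- order(-scores, sizes, seq_len(n_runs))[1]
  out <- runs[[best]]
  out$mean_nmi <- scores[best]
  out
}

#' Phase-1 clustering: clicks within 5-minute bins
#'
#' For each 5-minute bin, detections above the received-level floor are
#' connected by spectral-shape similarity (correlation distance between
#' min-max-normalized dB spectra) and partitioned with Chinese Whispers;
#' the partition with the highest average NMI over repeated runs is kept.
#' Bins with more eligible detections than the network cap are randomly
#' subsampled. Clusters below the minimum click count are discarded. Each
#' surviving cluster is summarized by its mean normalized spectrum, ICI
#' distribution, mean envelope and a Gaussian modal-ICI fit.
#'
#' @param detections Detections tibble from [detect_clicks()] (a
#'   `bin_start` column is added via [assign_bins()] when absent).
#' @param params A [cluster_params].
#' @param bin_length_s Bin length in seconds.
#' @return Tibble with one row per bin-cluster: `bin_start`, `cluster_id`,
#'   `member_count`, `modal_ici_s`, `ici_sd_s`, `rl_max_dbpp`, `mean_nmi`
#'   and list-columns `mean_spectrum`, `ici_hist`, `mean_envelope`.
#' @export
cluster_bins <- function(detections, params = cluster_params(), bin_length_s = 300) {
  if (!"bin_start" %in% names(detections)) {
    detections <- assign_bins(detections, bin_length_s)
  }
  eligible <- dplyr::filter(detections, .data$rl_dbpp >= params$min_rl_dbpp)
  if (!nrow(eligible)) return(empty_bin_clusters())
  out <- eligible |>
    dplyr::group_by(.data$bin_start) |>
    dplyr::group_map(~ cluster_one_bin(.x, .y$bin_start, params)) |>
    dplyr::bind_rows()
  if (!nrow(out)) return(empty_bin_clusters())
  out
}

empty_bin_clusters <- function() {
  tibble::tibble(bin_start = numeric(), cluster_id = character(),
                 member_count = integer(), modal_ici_s = numeric(),
                 ici_sd_s = numeric(), rl_max_dbpp = numeric(),
                 mean_nmi = numeric(), mean_spectrum = list(),
                 ici_hist = list(), mean_envelope = list())
}

cluster_one_bin <- function(dets, bin_start, params) {
  bin_seed <- derive_seed(params$seed, round(bin_start))
  if (nrow(dets) > params$max_nodes_phase1) {
    keep <- with_seed(derive_seed(bin_seed, 99),
                      sample.int(nrow(dets), params$max_nodes_phase1))
    dets <- dets[sort(keep), ]
  }
  norm_ok <- vapply(dets$spectrum, function(s) stats::sd(s) > 0, TRUE)
  dets <- dets[norm_ok, ]
  if (nrow(dets) < 2) return(NULL)
  M <- do.call(rbind, purrr::map(dets$spectrum, normalize_spectrum))
  S <- similarity_graph(correlation_distance_matrix(M),
                        params$edge_similarity_threshold)
  part <- cw_consensus(S, params$n_trials_phase1, params$max_cw_iterations,
                       bin_seed)
  keep_labels <- which(tabulate(part$labels) >= params$min_cluster_size_clicks)
  if (!length(keep_labels)) return(NULL)
  purrr::map(keep_labels, function(lab) {
    idx <- which(part$labels == lab)
    env <- colMeans(do.call(rbind, dets$envelope[idx]))
    ici <- ici_distribution(sort(dets$time_s[idx]))
    fit <- fit_ici_gaussian(ici)
    tibble::tibble(
      bin_start = bin_start,
      cluster_id = sprintf("b%s_c%d", format(bin_start, trim = TRUE), lab),
      member_count = length(idx),
      modal_ici_s = fit$modal_ici_s, ici_sd_s = fit$ici_sd_s,
      rl_max_dbpp = max(dets$rl_dbpp[idx]),
      mean_nmi = part$mean_nmi,
      mean_spectrum = list(colMeans(M[idx, , drop = FALSE])),
      ici_hist = list(ici),
      mean_envelope = list(env / max(env))
    )
  }) |>
    dplyr::bind_rows()
}

#' Phase-2 clustering: bin clusters into click types
#'
#' Bin-cluster summaries from [cluster_bins()] are compared across the
#' dataset with a fused distance (the unweighted mean of the spectral and
#' envelope correlation distances), capped at the phase-2 network size,
#' and partitioned with Chinese Whispers. The procedure runs as repeated
#' trials with different random orders; the trial with the highest
#' average NMI against the others wins. Within each winning cluster the
#' least-connected fraction of nodes (lowest summed intra-cluster edge
#' weight) is pruned, and clusters below the minimum bin count are
#' discarded.
#'
#' @param bin_clusters Tibble from [cluster_bins()].
#' @param params A [cluster_params].
#' @return List of class `click_types`: `assignments` (the input tibble
#'   plus a `type_id` column, `NA` for pruned or discarded rows) and
#'   `types` (one row per surviving type: `type_id`, `n_bins`,
#'   `modal_ici_s`, `ici_sd_s`, list-columns `mean_spectrum`,
#'   `mean_envelope`), plus the winning trial's `mean_nmi`.
#' @export
cluster_types <- function(bin_clusters, params = cluster_params()) {
  if (!nrow(bin_clusters)) stopf("cluster_types() needs at least one bin cluster")
  bc <- bin_clusters
  if (nrow(bc) > params$max_nodes_phase2) {
    keep <- with_seed(derive_seed(params$seed, 777),
                      sample.int(nrow(bc), params$max_nodes_phase2))
    bc <- bc[sort(keep), ]
  }
  Ms <- do.call(rbind, bc$mean_spectrum)
  Me <- do.call(rbind, bc$mean_envelope)
  D <- (correlation_distance_matrix(Ms) + correlation_distance_matrix(Me)) / 2
  S <- similarity_graph(D, params$edge_similarity_threshold_phase2)
  part <- cw_consensus(S, params$n_trials_phase2, params$max_cw_iterations,
                       derive_seed(params$seed, 555))
  labels <- part$labels
  # prune the least-connected fraction within each cluster
  pruned <- logical(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    n_prune <- floor(params$prune_fraction * length(idx))
    if (n_prune > 0) {
      conn <- colSums(S[idx, idx, drop = FALSE])
      pruned[idx[order(conn)[seq_len(n_prune)]]] <- TRUE
    }
  }
  labels[pruned] <- NA_integer_
  sizes <- table(labels)
  keep <- as.integer(names(sizes)[sizes >= params$min_cluster_size_bins])
  labels[!labels %in% keep] <- NA_integer_
  if (!any(!is.na(labels))) {
    warnf("cluster_types: no cluster reached %d bins", params$min_cluster_size_bins)
  }
  type_ids <- match(labels, sort(unique(stats::na.omit(labels))))
  assignments <- dplyr::mutate(bc, type_id = type_ids)
  if (!any(!is.na(type_ids))) {
    return(structure(list(
      assignments = assignments,
      types = tibble::tibble(type_id = integer(), n_bins = integer(),
                             modal_ici_s = numeric(), ici_sd_s = numeric(),
                             mean_spectrum = list(), mean_envelope = list(),
                             ici_hist = list()),
      mean_nmi = part$mean_nmi), class = "click_types"))
  }
  types <- assignments |>
    dplyr::filter(!is.na(.data$type_id)) |>
    dplyr::group_by(.data$type_id) |>
    dplyr::group_map(function(g, key) {
      ici_mean <- colMeans(do.call(rbind, g$ici_hist))
      fit <- fit_ici_gaussian(ici_mean)
      env <- colMeans(do.call(rbind, g$mean_envelope))
      tibble::tibble(
        type_id = key$type_id, n_bins = nrow(g),
        modal_ici_s = fit$modal_ici_s, ici_sd_s = fit$ici_sd_s,
        mean_spectrum = list(colMeans(do.call(rbind, g$mean_spectrum))),
        mean_envelope = list(env / max(env)),
        ici_hist = list(ici_mean)
      )
    }) |>
    dplyr::bind_rows()
  structure(list(assignments = assignments, types = types,
                 mean_nmi = part$mean_nmi),
            class = "click_types")
}

#' @export
print.click_types <- function(x, ...) {
  cat("<click_types>", nrow(x$types), "type cluster(s) over",
      nrow(x$assignments), "bin cluster(s); mean NMI",
      sprintf("%.3f", x$mean_nmi), "\n")
  print(dplyr::select(x$types, "type_id", "n_bins", "modal_ici_s"))
  invisible(x)
}

#' Match discovered type clusters to known templates
#'
#' Assigns each type cluster to the click-type template whose idealized
#' spectrum (see [template_spectrum()]) is nearest in correlation
#' distance, or `"unassigned"` when the nearest distance exceeds the
#' ceiling. This programmatic matching stands in for the manual grouping
#' of clusters into named types that a human analyst would perform.
#'
#' @param types A `click_types` object or its `types` tibble.
#' @param templates List of [click_template] objects.
#' @param distance_ceiling Maximum correlation distance for a match.
#' @return Tibble: `type_id`, `template`, `distance`.
#' @export
match_templates <- function(types, templates, distance_ceiling = 0.5) {
  tb <- if (inherits(types, "click_types")) types$types else types
  if (!length(templates)) {
    return(tibble::tibble(type_id = tb$type_id, template = "unassigned",
                          distance = NA_real_))
  }
  ref <- do.call(rbind, purrr::map(templates, template_spectrum))
  purrr::map(seq_len(nrow(tb)), function(i) {
    d <- apply(ref, 1, function(r) correlation_distance(r, tb$mean_spectrum[[i]]))
    j <- which.min(d)
    tibble::tibble(
      type_id = tb$type_id[i],
      template = if (d[j] <= distance_ceiling) {
        unname(vapply(templates, `[[`, "", "name"))[j]
      } else {
        "unassigned"
      },
      distance = d[j]
    )
  }) |>
    dplyr::bind_rows()
}
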