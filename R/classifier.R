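#' Network and training-set configuration
#'
#' The bin classifier is a feed-forward network: an input layer over the
#' 341-point feature vector (181 spectrum + 60 ICI + 100 envelope), four
#' 512-node fully connected hidden layers with 50% dropout between each,
#' and a softmax output over the classes. Training minimizes
#' cross-entropy with an adaptive-moment optimizer; the epoch with the
#' best validation loss is retained. Each class contributes a fixed
#' number of examples (random subsample when more are available,
#' noise-augmented copies when fewer), split 70/20/10 into
#' train/test/validation with augmented examples confined to training.
#'
#' @param hidden_layers Integer vector of hidden-layer widths.
#' @param dropout Dropout probability between hidden layers, in \[0, 1).
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); `Inf` disables early stopping.
#' @param examples_per_class Examples per class after balancing.
#' @param split Percent train/test/validation; must sum to 100.
#' @param augment_noise_sd Gaussian noise sd (fraction of the normalized
#'   range) for spectrum/envelope augmentation.
#' @param seed Integer seed for balancing, splitting and training.
#' @return A list of class `network_config`.
#' @export
network_config <- function(hidden_layers = c(512, 512, 512, 512), dropout = 0.5,
                           epochs = 50, batch_size = 128, learning_rate = 1e-3,
                           patience = 10, examples_per_class = 5000,
                           split = c(70, 20, 10), augment_noise_sd = 0.05,
                           seed = 1) {
  if (sum(split) != 100) stopf("split must sum to 100, got %s", sum(split))
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  structure(
    list(hidden_layers = hidden_layers, dropout = dropout, epochs = epochs,
         batch_size = batch_size, learning_rate = learning_rate,
         patience = patience, examples_per_class = examples_per_class,
         split = split, augment_noise_sd = augment_noise_sd,
         seed = as.integer(seed)),
    class = "network_config"
  )
}

#' Assemble the 341-point feature matrix of a bin table
#'
#' Concatenates each row's mean spectrum (181), ICI distribution (60) and
#' mean envelope (100) into the fixed feature layout the network trains
#' on.
#'
#' @param bins Tibble with list-columns `mean_spectrum`, `ici_hist`,
#'   `mean_envelope`.
#' @return Numeric matrix, one row per bin.
#' @export
bin_features_matrix <- function(bins) {
  t(vapply(seq_len(nrow(bins)), function(i) {
    c(as.numeric(bins$mean_spectrum[[i]]), as.numeric(bins$ici_hist[[i]]),
      as.numeric(bins$mean_envelope[[i]]))
  }, numeric(181 + 60 + n_envelope_points())))
}

feature_segments <- function() {
  list(spectrum = 1:181, ici = 182:241, envelope = 242:341)
}

#' Augment one example's spectrum and envelope with Gaussian noise
#'
#' Adds i.i.d. low-amplitude Gaussian noise to the spectrum and envelope
#' segments of a bin-feature row, then restores the segment conventions
#' (spectrum min-max to \[0, 1\]; envelope clipped at 0 and
#' max-normalized). The class label is preserved and the `augmented`
#' flag set.
#'
#' @param example One-row tibble with `mean_spectrum` and `mean_envelope`
#'   list-columns.
#' @param noise_sd Noise standard deviation as a fraction of the
#'   normalized range; 0 returns the input unchanged (flag still set).
#' @return One-row tibble.
#' @export
augment_spectrum_envelope <- function(example, noise_sd = 0.05) {
  out <- example
  if (noise_sd > 0) {
    s <- example$mean_spectrum[[1]] + stats::rnorm(181, 0, noise_sd)
    e <- pmax(0, example$mean_envelope[[1]] +
                stats::rnorm(n_envelope_points(), 0, noise_sd))
    out$mean_spectrum <- list(normalize_spectrum(s))
    out$mean_envelope <- list(e / max(e))
  }
  out$augmented <- TRUE
  out
}

#' Augment one example's ICI distribution from the class pool
#'
#' Perturbs the ICI histogram by adding pseudo-counts resampled from the
#' class's pooled empirical ICI distribution, then re-normalizes to sum
#' one. With an empty pool the input is returned unchanged with a
#' warning.
#'
#' @param example One-row tibble with an `ici_hist` list-column.
#' @param class_ici_pool Probability vector over the same ICI bins
#'   (typically the mean histogram of the class).
#' @param perturb_frac Fraction of the histogram mass replaced by
#'   resampled counts; 0 is the identity.
#' @param n_counts Notional click count behind the resampling.
#' @return One-row tibble.
#' @export
augment_ici <- function(example, class_ici_pool, perturb_frac = 0.2,
                        n_counts = 100) {
  out <- example
  out$augmented <- TRUE
  if (is.null(class_ici_pool) || !length(class_ici_pool) ||
      sum(class_ici_pool) == 0) {
    warnf("augment_ici: empty class pool; example copied unmodified")
    return(out)
  }
  if (perturb_frac <= 0) return(out)
  h <- example$ici_hist[[1]]
  add <- as.numeric(stats::rmultinom(1, size = max(1, round(perturb_frac * n_counts)),
                                     prob = class_ici_pool))
  mixed <- h * (1 - perturb_frac) * n_counts + add
  if (sum(mixed) > 0) mixed <- mixed / sum(mixed)
  out$ici_hist <- list(mixed)
  out
}

#' Build balanced train/test/validation sets
#'
#' Balances every class to `examples_per_class` rows -- a random
#' subsample when more are available, augmented copies (noise on
#' spectrum/envelope, pool-resampled ICI) when fewer -- and splits
#' 70/20/10 per class. Augmented examples are placed only in the
#' training partition; when a class has too few originals to fill the
#' test and validation quotas, its originals are split 2:1 between them
#' with a warning and training is filled entirely by augmentation.
#'
#' @param labelled_bins Tibble as from [synth_labelled_bins()] (columns
#'   `class_label`, `mean_spectrum`, `ici_hist`, `mean_envelope`).
#' @param config A [network_config].
#' @return List of class `training_set` with tibbles `train`, `test`,
#'   `validation` (each with an `augmented` flag).
#' @export
build_training_set <- function(labelled_bins, config = network_config()) {
  classes <- sort(unique(labelled_bins$class_label))
  counts <- table(labelled_bins$class_label)
  if (any(counts == 0) || !length(classes)) stopf("every class needs >= 1 example")
  target <- config$examples_per_class
  n_test <- round(config$split[2] / 100 * target)
  n_val <- round(config$split[3] / 100 * target)
  n_train <- target - n_test - n_val
  if (!"augmented" %in% names(labelled_bins)) labelled_bins$augmented <- FALSE
  parts <- with_seed(derive_seed(config$seed, 31), {
    purrr::map(classes, function(cls) {
      pool <- labelled_bins[labelled_bins$class_label == cls, ]
      pool <- pool[sample.int(nrow(pool)), ]
      if (nrow(pool) >= target) pool <- pool[seq_len(target), ]
      n_orig <- nrow(pool)
      if (n_orig >= n_test + n_val) {
        test <- pool[seq_len(n_test), ]
        val <- pool[n_test + seq_len(n_val), ]
        train <- pool[-(seq_len(n_test + n_val)), ]
      } else {
        warnf("class '%s': only %d originals; test/validation reduced", cls, n_orig)
        k <- floor(n_orig * 2 / 3)
        test <- pool[seq_len(k), ]
        val <- pool[k + seq_len(n_orig - k), ]
        train <- pool[0, ]
      }
      n_aug <- n_train - nrow(train)
      if (n_aug > 0) {
        ici_pool <- colMeans(do.call(rbind, pool$ici_hist))
        src_idx <- sample.int(nrow(pool), n_aug, replace = TRUE)
        aug <- purrr::map(src_idx, function(i) {
          ex <- augment_spectrum_envelope(pool[i, ], config$augment_noise_sd)
          augment_ici(ex, ici_pool)
        })
        train <- dplyr::bind_rows(train, dplyr::bind_rows(aug))
      }
      list(train = train, test = test, validation = val)
    })
  })
  out <- list(
    train = dplyr::bind_rows(purrr::map(parts, "train")),
    test = dplyr::bind_rows(purrr::map(parts, "test")),
    validation = dplyr::bind_rows(purrr::map(parts, "validation"))
  )
  structure(out, class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set>",
      sprintf("train %d (%d augmented), test %d, validation %d\n",
              nrow(x$train), sum(x$train$augmented), nrow(x$test),
              nrow(x$validation)))
  invisible(x)
}

#' Train the feed-forward bin classifier
#'
#' Trains the network described in [network_config()] on 341-point bin
#' feature vectors: ReLU hidden layers with inverted dropout, softmax
#' output, cross-entropy loss, Adam updates, per-epoch validation, and
#' retention of the best-validation-epoch weights.
#'
#' @param train,validation Tibbles with feature list-columns and
#'   `class_label` (e.g. the partitions of [build_training_set()]).
#' @param config A [network_config].
#' @param quiet Suppress per-epoch progress.
#' @return A `click_net` object: weights, class levels, config and a
#'   per-epoch training history.
#' @export
train_click_net <- function(train, validation = NULL, config = network_config(),
                            quiet = TRUE) {
  X <- bin_features_matrix(train)
  if (!all(is.finite(X))) stopf("non-finite training features")
  classes <- sort(unique(train$class_label))
  if (length(classes) < 2) stopf("need >= 2 classes")
  y <- match(train$class_label, classes)
  Y <- diag(length(classes))[y, , drop = FALSE]
  has_val <- !is.null(validation) && nrow(validation) > 0
  if (has_val) {
    Xv <- bin_features_matrix(validation)
    yv <- match(validation$class_label, classes)
    if (anyNA(yv)) stopf("validation contains labels unseen in training")
  }
  dims <- c(ncol(X), config$hidden_layers, length(classes))
  L <- length(dims) - 1
  state <- with_seed(derive_seed(config$seed, 47), {
    W <- purrr::map(seq_len(L), function(l) {
      matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
             dims[l], dims[l + 1])
    })
    b <- purrr::map(seq_len(L), function(l) numeric(dims[l + 1]))
    mW <- purrr::map(W, function(w) w * 0); vW <- mW
    mb <- purrr::map(b, function(x) x * 0); vb <- mb
    history <- list()
    best <- list(loss = Inf, W = W, b = b, epoch = 0L)
    t_adam <- 0
    n <- nrow(X)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    p_drop <- config$dropout
    stall <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        Xb <- X[bt, , drop = FALSE]
        Yb <- Y[bt, , drop = FALSE]
        m <- nrow(Xb)
        A <- vector("list", L + 1)
        masks <- vector("list", L)
        A[[1]] <- Xb
        for (l in seq_len(L)) {
          Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], `+`)
          if (l < L + 0.5 && l <= L - 1) {
            H <- pmax(Z, 0)
            if (p_drop > 0) {
              mask <- matrix(stats::runif(length(H)) >= p_drop, nrow(H)) / (1 - p_drop)
              H <- H * mask
              masks[[l]] <- mask
            }
            A[[l + 1]] <- H
          } else {
            A[[l + 1]] <- Z  # logits
          }
        }
        logits <- A[[L + 1]]
        mx <- apply(logits, 1, max)
        ex <- exp(logits - mx)
        P <- ex / rowSums(ex)
        ep_loss <- ep_loss - sum(log(pmax(P[cbind(seq_len(m), max.col(Yb))], 1e-12)))
        delta <- (P - Yb) / m
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(W[[l]])
            delta <- delta * (A[[l]] > 0)
            if (p_drop > 0 && !is.null(masks[[l - 1]])) delta <- delta * masks[[l - 1]]
          }
          t_adam <- t_adam + ifelse(l == L, 1, 0)
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          bc1 <- 1 - beta1^t_adam
          bc2 <- 1 - beta2^t_adam
          W[[l]] <- W[[l]] - lr * (mW[[l]] / bc1) / (sqrt(vW[[l]] / bc2) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / bc1) / (sqrt(vb[[l]] / bc2) + eps)
        }
      }
      train_eval <- mlp_eval(W, b, X, y)
      val_eval <- if (has_val) mlp_eval(W, b, Xv, yv) else list(loss = NA, acc = NA)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_eval$loss, train_acc = train_eval$acc,
        val_loss = val_eval$loss, val_acc = val_eval$acc
      )
      monitor <- if (has_val) val_eval$loss else train_eval$loss
      if (monitor < best$loss - 1e-6) {
        best <- list(loss = monitor, W = W, b = b, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (!quiet) {
        message(sprintf("epoch %3d  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
                        epoch, train_eval$loss, train_eval$acc,
                        val_eval$loss, val_eval$acc))
      }
      if (stall >= config$patience) break
    }
    list(W = best$W, b = best$b, best_epoch = best$epoch,
         history = dplyr::bind_rows(history))
  })
  structure(
    list(weights = state$W, biases = state$b, classes = classes,
         config = config, history = state$history,
         best_epoch = state$best_epoch, n_features = ncol(X)),
    class = "click_net"
  )
}

mlp_logits <- function(W, b, X) {
  L <- length(W)
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% W[[l]], 2, b[[l]], `+`)
    A <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

softmax_rows <- function(Z) {
  mx <- apply(Z, 1, max)
  ex <- exp(Z - mx)
  ex / rowSums(ex)
}

mlp_eval <- function(W, b, X, y) {
  P <- softmax_rows(mlp_logits(W, b, X))
  loss <- -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-12)))
  list(loss = loss, acc = mean(max.col(P) == y))
}

#' Predict class probabilities for new bins
#'
#' @param object A `click_net`.
#' @param newdata Feature matrix (341 columns) or a bin tibble with the
#'   feature list-columns.
#' @param ... Unused.
#' @return Matrix of class probabilities (rows sum to 1), columns named
#'   by class.
#' @export
predict.click_net <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else bin_features_matrix(newdata)
  if (ncol(X) != object$n_features) {
    stopf("feature dimension mismatch: model expects %d, got %d",
          object$n_features, ncol(X))
  }
  P <- softmax_rows(mlp_logits(object$weights, object$biases, X))
  colnames(P) <- object$classes
  P
}

#' Label bin clusters with the trained network
#'
#' Every bin cluster receives the argmax class and the maximum softmax
#' probability as its confidence; no abstention.
#'
#' @param model A `click_net`.
#' @param bin_clusters Tibble with the feature list-columns (e.g. from
#'   [cluster_bins()]).
#' @return The input tibble with `label` and `confidence` columns added.
#' @export
classify_bins <- function(model, bin_clusters) {
  if (!nrow(bin_clusters)) {
    return(dplyr::mutate(bin_clusters, label = character(0), confidence = numeric(0)))
  }
  P <- predict(model, bin_clusters)
  dplyr::mutate(bin_clusters,
                label = model$classes[max.col(P)],
                confidence = apply(P, 1, max))
}

#' @export
print.click_net <- function(x, ...) {
  cat("<click_net>", paste(c(x$n_features, x$config$hidden_layers,
                             length(x$classes)), collapse = "-"),
      sprintf("(dropout %.0f%%), %d classes, best epoch %d\n",
              100 * x$config$dropout, length(x$classes), x$best_epoch))
  invisible(x)
}

#' Tidy the training history of a fitted network
#'
#' @param x A `click_net`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: losses and accuracies.
#' @exportS3Method generics::tidy
tidy.click_net <- function(x, ...) x$history

#' One-row summary of a fitted network
#'
#' @param x A `click_net`.
#' @param ... Unused.
#' @return Tibble: classes, parameter count, epochs run, best epoch and
#'   the best validation loss/accuracy.
#' @exportS3Method generics::glance
glance.click_net <- function(x, ...) {
  n_par <- sum(vapply(x$weights, length, 0)) + sum(vapply(x$biases, length, 0))
  best <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(
    n_classes = length(x$classes), n_parameters = n_par,
    epochs_run = nrow(x$history), best_epoch = x$best_epoch,
    val_loss = best$val_loss, val_acc = best$val_acc
  )
}

#' Serialize a fitted network to text
#'
#' Writes the weights and a JSON sidecar (feature layout, classes,
#' config, seed) so models are portable without binary files.
#'
#' @param model A `click_net`.
#' @param path Base path; `<path>.json` (sidecar) and `<path>_weights.json`
#'   are written.
#' @return `read_click_net()` returns the restored `click_net`.
#' @export
write_click_net <- function(model, path) {
  sidecar <- list(
    classes = model$classes, n_features = model$n_features,
    feature_layout = purrr::map(feature_segments(), range),
    best_epoch = model$best_epoch,
    config = model$config[c("hidden_layers", "dropout", "epochs", "batch_size",
                            "learning_rate", "patience", "examples_per_class",
                            "split", "augment_noise_sd", "seed")]
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  jsonlite::write_json(
    list(weights = purrr::map(model$weights, as.data.frame),
         biases = model$biases),
    paste0(path, "_weights.json"), digits = NA)
  invisible(path)
}

#' @rdname write_click_net
#' @export
read_click_net <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  wts <- jsonlite::read_json(paste0(path, "_weights.json"), simplifyVector = TRUE)
  cfg <- do.call(network_config, sidecar$config)
  structure(
    list(weights = purrr::map(wts$weights, as.matrix),
         biases = purrr::map(wts$biases, as.numeric),
         classes = sidecar$classes, config = cfg,
         history = tibble::tibble(), best_epoch = sidecar$best_epoch,
         n_features = sidecar$n_features),
    class = "click_net"
  )
}
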