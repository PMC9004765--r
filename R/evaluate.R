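#' Build a confusion matrix of bin labels
#'
#' Cell (i, j) counts bins whose true class is i and predicted class j.
#' The "noise"/"junk" outgroup participates as an ordinary class.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_order Ordered class labels; any label outside it is an
#'   error.
#' @return A `click_confusion` object (an integer matrix with class
#'   dimnames).
#' @examples
#' cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
#' tidy(cm)
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_order) {
  if (length(true_labels) != length(predicted_labels)) {
    stopf("label vectors must have equal length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(bad)) stopf("labels outside class_order: %s", paste(bad, collapse = ", "))
  tl <- factor(true_labels, levels = class_order)
  pl <- factor(predicted_labels, levels = class_order)
  m <- unclass(table(tl, pl))
  dimnames(m) <- list(true = class_order, predicted = class_order)
  as_click_confusion(m)
}

#' Coerce a square count matrix to a `click_confusion`
#'
#' @param m Square numeric matrix with identical row/column names.
#' @return A `click_confusion`.
#' @export
as_click_confusion <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stopf("confusion matrix must be square")
  if (any(m < 0) || any(m != round(m))) stopf("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  structure(m, class = c("click_confusion", "matrix", "array"))
}

#' @export
print.click_confusion <- function(x, ...) {
  cat("<click_confusion>", nrow(x), "classes,", sum(x), "bins\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class performance metrics from a confusion matrix
#'
#' For class k: TP is the diagonal cell, FN the rest of row k, FP the
#' rest of column k, TN everything else. Accuracy is
#' `(TP + TN) / total`, recall `TP / (TP + FN)`, precision
#' `TP / (TP + FP)`, specificity `TN / (TN + FP)` and the
#' misclassification rate `1 - accuracy`. Ratios with a zero denominator
#' are reported as `NA`, never 0.
#'
#' @param matrix A `click_confusion`.
#' @param class_k Class label, must be present in the matrix.
#' @return One-row tibble: `class`, `n_bins` (row total), `tp`, `fn`,
#'   `fp`, `tn`, `accuracy`, `recall`, `precision`, `specificity`,
#'   `misclassification_rate`.
#' @export
class_metrics <- function(matrix, class_k) {
  if (!class_k %in% rownames(matrix)) stopf("class '%s' not in matrix", class_k)
  total <- sum(matrix)
  tp <- matrix[class_k, class_k]
  fn <- sum(matrix[class_k, ]) - tp
  fp <- sum(matrix[, class_k]) - tp
  tn <- total - tp - fn - fp
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- ratio(tp + tn, total)
  tibble::tibble(
    class = class_k, n_bins = tp + fn,
    tp = tp, fn = fn, fp = fp, tn = tn,
    accuracy = acc,
    recall = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp),
    specificity = ratio(tn, tn + fp),
    misclassification_rate = if (is.na(acc)) NA_real_ else 1 - acc
  )
}

#' Tidy a confusion matrix into per-class metrics
#'
#' @param x A `click_confusion`.
#' @param ... Unused.
#' @return Tibble with one [class_metrics()] row per class.
#' @exportS3Method generics::tidy
tidy.click_confusion <- function(x, ...) {
  dplyr::bind_rows(purrr::map(rownames(x), class_metrics, matrix = x))
}

#' One-row summary of a confusion matrix
#'
#' @param x A `click_confusion`.
#' @param ... Unused.
#' @return Tibble: total bins, classes, overall accuracy (trace / total).
#' @exportS3Method generics::glance
glance.click_confusion <- function(x, ...) {
  tibble::tibble(n_bins = sum(x), n_classes = nrow(x),
                 overall_accuracy = sum(diag(x)) / sum(x))
}

#' Sum confusion matrices across sites
#'
#' Element-wise sum; all matrices must share the same class order.
#'
#' @param matrices List of `click_confusion` objects.
#' @return A `click_confusion`.
#' @export
combine_matrices <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ref <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), ref) || !identical(colnames(m), ref)) {
      stopf("matrices have mismatched class sets")
    }
  }
  as_click_confusion(Reduce(`+`, purrr::map(matrices, unclass)))
}

#' Received-level evaluation filter
#'
#' Keeps only bins whose loudest click exceeds the evaluation floor
#' (strictly above), the restriction used when scoring the classifier so
#' that differing hydrophone sensitivities do not bias the comparison.
#'
#' @param bins Tibble with an `rl_max_dbpp` column.
#' @param min_rl_dbpp Threshold in dBpp re 1 uPa.
#' @return Filtered tibble.
#' @export
rl_evaluation_filter <- function(bins, min_rl_dbpp = 125) {
  dplyr::filter(bins, .data$rl_max_dbpp > min_rl_dbpp)
}

#' Relative acoustic presence per deployment
#'
#' For each deployment and class: the percentage of recording days on
#' which at least one bin carries that class's label. Deployments with
#' zero recording days are excluded with a warning.
#'
#' @param labelled_bins Tibble with columns `deployment`, `day` (any
#'   day identifier, e.g. a `Date`) and `label`.
#' @param deployment_calendar Tibble with columns `deployment`, `site`,
#'   `recording_days`.
#' @param classes Classes to report; defaults to those present.
#' @return Tibble: `site`, `deployment`, `class`, `percent_days`.
#' @seealso [site_presence()] for the across-deployment site average.
#' @export
relative_presence <- function(labelled_bins, deployment_calendar, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(labelled_bins$label))
  bad <- deployment_calendar$recording_days <= 0
  if (any(bad)) {
    warnf("excluding %d deployment(s) with zero recording days", sum(bad))
    deployment_calendar <- deployment_calendar[!bad, ]
  }
  days_present <- labelled_bins |>
    dplyr::distinct(.data$deployment, .data$label, .data$day) |>
    dplyr::count(.data$deployment, .data$label, name = "n_days")
  tidyr::crossing(
    deployment_calendar[c("site", "deployment", "recording_days")],
    class = classes
  ) |>
    dplyr::left_join(days_present,
                     by = c(deployment = "deployment", class = "label")) |>
    dplyr::mutate(n_days = dplyr::coalesce(.data$n_days, 0L),
                  percent_days = 100 * .data$n_days / .data$recording_days) |>
    dplyr::select("site", "deployment", "class", "percent_days")
}

#' Site-level relative acoustic presence
#'
#' Unweighted mean of the per-deployment presence percentages at each
#' site.
#'
#' @param presence Tibble from [relative_presence()].
#' @return Tibble: `site`, `class`, `percent_days`.
#' @export
site_presence <- function(presence) {
  presence |>
    dplyr::group_by(.data$site, .data$class) |>
    dplyr::summarise(percent_days = mean(.data$percent_days), .groups = "drop")
}

#' Published Hawaiian evaluation data
#'
#' `hawaii_confusion_matrices()` loads the three published site-level
#' confusion matrices (Kona, Pearl and Hermes Reef, Kauai) of 5-minute
#' bins labelled by the final network versus manual labels, shipped with
#' the package as CSV. `hawaii_reported_metrics()` loads the published
#' per-class recall and precision table for the same evaluation (values
#' in percent, one decimal; `NA` where a class was absent from a site's
#' manual labels).
#'
#' @return A named list of `click_confusion` objects, or a tibble.
#' @examples
#' cms <- hawaii_confusion_matrices()
#' class_metrics(cms$kona, "False killer whale")[, c("recall", "precision")]
#' @export
hawaii_confusion_matrices <- function() {
  files <- c(kona = "confusion_kona.csv", phr = "confusion_phr.csv",
             kauai = "confusion_kauai.csv")
  purrr::map(files, function(f) {
    path <- system.file("extdata", f, package = "echoclick", mustWork = TRUE)
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
    as_click_confusion(m)
  })
}

#' @rdname hawaii_confusion_matrices
#' @export
hawaii_reported_metrics <- function() {
  path <- system.file("extdata", "reported_metrics.csv", package = "echoclick",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
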