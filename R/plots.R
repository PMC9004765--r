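#' Plot the mean spectra of discovered click types
#'
#' @param object A `click_types` object from [cluster_types()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.click_types <- function(object, ...) {
  df <- object$types |>
    dplyr::mutate(spectrum = purrr::map(.data$mean_spectrum, function(s) {
      tibble::tibble(freq_khz = click_freq_grid(), level = as.numeric(s))
    })) |>
    dplyr::select("type_id", "n_bins", "spectrum") |>
    tidyr::unnest("spectrum")
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_khz, .data$level)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$type_id), labeller = "label_both") +
    ggplot2::labs(x = "Frequency (kHz)", y = "Normalized level",
                  title = "Mean normalized spectra of type clusters")
}

#' Heatmap of a confusion matrix
#'
#' @param object A `click_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.click_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = "Network label", y = "True class", fill = "Bins")
}

#' Training history of a fitted network
#'
#' @param object A `click_net`.
#' @param ... Unused.
#' @return A ggplot of loss per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.click_net <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            dplyr::any_of(c("train_loss", "val_loss")),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy loss", colour = NULL)
}

#' Relative acoustic presence per site and class
#'
#' @param presence Tibble from [relative_presence()].
#' @return A ggplot of per-deployment presence with site means.
#' @export
plot_presence <- function(presence) {
  ggplot2::ggplot(presence,
                  ggplot2::aes(.data$class, .data$percent_days)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$deployment), alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$site)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "% of recording days with presence")
}
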