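# ggplot2 displays for the main result types.

#' @describeIn phi_screen Tile plot of the Phi association screen.
#' @param object A `phi_matrix`.
#' @param ... Unused.
#' @method autoplot phi_matrix
#' @export
autoplot.phi_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$var2, .data$var1, fill = .data$phi)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$phi))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "phi") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Indicator / lameness association (Phi)") +
    ggplot2::theme_minimal()
}

#' @describeIn confusion_matrix3 Tile plot of the confusion matrix.
#' @param object A `confusion_matrix3`.
#' @param ... Unused.
#' @method autoplot confusion_matrix3
#' @export
autoplot.confusion_matrix3 <- function(object, ...) {
  long <- tibble::as_tibble(as.table(unclass(object))) |>
    dplyr::rename(count = "n")
  ggplot2::ggplot(long, ggplot2::aes(.data$predicted, .data$truth,
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted locomotion score", y = "locomotion score",
                  title = sprintf("Held-out confusion matrix (accuracy %.1f%%)",
                                  100 * accuracy(object))) +
    ggplot2::theme_minimal()
}

#' @describeIn test_metrics Forest plot of the metrics and their intervals.
#' @param object An `ips_test_metrics` tibble.
#' @param ... Unused.
#' @method autoplot ips_test_metrics
#' @export
autoplot.ips_test_metrics <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(metric = factor(.data$metric, levels = rev(c("se", "sp", "ppv", "npv"))))
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = "Diagnostic metrics against the lame reference") +
    ggplot2::theme_minimal()
}

#' @describeIn cross_validate_select Held-out accuracy per fold; the selected
#'   fold is highlighted.
#' @param object An `ips_cv` object.
#' @method autoplot ips_cv
#' @export
autoplot.ips_cv <- function(object, ...) {
  d <- dplyr::mutate(object$results, selected = .data$fold == object$best_fold)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$fold), .data$accuracy,
                                  fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "steelblue")) +
    ggplot2::labs(x = "fold", y = "held-out accuracy",
                  title = "Cross-validated tree selection") +
    ggplot2::theme_minimal()
}

#' Forest plot of the composite diagnostics table
#'
#' Sensitivity and specificity (with intervals) for each single indicator and
#' composite threshold, as produced by [composite_diagnostics()].
#'
#' @param diagnostics The tibble returned by [composite_diagnostics()].
#' @return A ggplot object.
#' @export
plot_diagnostics <- function(diagnostics) {
  d <- dplyr::filter(diagnostics, .data$metric %in% c("se", "sp")) |>
    dplyr::mutate(test = factor(.data$test, levels = rev(unique(.data$test))),
                  metric = dplyr::recode(.data$metric, se = "sensitivity",
                                         sp = "specificity"))
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$test)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = "Screening performance against LS >= 2") +
    ggplot2::theme_minimal()
}
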