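#' Bubble plot of mortality against the maternal severity score
#'
#' Visualizes the score-mortality gradient: one bubble per score category,
#' sized by the number of cases, with Wilson interval whiskers.
#'
#' @param table A table from [score_mortality_table()].
#' @return A ggplot object.
#' @export
plot_score_mortality <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$score_value,
                                      y = .data$mortality)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.2, colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7,
                        colour = "#2c5f8a") +
    ggplot2::scale_size_area(max_size = 12, name = "Cases") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Maternal severity score (number of markers)",
                  y = "Mortality",
                  title = "Mortality rises with the number of life-threatening conditions") +
    ggplot2::theme_minimal()
}

#' ROC curve of a fitted MSI-style model
#'
#' @param object An `msi_fit`.
#' @param ... Unused.
#' @return A ggplot object with the empirical ROC curve and the AUROC in the
#'   subtitle.
#' @method autoplot msi_fit
#' @export
autoplot.msi_fit <- function(object, ...) {
  y <- object$y
  p <- object$fitted
  thr <- sort(unique(p), decreasing = TRUE)
  pts <- purrr::map_dfr(c(Inf, thr, -Inf), function(t) {
    tibble::tibble(fpr = mean(p[y == 0] >= t), tpr = mean(p[y == 1] >= t))
  })
  a <- auroc(y, p)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "Death-prediction ROC curve",
                  subtitle = sprintf("AUROC %.3f (%.0f%% CI %.3f-%.3f)",
                                     a$point, 100 * a$level, a$lo, a$hi)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed/expected mortality by stratum
#'
#' @param report A [benchmark_cohort()] report.
#' @return A ggplot object: O/E point and interval per stratum, with the
#'   reference line at 1.
#' @export
plot_benchmark <- function(report) {
  df <- report[report$stratum != "(pooled)", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$oe)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$oe_lo,
                                          ymax = .data$oe_hi)) +
    ggplot2::labs(x = NULL, y = "Observed / expected deaths",
                  title = "Mortality benchmark against the MSI reference") +
    ggplot2::theme_minimal()
}
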