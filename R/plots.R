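## ggplot2 graphics for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_vline
#'   geom_hline geom_abline geom_col scale_x_log10 labs theme_bw
NULL

#' Plot FDR and FNR curves with the detection threshold
#'
#' @param object An `sae_threshold` from [threshold_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sae_threshold
#' @export
autoplot.sae_threshold <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curves, c("fdr", "fnr"),
                           names_to = "curve", values_to = "rate")
  ggplot(d, aes(x = .data$level, y = .data$rate,
                colour = toupper(.data$curve))) +
    geom_line() + geom_point(size = 1) +
    geom_vline(xintercept = object$threshold, linetype = 2) +
    scale_x_log10() +
    labs(x = "Expression level (RPKM)", y = "Rate", colour = NULL,
         title = sprintf("Detection threshold: %.3g RPKM [%s]",
                         object$threshold, object$flag)) +
    theme_bw()
}

#' Modified volcano plot: absolute change versus -log10 p
#'
#' @param object An `sae_differential` from [smoking_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sae_differential
#' @export
autoplot.sae_differential <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$delta, y = .data$neg_log10_p,
             colour = .data$responsive)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_hline(yintercept = -log10(attr(object, "alpha")), linetype = 2) +
    labs(x = "Absolute change (RPKM, smoker - nonsmoker)",
         y = expression(-log[10] ~ p), colour = "responsive") +
    theme_bw()
}

#' Q-Q plot of junction-usage test p values
#'
#' @param x An `sae_junction_test` from [junction_test()].
#' @return A ggplot with the identity diagonal.
#' @export
plot_junction_qq <- function(x) {
  ggplot(x$qq, aes(x = .data$expected, y = .data$observed)) +
    geom_point(size = 1) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = expression(Expected ~ -log[10] ~ p),
         y = expression(Observed ~ -log[10] ~ p),
         title = sprintf("Inflation factor %.2f", x$inflation)) +
    theme_bw()
}

#' Half-log expression histogram
#'
#' @param histogram A tibble from [halflog_histogram()].
#' @return A ggplot of gene counts per half-log bin.
#' @export
plot_halflog <- function(histogram) {
  ggplot(histogram, aes(x = sqrt(.data$lower * .data$upper),
                        y = .data$count)) +
    geom_col(width = 0.4) +
    scale_x_log10() +
    labs(x = "Median expression (RPKM, half-log10 bins)",
         y = "Number of genes") +
    theme_bw()
}

#' Cumulative expression curves for cell-type gene sets
#'
#' @param curves A tibble combining [celltype_cumulative()] outputs with a
#'   `set` column naming each gene set.
#' @return A ggplot of cumulative frequency against expression level.
#' @export
plot_celltype_cumulative <- function(curves) {
  ggplot(curves, aes(x = .data$level, y = .data$cum_freq,
                     colour = .data$set)) +
    geom_line() +
    scale_x_log10() +
    labs(x = "Expression level (RPKM)", y = "Cumulative frequency",
         colour = NULL) +
    theme_bw()
}
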