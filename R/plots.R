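# ggplot2 views of the result objects.

#' Bar diagram of the ChoOSyn parameters
#'
#' @param object A `choosyn_profile`.
#' @param ... Unused.
#' @return A ggplot: ChoOSynW and ChoOSynC bars per candidate order.
#' @export
autoplot.choosyn_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(object$profile[, c("n", "choosyn_w", "choosyn_c")],
                            -"n", names_to = "parameter", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~parameter, ncol = 1) +
    ggplot2::labs(x = "number of synergies", y = "parameter value") +
    ggplot2::theme_minimal()
}

#' VAF curve with optional selection annotations
#'
#' @param object A `vaf_curve`.
#' @param threshold Optional horizontal threshold line (percent).
#' @param ... Unused.
#' @return A ggplot of VAF (percent) against the number of synergies.
#' @export
autoplot.vaf_curve <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$n, y = .data$vaf)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "number of synergies", y = "VAF (%)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Benchmark report as a grouped bar chart
#'
#' @param object A `synergy_benchmark`.
#' @param ... Unused.
#' @return A ggplot of the fraction correct per method and condition.
#' @export
autoplot.synergy_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$condition,
                               y = .data$fraction_correct,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "noise condition", y = "fraction correct",
                  fill = "criterion") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
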