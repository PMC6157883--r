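#' Diagnostic plot of a UMI correction fit
#'
#' Observed reads-per-UMI distribution (bars; grey below the threshold,
#' where phantoms accumulate) against the fitted model prediction (points),
#' scaled to the number of surviving UMIs. A good fit shows bars matching
#' points at and above the threshold; over-abundant grey bars below it are
#' the signature of phantom UMIs being filtered out.
#'
#' @param object A [umi_correct()] result.
#' @param k_max Largest read count displayed (default: 99th percentile of
#'   the observed counts).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.umi_fit <- function(object, k_max = NULL, ...) {
  d <- object$diagnostics
  if (is.null(k_max)) {
    k_max <- max(object$threshold + 1, stats::quantile(
      rep(d$k, d$observed), 0.99,
      names = FALSE
    ))
  }
  d <- dplyr::filter(d, .data$k <= k_max)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(
      ggplot2::aes(y = .data$observed, fill = .data$below_threshold),
      width = 0.8, show.legend = FALSE
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$predicted)) +
    ggplot2::geom_vline(
      xintercept = object$threshold - 0.5,
      linetype = "dashed"
    ) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey70", `FALSE` = "grey25")) +
    ggplot2::labs(
      x = "reads per UMI", y = "UMIs",
      title = sprintf(
        "Observed vs predicted reads per UMI (E = %.2f, D = %.2f, loss = %.1f%%)",
        object$summary$efficiency, object$summary$depth,
        100 * object$summary$loss
      )
    ) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of a threshold scan
#'
#' One observed-versus-predicted reads-per-UMI panel per candidate
#' threshold, supporting the usual manual choice: the lowest threshold whose
#' surviving distribution matches the model.
#'
#' @param object A [threshold_scan()] result.
#' @param k_max Largest read count displayed.
#' @param ... Unused.
#' @return A ggplot object faceted by candidate threshold.
#' @export
autoplot.umi_threshold_scan <- function(object, k_max = NULL, ...) {
  d <- object$histograms
  if (is.null(k_max)) {
    k_max <- stats::quantile(rep(d$k, d$observed), 0.99, names = FALSE)
  }
  d <- dplyr::filter(d, .data$k <= k_max)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(
      ggplot2::aes(y = .data$observed, fill = .data$below_threshold),
      width = 0.8, show.legend = FALSE
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$predicted), size = 0.8) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey70", `FALSE` = "grey25")) +
    ggplot2::facet_wrap(~threshold, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "reads per UMI", y = "UMIs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
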