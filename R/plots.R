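#' Volcano plot of pool summaries
#'
#' Percent of control (log scale) against -log10 p-value, with hit pools
#' (per the supplied thresholds) highlighted, mirroring the classic screen
#' volcano figure.
#'
#' @param object A `wnt_volcano` or `wnt_pool_summary` tibble.
#' @param thresholds A [hit_thresholds()] used to color hits and draw the
#'   cutoff guides.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wnt_volcano <- function(object, thresholds = hit_thresholds(), ...) {
  d <- classify_pools(object, thresholds)
  f <- thresholds$fold_threshold
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$percent_of_control, y = -log10(.data$p_value),
    colour = .data$pool_call
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(100 / f, 100 * f), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(thresholds$alpha), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(
      hit_up = "#d55e00", hit_down = "#0072b2", non_hit = "grey60"
    )) +
    ggplot2::labs(x = "median effect (% of control)", y = expression(-log[10]~p),
                  colour = NULL)
}

#' @rdname autoplot.wnt_volcano
#' @export
autoplot.wnt_pool_summary <- function(object, thresholds = hit_thresholds(), ...) {
  autoplot.wnt_volcano(build_volcano_table(object), thresholds = thresholds, ...)
}

#' Bar chart of three-set overlap regions
#'
#' @param object A [venn3()] result.
#' @param ... Unused.
#' @return A ggplot object showing the seven exclusive region sizes.
#' @export
autoplot.wnt_venn <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(.data$kind == "exclusive")
  d$region <- factor(d$region, levels = d$region)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$size)) +
    ggplot2::geom_col(fill = "#0072b2") +
    ggplot2::geom_text(ggplot2::aes(label = .data$size), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = sprintf("Overlap of %s",
                                  paste(object$sets$name, collapse = " / ")))
}

#' Column plot of reporter-assay group means with SEM bars
#'
#' @param object A [reporter_stats()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reporter_stats <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$mean_ratio)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_ratio - .data$sem, ymax = .data$mean_ratio + .data$sem
    ), width = 0.15) +
    ggplot2::labs(x = NULL, y = "firefly / Renilla",
                  subtitle = sprintf("p = %.3g (%s)", object$p_value, object$test))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
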