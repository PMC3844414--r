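# ggplot2 views of the main result types. Each takes the tidy series the
# computing function returns, so multiple assemblies can be compared by
# row-binding their series first.

#' Plot NG graph series
#'
#' NG(x) against the integer threshold x for one or more assemblies, with a
#' log-scaled y-axis and a guide line at x = 50 (the NG50).
#'
#' @param df Tibble from [ng_graph()] (bind rows to overlay assemblies).
#' @return A ggplot.
#' @export
plot_ng_graph <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$ng_length,
                                   colour = .data$label)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = 50, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "NG(x) threshold (% of genome size)",
                  y = "NG length (bp)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cumulative length series
#'
#' Cumulative length against rank (longest first) for one or more length
#' sets, the standard cumulative length plot.
#'
#' @param df Tibble from [cumulative_length_series()] or [alignment_clp()].
#' @return A ggplot.
#' @export
plot_clp <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$cumulative,
                                   colour = .data$label)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sequence rank (longest first)",
                  y = "cumulative length (bp)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a z-score ranking with leave-one-out error bars
#'
#' @param df Tibble from [rank_assemblies()] or [loo_bounds()].
#' @return A ggplot.
#' @export
plot_ranking <- function(df) {
  df$assembly <- factor(df$assembly, levels = rev(df$assembly[order(-df$sum_z)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sum_z, y = .data$assembly)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$min_sum,
                                         xmax = .data$max_sum),
                            height = 0.3) +
    ggplot2::labs(x = "summed z-score (error bars: any one metric omitted)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn compass Bar chart of the four validation metrics.
#' @param object A `compass_result`.
#' @method autoplot compass_result
#' @export
autoplot.compass_result <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("coverage", "validity", "multiplicity", "parsimony"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "ratio", title = object$label) +
    ggplot2::theme_minimal()
}

#' @describeIn classify_pairs Bar chart of the tag-mapping categories.
#' @param object A `tag_pair_report`.
#' @method autoplot tag_pair_report
#' @export
autoplot.tag_pair_report <- function(object, ...) {
  df <- tibble(category = factor(c("a", "b", "c", "d", "e"),
                                 levels = c("a", "b", "c", "d", "e")),
               count = c(object$a, object$b, object$c, object$d, object$e))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "tag-mapping category", y = "count",
                  title = sprintf("%s: summary score %.1f of %d",
                                  object$label, object$summary_score,
                                  object$n_pairs)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
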