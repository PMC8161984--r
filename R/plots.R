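#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a bubble forest
#'
#' Bubbles positioned by discovery order and level, segments joining
#' children to parents, points sized by bubble node count and colored by
#' sample membership.
#'
#' @param object a `bubble_tree`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bubble_tree <- function(object, ...) {
  df <- tibble::tibble(order = object$order, level = object$level,
                       color = object$color_str,
                       size = lengths(object$nodes),
                       parent = object$parent)
  seg <- dplyr::filter(df, !is.na(parent))
  seg <- dplyr::mutate(seg,
                       pl = df$level[match(parent, df$order)],
                       po = parent)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = -.data$level)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(xend = .data$po, yend = -.data$pl),
      color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$size,
                                     color = .data$color)) +
    ggplot2::scale_y_continuous(breaks = -seq_len(max(df$level)),
                                labels = seq_len(max(df$level))) +
    ggplot2::labs(x = "discovery order", y = "level", color = "color",
                  size = "nodes", title = "colored superbubble forest") +
    ggplot2::theme_minimal()
}

#' Plot called variants along the reference
#'
#' @param object a `variant_calls` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.variant_calls <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    type = factor(c("substitution", "deletion", "insertion",
                    "unsure")[.data$vartype],
                  levels = c("substitution", "deletion", "insertion",
                             "unsure")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$refpos, y = .data$type,
                                   color = .data$type)) +
    ggplot2::geom_point(alpha = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "reference position", y = NULL,
                  title = "called variants") +
    ggplot2::theme_minimal()
}

#' Plot precision/recall across simulation settings
#'
#' Convenience for parameter sweeps: expects one evaluation row per run
#' with an added column naming the swept parameter value.
#'
#' @param evals tibble of [evaluate_calls()] rows with a `setting` column.
#' @param setting column name of the swept parameter.
#' @return a ggplot.
#' @export
plot_eval_sweep <- function(evals, setting = "setting") {
  df <- tidyr::pivot_longer(evals, c("precision", "recall"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[setting]], y = .data$value,
                                   color = .data$metric)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(y = NULL, title = "variant detection accuracy") +
    ggplot2::theme_minimal()
}
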