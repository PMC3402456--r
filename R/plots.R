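#' Plot the inference chains of a drug
#'
#' Draws each chain as a left-to-right sequence of trigger steps, one
#' chain per row, with the action and target labelled at each step.
#'
#' @param object A `moa_inference` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.moa_inference <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no chains returned") +
             ggplot2::theme_void())
  }
  df$label <- sprintf("%s\n%s", df$action, df$target)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step,
                                   y = factor(.data$chain),
                                   group = .data$chain)) +
    ggplot2::geom_line(arrow = grid::arrow(length = grid::unit(2, "mm"),
                                           type = "closed"),
                       colour = "grey40") +
    ggplot2::geom_label(ggplot2::aes(label = .data$label,
                                     fill = .data$action),
                        size = 3, show.legend = FALSE) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(df$step))) +
    ggplot2::labs(title = sprintf("%s → %s", object$drug,
                                  object$disease_class),
                  x = "trigger step", y = "chain") +
    ggplot2::theme_minimal()
}

#' Plot chain counts across a drug screen
#'
#' @param object A `moa_screen` object.
#' @param ... Unused.
#' @return A ggplot object: chains per drug, coloured by verdict.
#' @export
autoplot.moa_screen <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = stats::reorder(.data$drug, .data$n_chains),
                                  y = .data$n_chains,
                                  fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "treats chains returned",
                  title = sprintf("screen against %s", object$disease_class)) +
    ggplot2::theme_minimal()
}

#' Plot an ablation result
#'
#' @param object A `moa_ablation` object.
#' @param ... Unused.
#' @return A ggplot object: inference counts (and recalls when labels
#'   were supplied) per source subset.
#' @export
autoplot.moa_ablation <- function(object, ...) {
  tb <- tidy(object)
  long <- if ("recall_original_pct" %in% names(tb)) {
    tidyr::pivot_longer(
      select(tb, "sources", "recall_original_pct", "recall_trial_pct",
             "confirmed_pct"),
      -"sources", names_to = "metric", values_to = "value"
    )
  } else {
    tibble(sources = tb$sources, metric = "n_inferred",
           value = tb$n_inferred)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sources, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "knowledge sources retained", y = "value",
                  title = "knowledge-source ablation") +
    ggplot2::theme_minimal()
}
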