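# Tidiers and plots for classification and scoring results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname score_contig_set
#' @param x A `contig_set_scores` object.
#' @param ... Ignored.
#' @export
tidy.contig_set_scores <- function(x, ...) x$per_rank

#' @rdname score_contig_set
#' @export
glance.contig_set_scores <- function(x, ...) {
  tibble(
    n = x$n, fraction_classified = x$fraction_classified,
    sensitivity = x$sensitivity, precision = x$precision,
    mean_rank = x$mean_rank, median_rank = x$median_rank
  )
}

#' @rdname cami_score
#' @param x A `cami_scores` object.
#' @param ... Ignored.
#' @export
tidy.cami_scores <- function(x, ...) {
  bind_rows(
    mutate(rename(x$predicted_bins, bp = "assigned_bp", value = "precision"),
      bin_type = "predicted"
    ),
    mutate(rename(x$real_bins, bp = "real_bp", value = "recall"),
      bin_type = "real"
    )
  )
}

#' @rdname cami_score
#' @export
glance.cami_scores <- function(x, ...) {
  tibble(
    rank = x$rank, accuracy = x$accuracy,
    misclassification = x$misclassification,
    average_precision = x$average_precision,
    average_recall = x$average_recall,
    average_precision_filtered = x$average_precision_filtered
  )
}

#' @rdname score_contig_set
#' @param object A `contig_set_scores` object.
#' @export
autoplot.contig_set_scores <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_rank,
    cols = c("fraction_classified", "sensitivity", "precision"),
    names_to = "measure", values_to = "value"
  )
  df$rank <- factor(df$rank, levels = official_ranks())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "rank", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-node support along the reported lineages of a query
#'
#' @param queries Query-level classification tibble.
#' @param query One query id to plot (default: the first).
#' @return A ggplot object.
#' @export
plot_support <- function(queries, query = queries$query_id[[1]]) {
  g <- filter(queries, .data$query_id == query, .data$status == "classified")
  if (nrow(g) == 0) abort(paste0("no classified lineage for query ", query))
  df <- bind_rows(lapply(seq_len(nrow(g)), function(i) {
    tibble(
      lineage = paste0("lineage ", i),
      depth = seq_along(g$lineage[[i]]),
      taxid = g$lineage[[i]],
      support = g$support[[i]]
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$depth, y = .data$support,
    colour = .data$lineage, group = .data$lineage
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "lineage depth (root = 1)", y = "support (fraction of B_sum)",
      title = query
    ) +
    ggplot2::theme_minimal()
}

#' Plot clade-exclusion benchmark scores
#'
#' Precision and mean classification rank across database exclusion levels,
#' the package's analogue of a clade-exclusion benchmark summary.
#'
#' @param scores The `scores` tibble from [clade_exclusion_experiment()].
#' @return A ggplot object.
#' @export
plot_exclusion_scores <- function(scores) {
  df <- tidyr::pivot_longer(scores,
    cols = c("precision", "fraction_classified", "mean_rank"),
    names_to = "measure", values_to = "value"
  )
  df$level <- factor(df$level, levels = unique(scores$level))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$value, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "clade exclusion level", y = NULL) +
    ggplot2::theme_minimal()
}
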