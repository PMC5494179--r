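# ggplot2 views of the main result types.

#' Serial-position curve of a scored session
#'
#' Recall proportion by presentation position over the main-list immediate
#' trials, with the primacy/middle/recency regions shaded.
#'
#' @param log An `ll_session_log`.
#' @return A ggplot object.
#' @export
plot_serial_position <- function(log) {
  sched <- log$schedule
  a_phases <- sched$phase_id[sched$phase_kind == "immediate_free_recall" &
                               sched$list_ref == "A"]
  pos_of <- stats::setNames(log$lists$A$position, log$lists$A$word)
  pos <- unlist(lapply(a_phases, function(pid) {
    pos_of[trial_recall(log, pid)$recall_sequence]
  }))
  df <- tibble::tibble(position = factor(seq_len(16), levels = seq_len(16)),
                       prop = as.numeric(table(factor(pos, levels = seq_len(16)))) /
                         length(a_phases))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$prop)) +
    ggplot2::annotate("rect", xmin = 0.5, xmax = 4.5, ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "steelblue") +
    ggplot2::annotate("rect", xmin = 12.5, xmax = 16.5, ymin = -Inf,
                      ymax = Inf, alpha = 0.08, fill = "firebrick") +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Presentation position", y = "Recall proportion",
                  title = "Serial-position curve (immediate trials)") +
    ggplot2::theme_minimal()
}

#' Heat map of a correlation matrix
#'
#' @param r A correlation matrix from [correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(r) {
  df <- tibble::as_tibble(r, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "r")
  df$row <- factor(df$row, levels = rownames(r))
  df$col <- factor(df$col, levels = colnames(r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Group comparison of a battery variable
#'
#' Box plots of one scored variable by diagnostic group.
#'
#' @param cohort A scored `ll_cohort`.
#' @param variable Battery column name (default the immediate-trial total).
#' @return A ggplot object.
#' @export
plot_group_scores <- function(cohort, variable = "total_A") {
  if (is.null(cohort$batteries)) {
    abort_state("Cohort is not scored; run score_cohort() first.")
  }
  df <- dplyr::bind_cols(cohort$subjects["group"],
                         cohort$batteries[variable])
  df$group <- factor(df$group, levels = c("HC", "MCI", "AD"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data[[variable]])) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = variable) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evaluation report
#'
#' Bar chart of the per-class one-vs-rest metrics.
#'
#' @param object An `ll_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ll_report <- function(object, ...) {
  df <- tidy(object)
  if (!"class" %in% names(df)) df$class <- "macro"
  df <- tidyr::pivot_longer(df, dplyr::any_of(c("precision", "f1",
                                                "sensitivity", "specificity")),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s / %s", object$scheme$type, object$model)) +
    ggplot2::theme_minimal()
}
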