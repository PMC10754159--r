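#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a UMAP embedding of cells
#'
#' Scatter of cells in the oriented UMAP plane (UMAP-1 anti-correlates with
#' size, UMAP-2 correlates with elongation), optionally colored by a
#' grouping column such as `cluster`, `cg` or `condition`.
#'
#' @param object A `morph_embed_tbl` from [embed_umap()] (or any data frame
#'   with `umap1`/`umap2`).
#' @param colour Column to color by (tidy-eval); default `cluster` if
#'   present.
#' @param ... Passed to [ggplot2::geom_point()].
#' @return A ggplot.
#' @export
autoplot.morph_embed_tbl <- function(object, colour = NULL, ...) {
  col_quo <- rlang::enquo(colour)
  if (rlang::quo_is_null(col_quo) && "cluster" %in% names(object)) {
    col_quo <- rlang::quo(factor(.data$cluster))
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$umap1, .data$umap2))
  if (!rlang::quo_is_null(col_quo)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = !!col_quo),
                                 size = 0.6, ...)
  } else {
    p <- p + ggplot2::geom_point(size = 0.6, ...)
  }
  p + ggplot2::labs(x = "UMAP-1 (decreasing size →)",
                    y = "UMAP-2 (increasing elongation →)") +
    ggplot2::theme_minimal()
}

#' Plot the k-selection trace
#'
#' Inertia (elbow) and mean silhouette against candidate k, with the
#' selected k marked.
#'
#' @param object A `morph_kselect` object.
#' @param ... Unused.
#' @return A ggplot (two stacked panels via facets).
#' @export
autoplot.morph_kselect <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, c("inertia", "silhouette"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "number of clusters k", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-by-condition enrichment heatmap
#'
#' Fractions of cells per morphology cluster (rows, in dendrogram order)
#' and exposure condition (columns), the tabular analogue of a
#' cluster-enrichment heatmap with per-condition entropy annotation.
#'
#' @param object A `morph_enrichment` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.morph_enrichment <- function(object, ...) {
  long <- tidy.morph_enrichment(object)
  ord <- as.integer(rownames(object$matrix))[object$row_order]
  long$cluster <- factor(long$cluster, levels = rev(ord))
  ent <- tibble::tibble(condition = names(object$entropy),
                        entropy = unname(object$entropy))
  long <- dplyr::left_join(long, ent, by = "condition")
  long$condition <- factor(long$condition, levels = colnames(object$matrix))
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$cluster,
                                     fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = "morphology cluster", fill = "fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot mean gamma-H2AX by morphology cluster
#'
#' @param object A `morph_damage` object.
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.morph_damage <- function(object, ...) {
  d <- object$by_cluster
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$cluster), .data$mean_gh2ax)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "morphology cluster",
                  y = "mean nuclear γH2AX (normalized)") +
    ggplot2::theme_minimal()
}

#' Plot ranked susceptibility scores
#'
#' Signed bar chart of per-population susceptibility scores (normalized to
#' the parental population when available), most susceptible first.
#'
#' @param object A `morph_scores` tibble from [rank_populations()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.morph_scores <- function(object, ...) {
  key <- if ("s_norm" %in% names(object)) "s_norm" else "s_sc"
  d <- dplyr::filter(object, !is.na(.data[[key]]))
  d$population <- factor(d$population, levels = rev(d$population))
  ggplot2::ggplot(d, ggplot2::aes(.data[[key]], .data$population,
                                  fill = .data[[key]] > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = if (key == "s_norm") "susceptibility score (parental = 0)"
                      else "susceptibility score",
                  y = NULL) +
    ggplot2::theme_minimal()
}
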