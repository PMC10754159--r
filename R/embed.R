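#' Embed cells in two dimensions with UMAP
#'
#' Runs UMAP on the normalized 33-parameter feature matrix and
#' post-processes the two embedding axes (axis swap and sign flips only, so
#' the layout itself is untouched) to a fixed reading convention: UMAP-1
#' anti-correlates with cell size and UMAP-2 correlates with cell
#' elongation (Spearman, computed on the normalized `cell_area` and
#' `cell_aspect_ratio` columns). UMAP axes are otherwise arbitrary in
#' orientation, so fixing them makes plots comparable across runs.
#'
#' @param data A `morph_norm_tbl` from [normalize_features()].
#' @param n_neighbors UMAP neighborhood size; automatically shrunk (with a
#'   warning) when there are fewer cells.
#' @param min_dist UMAP minimum embedding distance.
#' @param seed Integer seed; fixed seed gives a reproducible layout.
#' @return The input tibble with `umap1` and `umap2` columns appended and
#'   class `morph_embed_tbl` (has an `autoplot()` method).
#' @export
embed_umap <- function(data, n_neighbors = 30L, min_dist = 0.1, seed = 1L) {
  x <- norm_feature_matrix(data)
  if (nrow(x) < 10) stop("need at least 10 cells to embed")
  if (n_neighbors >= nrow(x)) {
    n_neighbors <- max(2L, nrow(x) - 1L)
    warning("n_neighbors >= number of cells; shrunk to ", n_neighbors)
  }
  emb <- withr::with_seed(seed,
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               n_threads = 1, n_sgd_threads = 0, batch = FALSE)
  )

  size <- if ("cell_area" %in% colnames(x)) x[, "cell_area"] else x[, 1]
  elong <- if ("cell_aspect_ratio" %in% colnames(x)) x[, "cell_aspect_ratio"] else x[, 2]
  r_size <- c(stats::cor(emb[, 1], size, method = "spearman"),
              stats::cor(emb[, 2], size, method = "spearman"))
  ax1 <- which.max(abs(r_size))
  ax2 <- 3L - ax1
  u1 <- emb[, ax1] * if (r_size[ax1] > 0) -1 else 1
  r_el <- stats::cor(emb[, ax2], elong, method = "spearman")
  u2 <- emb[, ax2] * if (r_el < 0) -1 else 1

  out <- dplyr::mutate(tibble::as_tibble(data), umap1 = u1, umap2 = u2)
  attr(out, "transform") <- attr(data, "transform")
  class(out) <- unique(c("morph_embed_tbl", class(data)))
  out
}
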