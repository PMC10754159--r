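#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a k-selection trace
#'
#' @param x A `morph_kselect` object.
#' @param ... Unused.
#' @return Tibble with one row per candidate k: `k`, `inertia`,
#'   `silhouette`, `knee_distance`, `selected`.
#' @export
tidy.morph_kselect <- function(x, ...) {
  dplyr::mutate(x$trace, selected = .data$k == x$k)
}

#' @rdname tidy.morph_kselect
#' @export
glance.morph_kselect <- function(x, ...) {
  tibble::tibble(k = x$k, knee_strength = x$knee_strength, no_knee = x$no_knee,
                 n_candidates = nrow(x$trace))
}

#' Tidy a fitted k-means morphology clustering
#'
#' @param x A `morph_km` object.
#' @param ... Unused.
#' @return `tidy()`: one row per (cluster, feature) centroid coordinate;
#'   `glance()`: one-row fit summary; `augment()`: `data` with a `.cluster`
#'   column.
#' @export
tidy.morph_km <- function(x, ...) {
  tibble::as_tibble(x$centroids) |>
    dplyr::mutate(cluster = seq_len(x$k), size = x$sizes) |>
    tidyr::pivot_longer(-c("cluster", "size"), names_to = "feature",
                        values_to = "centroid")
}

#' @rdname tidy.morph_km
#' @export
glance.morph_km <- function(x, ...) {
  tibble::tibble(k = x$k, n_cells = length(x$labels), inertia = x$inertia,
                 min_cluster_size = min(x$sizes))
}

#' @rdname tidy.morph_km
#' @param data Data frame the model was fitted on (same row order).
#' @export
augment.morph_km <- function(x, data, ...) {
  if (nrow(data) != length(x$labels)) stop("data does not match the fit")
  dplyr::mutate(tibble::as_tibble(data), .cluster = x$labels)
}

#' Tidy a Ward cluster-group assignment
#'
#' @param x A `morph_cg` object.
#' @param ... Unused.
#' @return `tidy()`: the cluster-to-CG map; `glance()`: a one-row summary.
#' @export
tidy.morph_cg <- function(x, ...) x$cg_map

#' @rdname tidy.morph_cg
#' @export
glance.morph_cg <- function(x, ...) {
  tibble::tibble(n_groups = x$n_groups, n_clusters = nrow(x$cg_map),
                 top_merge_height = max(x$hclust$height))
}

#' Tidy an enrichment matrix
#'
#' @param x A `morph_enrichment` object.
#' @param ... Unused.
#' @return Long tibble: `cluster`, `condition`, `fraction`.
#' @export
tidy.morph_enrichment <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    cluster = rep(as.integer(rownames(m)), times = ncol(m)),
    condition = rep(colnames(m), each = nrow(m)),
    fraction = as.vector(m)
  )
}

#' Tidy a damage-by-cluster summary
#'
#' @param x A `morph_damage` object.
#' @param ... Unused.
#' @return The per-cluster means tibble.
#' @export
tidy.morph_damage <- function(x, ...) x$by_cluster
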