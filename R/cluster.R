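# k-means++ seeding (Arthur & Vassilvitskii): each next center is drawn with
# probability proportional to the squared distance to the nearest chosen one.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 <= 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[i, ]
    d2j <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, d2j)
  }
  centers
}

run_kmeans_once <- function(x, k, iter_max = 100L) {
  init <- kmeanspp_centers(x, k)
  init <- init + stats::rnorm(length(init), 0, 1e-9)  # guard duplicate centers
  tryCatch(
    suppressWarnings(stats::kmeans(x, centers = init, iter.max = iter_max,
                                   algorithm = "Lloyd")),
    error = function(e) NULL
  )
}

#' k-means clustering of normalized morphology features
#'
#' Runs k-means (Lloyd iterations from k-means++ starts, best of `n_init`
#' restarts by total within-cluster sum of squares) on the normalized
#' feature matrix. Cluster ids are renumbered in decreasing mean cell size
#' (cluster 1 = largest cells), which gives a stable, reportable ordering.
#'
#' @param data A `morph_norm_tbl` from [normalize_features()] (or any data
#'   frame containing the 33 normalized feature columns).
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts.
#' @return An object of class `morph_km`: list with `k`, `centroids`
#'   (k x 33, renumbered), `labels` (1..k per cell), `inertia`, `sizes`.
#'   Supports [generics::tidy()], [generics::glance()],
#'   [generics::augment()].
#' @export
cluster_kmeans <- function(data, k, seed = 1L, n_init = 50L) {
  stopifnot(k >= 2)
  x <- norm_feature_matrix(data)
  if (k > nrow(x)) stop("k exceeds the number of cells")
  withr::with_seed(seed, {
    best <- NULL
    tries <- 0L
    while (is.null(best) || tries < n_init) {
      fit <- run_kmeans_once(x, k)
      tries <- tries + 1L
      if (is.null(fit)) {
        message("k-means restart produced an empty cluster; rerunning")
        next
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      if (tries > 5L * n_init) break
    }
    if (is.null(best)) stop("k-means failed to converge for k = ", k)
  })

  # renumber clusters by decreasing mean cell size (normalized cell_area)
  size_col <- if ("cell_area" %in% colnames(x)) "cell_area" else colnames(x)[1]
  mean_size <- tapply(x[, size_col], best$cluster, mean)
  ord <- order(mean_size, decreasing = TRUE)
  relab <- integer(k); relab[as.integer(names(mean_size))[ord]] <- seq_len(k)
  labels <- relab[best$cluster]
  centroids <- best$centers[as.integer(names(mean_size))[ord], , drop = FALSE]
  rownames(centroids) <- seq_len(k)

  structure(list(k = k, centroids = centroids, labels = labels,
                 inertia = best$tot.withinss,
                 sizes = as.integer(table(factor(labels, levels = seq_len(k)))),
                 features = colnames(x)),
            class = "morph_km")
}

#' @export
print.morph_km <- function(x, ...) {
  cat("<morph_km> k =", x$k, "clusters,", length(x$labels), "cells, inertia",
      format(x$inertia, digits = 6), "\n")
  invisible(x)
}

mean_silhouette <- function(x, labels, max_cells = 2000L) {
  n <- nrow(x)
  idx <- if (n > max_cells) sample.int(n, max_cells) else seq_len(n)
  if (length(unique(labels[idx])) < 2) return(NA_real_)
  sil <- cluster::silhouette(labels[idx], stats::dist(x[idx, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Select the number of morphology clusters by the inertia/silhouette plateau
#'
#' For each candidate k, fits k-means and records the inertia (total
#' within-cluster sum of squares) and mean silhouette width (computed on a
#' seeded subsample when the data are large). The selected k is the knee of
#' the inertia curve on a logarithmic inertia scale: the candidate with
#' maximum perpendicular distance to the chord joining the curve's
#' endpoints, both axes rescaled to `[0, 1]`. The log scale makes the knee
#' scale-free — the plateau (per-cluster relative improvement dropping to
#' the noise-carving level) shows up as the bend of the log curve regardless
#' of sample size or of how much variance coarser structure removes first.
#' Near-ties (within `tie_tol` of the maximum distance) are broken toward
#' the k at which the silhouette change flattens (absolute change below
#' `sil_tol`), then toward smaller k. If no candidate's knee distance
#' reaches `knee_min` the curve has no distinct knee: the selection is
#' flagged and the smallest candidate returned.
#'
#' @param data A `morph_norm_tbl` (or data frame of normalized features).
#' @param k_range Integer vector of candidate k (>= 2).
#' @param seed Integer seed.
#' @param n_init k-means restarts per candidate.
#' @param tie_tol Knee distances within this margin of the maximum count as
#'   ties.
#' @param sil_tol Silhouette-flattening tolerance for tie-breaks.
#' @param knee_min Minimum normalized knee distance for a distinct knee.
#' @param sil_cells Subsample size for silhouette computation.
#' @return An object of class `morph_kselect`: list with `k` (selected),
#'   `trace` (tibble: k, inertia, silhouette, improvement, knee distance),
#'   `no_knee` flag, and `knee_strength`. Supports `tidy()`, `glance()`,
#'   `autoplot()`.
#' @export
select_k <- function(data, k_range = 2:20, seed = 1L, n_init = 10L,
                     tie_tol = 0.01, sil_tol = 0.01, knee_min = 0.1,
                     sil_cells = 2000L) {
  x <- norm_feature_matrix(data)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2) stop("k_range must start at 2 or above")
  if (max(k_range) > nrow(x) / 10) stop("k_range exceeds n_cells / 10")
  if (all(stats::dist(x[seq_len(min(50L, nrow(x))), , drop = FALSE]) < 1e-12)) {
    stop("degenerate data: all rows identical")
  }

  res <- purrr::map(k_range, function(k) {
    fit <- cluster_kmeans(data, k, seed = seed + k, n_init = n_init)
    sil <- withr::with_seed(seed + 10000L + k,
                            mean_silhouette(x, fit$labels, max_cells = sil_cells))
    list(inertia = fit$inertia, silhouette = sil)
  })
  inertia <- purrr::map_dbl(res, "inertia")
  sil <- purrr::map_dbl(res, "silhouette")
  m <- length(k_range)

  improvement <- c((inertia[-m] - inertia[-1]) / pmax(inertia[-m], 1e-300), NA)

  # knee of the log-inertia curve: max perpendicular distance to the chord
  li <- log(pmax(inertia, .Machine$double.xmin))
  kk <- (k_range - min(k_range)) / max(1L, diff(range(k_range)))
  ii <- if (diff(range(li)) > 0) (li - min(li)) / diff(range(li)) else rep(0, m)
  p1 <- c(kk[1], ii[1]); p2 <- c(kk[m], ii[m])
  chord <- p2 - p1; chord_len <- max(sqrt(sum(chord^2)), 1e-12)
  dist_knee <- abs(chord[2] * (kk - p1[1]) - chord[1] * (ii - p1[2])) / chord_len
  strength <- max(dist_knee)

  no_knee <- strength < knee_min
  if (no_knee) {
    selected <- min(k_range)
    message("no distinct knee in the inertia curve (strength ",
            format(strength, digits = 3), " < ", knee_min,
            "); returning the smallest candidate k = ", selected)
  } else {
    near <- which(dist_knee >= strength - tie_tol)
    if (length(near) > 1) {
      dsil <- c(NA, abs(diff(sil)))
      flat <- near[!is.na(dsil[near]) & dsil[near] < sil_tol]
      if (length(flat)) near <- flat
    }
    selected <- k_range[min(near)]
  }

  structure(list(
    k = selected,
    trace = tibble::tibble(k = k_range, inertia = inertia, silhouette = sil,
                           improvement = improvement,
                           knee_distance = dist_knee),
    no_knee = no_knee,
    knee_strength = strength
  ), class = "morph_kselect")
}

#' @export
print.morph_kselect <- function(x, ...) {
  cat("<morph_kselect> selected k =", x$k,
      if (x$no_knee) "(no distinct knee; smallest candidate)" else "",
      "\n  knee strength:", format(x$knee_strength, digits = 3), "\n")
  invisible(x)
}

#' Group morphology clusters into cluster-groups by Ward linkage
#'
#' Performs Ward (ward.D2) hierarchical clustering on the per-cluster mean
#' normalized signatures and cuts the tree into `n_groups` cluster-groups
#' (CGs). With `n_groups = "auto"`, the tree is cut at the largest gap in
#' linkage heights. CG ids are renumbered in decreasing mean cell size, so
#' CG1 always contains the largest-cell clusters.
#'
#' @param centroids k x p matrix of cluster mean signatures (rows named by
#'   cluster id), e.g. `fit$centroids` from [cluster_kmeans()], or a
#'   `morph_km` object.
#' @param n_groups Number of groups, or `"auto"`.
#' @return An object of class `morph_cg`: list with `cg_map` (tibble:
#'   `cluster`, `cg`), `n_groups`, `hclust` (the dendrogram), and
#'   `dendrogram_order` (cluster ids in dendrogram leaf order).
#' @export
group_clusters_ward <- function(centroids, n_groups = "auto") {
  if (inherits(centroids, "morph_km")) centroids <- centroids$centroids
  k <- nrow(centroids)
  hc <- stats::hclust(stats::dist(centroids), method = "ward.D2")
  if (identical(n_groups, "auto")) {
    h <- hc$height  # increasing, length k - 1
    if (k <= 2) {
      g <- k
    } else {
      gaps <- diff(h)
      g <- k - which.max(gaps)
    }
  } else {
    g <- as.integer(n_groups)
    if (g > k) stop("n_groups exceeds the number of clusters")
    if (g < 1) stop("n_groups must be at least 1")
  }
  raw <- stats::cutree(hc, k = g)

  # renumber CGs by decreasing mean cell size across member clusters
  size_col <- if ("cell_area" %in% colnames(centroids)) "cell_area" else colnames(centroids)[1]
  cg_size <- tapply(centroids[, size_col], raw, mean)
  ord <- order(cg_size, decreasing = TRUE)
  relab <- integer(g); relab[as.integer(names(cg_size))[ord]] <- seq_len(g)
  cg <- relab[raw]

  structure(list(
    cg_map = tibble::tibble(cluster = as.integer(rownames(centroids) %||% seq_len(k)),
                            cg = as.integer(cg)),
    n_groups = g,
    hclust = hc,
    dendrogram_order = as.integer((rownames(centroids) %||% seq_len(k))[hc$order])
  ), class = "morph_cg")
}

#' @export
print.morph_cg <- function(x, ...) {
  cat("<morph_cg>", x$n_groups, "cluster-groups over",
      nrow(x$cg_map), "clusters\n")
  print(x$cg_map, n = nrow(x$cg_map))
  invisible(x)
}
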