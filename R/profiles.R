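#' Per-population, per-condition cluster-fraction profiles
#'
#' Counts cells per morphology cluster within each (population, condition)
#' key and converts counts to fractions `p_i` over the global clusters
#' 1..k (clusters absent from a key get 0). When a cluster-to-CG map is
#' supplied, CG fractions and the key's Shannon entropy over clusters are
#' appended.
#'
#' @param data Data frame with one row per cell, containing `cluster` and
#'   the grouping columns.
#' @param k Total number of clusters; defaults to `max(cluster)`.
#' @param cg_map Optional [group_clusters_ward()] result (or its `cg_map`
#'   tibble) for CG aggregation.
#' @param group_vars Grouping columns, default `c("population", "condition")`
#'   (missing ones are dropped).
#' @param entropy_base Logarithm base for the entropy column.
#' @return A tibble with one row per key: grouping columns, `n_cells`,
#'   `p_1 .. p_k`, optional `p_cg1 ..`, and `entropy` (nats).
#' @export
cluster_fractions <- function(data, k = NULL, cg_map = NULL,
                              group_vars = c("population", "condition"),
                              entropy_base = exp(1)) {
  if (!"cluster" %in% names(data)) stop("data must contain a 'cluster' column")
  group_vars <- intersect(group_vars, names(data))
  if (is.null(k)) k <- max(data$cluster)
  if (any(!data$cluster %in% seq_len(k))) stop("cluster labels outside 1..k")
  if (inherits(cg_map, "morph_cg")) cg_map <- cg_map$cg_map

  counts <- data |>
    dplyr::count(dplyr::across(dplyr::all_of(group_vars)),
                 cluster = factor(.data$cluster, levels = seq_len(k)),
                 .drop = FALSE, name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::mutate(n_cells = sum(.data$n), p = .data$n / .data$n_cells) |>
    dplyr::ungroup()
  if (any(counts$n_cells == 0)) {
    bad <- dplyr::filter(counts, .data$n_cells == 0) |>
      dplyr::distinct(dplyr::across(dplyr::all_of(group_vars)))
    stop("empty (population, condition) key(s): ",
         paste(do.call(paste, c(bad, sep = "/")), collapse = ", "))
  }

  wide <- counts |>
    dplyr::select(dplyr::all_of(group_vars), "n_cells", "cluster", "p") |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "p",
                       names_prefix = "p_")
  pmat <- as.matrix(wide[paste0("p_", seq_len(k))])
  wide$entropy <- apply(pmat, 1, shannon_entropy, base = entropy_base)

  if (!is.null(cg_map)) {
    gmax <- max(cg_map$cg)
    cg_of <- integer(k); cg_of[cg_map$cluster] <- cg_map$cg
    for (g in seq_len(gmax)) {
      wide[[paste0("p_cg", g)]] <- rowSums(pmat[, which(cg_of == g), drop = FALSE])
    }
    wide <- dplyr::relocate(wide, "entropy", .after = dplyr::last_col())
  }
  wide
}

#' Shannon entropy of a cluster-fraction vector
#'
#' `S = -sum(p_i * log(p_i))` over fractions `p_i`, with `0 log 0 = 0` by
#' continuity. Natural log by default, so `S` ranges from 0 (one-hot) to
#' `log(k)` (uniform over k clusters); greater values signify a more
#' heterogeneous population.
#'
#' @param p Nonnegative fraction vector summing to 1.
#' @param base Logarithm base (`exp(1)` for nats).
#' @return Entropy (a single nonnegative number).
#' @export
#' @examples
#' shannon_entropy(rep(0.1, 10))  # log(10)
#' shannon_entropy(c(1, rep(0, 9)))  # 0
shannon_entropy <- function(p, base = exp(1)) {
  if (any(p < 0)) stop("fractions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("fractions must sum to 1")
  pos <- p[p > 0]
  -sum(pos * log(pos, base = base))
}

#' Cluster-by-condition enrichment matrix
#'
#' Arranges per-condition cluster fractions as a clusters x conditions
#' matrix (each column a condition's fraction vector, summing to 1), with
#' rows ordered by the Ward dendrogram of the cluster mean signatures when
#' available, plus the per-condition Shannon entropies.
#'
#' @param profiles Profile tibble from [cluster_fractions()] (one row per
#'   condition; if a `population` column is present it must be constant).
#' @param cg A [group_clusters_ward()] result; optional, used for the row
#'   (dendrogram) ordering and CG annotation.
#' @return An object of class `morph_enrichment`: list with `matrix`
#'   (clusters x conditions), `entropy` (named per-condition vector),
#'   `row_order`, and `cg_map`. Has an `autoplot()` method.
#' @export
enrichment_matrix <- function(profiles, cg = NULL) {
  pcols <- grep("^p_[0-9]+$", names(profiles), value = TRUE)
  if (!length(pcols)) stop("profiles carry no p_<cluster> columns")
  if (nrow(profiles) < 2) stop("need at least 2 conditions")
  if (!"condition" %in% names(profiles)) stop("profiles lack a 'condition' column")
  if (anyDuplicated(profiles$condition)) {
    stop("profiles must have one row per condition (aggregate populations first)")
  }
  m <- t(as.matrix(profiles[pcols]))
  rownames(m) <- sub("^p_", "", pcols)
  colnames(m) <- profiles$condition
  row_order <- seq_len(nrow(m))
  cg_map <- NULL
  if (!is.null(cg)) {
    row_order <- match(cg$dendrogram_order, as.integer(rownames(m)))
    cg_map <- cg$cg_map
  }
  structure(list(matrix = m,
                 entropy = stats::setNames(profiles$entropy, profiles$condition),
                 row_order = row_order, cg_map = cg_map),
            class = "morph_enrichment")
}

#' @export
print.morph_enrichment <- function(x, ...) {
  cat("<morph_enrichment>", nrow(x$matrix), "clusters x", ncol(x$matrix),
      "conditions\n")
  print(round(x$matrix[x$row_order, ], 3))
  invisible(x)
}

#' Mean gamma-H2AX per morphology cluster
#'
#' Pools cells within each morphology cluster across all conditions and
#' averages their nuclear gamma-H2AX signal; also reports per-condition
#' means (the top margin of an enrichment heatmap). Cells with missing
#' damage values are excluded with a message.
#'
#' @param data Data frame with `cluster`, `gh2ax`, and optionally
#'   `condition` columns.
#' @return An object of class `morph_damage`: list with `by_cluster`
#'   (tibble: cluster, mean_gh2ax, n) and `by_condition`. Has an
#'   `autoplot()` method.
#' @export
damage_by_cluster <- function(data) {
  if (!all(c("cluster", "gh2ax") %in% names(data))) {
    stop("data must contain 'cluster' and 'gh2ax' columns")
  }
  n_miss <- sum(is.na(data$gh2ax))
  if (n_miss) {
    message(n_miss, " cell(s) with missing gh2ax excluded")
    data <- dplyr::filter(data, !is.na(.data$gh2ax))
  }
  by_cluster <- data |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(mean_gh2ax = mean(.data$gh2ax), n = dplyr::n()) |>
    dplyr::arrange(.data$cluster)
  by_condition <- NULL
  if ("condition" %in% names(data)) {
    by_condition <- data |>
      dplyr::group_by(condition = .data$condition) |>
      dplyr::summarise(mean_gh2ax = mean(.data$gh2ax), n = dplyr::n())
  }
  structure(list(by_cluster = by_cluster, by_condition = by_condition),
            class = "morph_damage")
}

#' @export
print.morph_damage <- function(x, ...) {
  cat("<morph_damage> mean gamma-H2AX by cluster\n")
  print(x$by_cluster, n = nrow(x$by_cluster))
  invisible(x)
}

#' Pearson correlation with a two-sided t-test
#'
#' Standard Pearson correlation between two summary vectors (for example
#' per-condition mean gamma-H2AX against per-condition dead-cell fraction),
#' with the usual t-distribution two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, nonconstant.
#' @return A one-row tibble: `r`, `p_value`, `n`, `df`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), df = unname(ct$parameter))
}
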