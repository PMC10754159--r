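# Three well-separated spherical blobs in 33-d, dressed up as a normalized
# feature table; an easy case with a brute-force-checkable answer.
blob_table <- function(n_per = 120, k = 3, sep = 8, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(stats::rnorm(k * 33), k, 33)
    centers <- centers / sqrt(rowSums(centers^2)) * sep
    x <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(stats::rnorm(n_per * 33, sd = 1), n_per, 33) +
        matrix(centers[i, ], n_per, 33, byrow = TRUE)
    }))
  })
  colnames(x) <- morph_feature_names()
  d <- tibble::as_tibble(x)
  d$truth <- rep(seq_len(k), each = n_per)
  d
}

test_that("k-means recovers two planted subtypes nearly perfectly", {
  d <- blob_table(k = 2, n_per = 150)
  km <- cluster_kmeans(d, k = 2, seed = 3, n_init = 10)
  expect_gte(oracle_ari(km$labels, d$truth), 0.95)
})

test_that("k-means is deterministic for a fixed seed and renumbers by size", {
  d <- blob_table(k = 3)
  km1 <- cluster_kmeans(d, 3, seed = 7, n_init = 10)
  km2 <- cluster_kmeans(d, 3, seed = 7, n_init = 10)
  expect_identical(km1$labels, km2$labels)
  expect_identical(km1$centroids, km2$centroids)
  # cluster 1 has the largest mean cell size
  sizes <- tapply(d$cell_area, km1$labels, mean)
  expect_equal(order(sizes, decreasing = TRUE), 1:3)
})

test_that("k equal to the number of cells drives inertia to zero", {
  d <- blob_table(k = 2, n_per = 10)
  km <- cluster_kmeans(d, k = 20, seed = 2, n_init = 2)
  expect_equal(km$inertia, 0, tolerance = 1e-9)
  expect_equal(sort(unique(km$labels)), 1:20)
})

test_that("select_k finds three well-separated planted subtypes", {
  d <- blob_table(k = 3, n_per = 150)
  ks <- select_k(d, k_range = 2:10, seed = 5, n_init = 5)
  expect_equal(ks$k, 3)
  expect_false(ks$no_knee)
  # brute-force corroboration: inertia knee and silhouette max coincide at 3
  expect_equal(ks$trace$k[which.max(ks$trace$silhouette)], 3)
})

test_that("a single spherical blob is flagged as having no distinct knee", {
  d <- blob_table(k = 1, n_per = 400)
  expect_message(ks <- select_k(d, k_range = 2:10, seed = 4, n_init = 3),
                 "no distinct knee")
  expect_true(ks$no_knee)
  expect_equal(ks$k, 2)
})

test_that("degenerate identical rows raise an error", {
  d <- tibble::as_tibble(matrix(1, 100, 33,
                                dimnames = list(NULL, morph_feature_names())))
  expect_error(select_k(d, k_range = 2:5), "degenerate")
})

test_that("select_k recovers planted k across seeds at fixture separation", {
  recovery_rate <- function(sub_idx, n, krange, n_rep = 20L, n_init = 3L) {
    st <- subtype_template()[sub_idx, ]
    fr <- rep(1 / length(sub_idx), length(sub_idx))
    cond <- condition_spec("mix", "control", fr)
    hits <- 0L
    for (r in seq_len(n_rep)) {
      cells <- generate_population(st, cond, n_cells = n, seed = 3000 + r)
      ks <- select_k(normalize_features(cells), k_range = krange,
                     seed = r, n_init = n_init)
      hits <- hits + (ks$k == length(sub_idx))
    }
    hits / n_rep
  }
  expect_gte(recovery_rate(c(1, 4, 10), 300, 2:10), 0.9)
  expect_gte(recovery_rate(c(1, 3, 5, 8, 10), 400, 2:12), 0.9)
  expect_gte(recovery_rate(1:10, 1500, 2:15, n_init = 12L), 0.9)
})

test_that("Ward grouping: identity at n_groups = k, errors beyond k", {
  d <- blob_table(k = 4, n_per = 60)
  km <- cluster_kmeans(d, 4, seed = 1, n_init = 5)
  cg <- group_clusters_ward(km, n_groups = 4)
  expect_equal(sort(cg$cg_map$cg), 1:4)
  expect_error(group_clusters_ward(km, n_groups = 5), "exceeds")
})

test_that("Ward auto cut finds planted super-groups and orders CGs by size", {
  # 6 clusters in 3 pairs: pair members close, pairs far apart
  withr::with_seed(11, {
    base <- matrix(stats::rnorm(3 * 33), 3, 33)
    base <- base / sqrt(rowSums(base^2)) * 12
    cents <- rbind(base[1, ] + stats::rnorm(33, sd = 0.5), base[1, ] - stats::rnorm(33, sd = 0.5),
                   base[2, ] + stats::rnorm(33, sd = 0.5), base[2, ] - stats::rnorm(33, sd = 0.5),
                   base[3, ] + stats::rnorm(33, sd = 0.5), base[3, ] - stats::rnorm(33, sd = 0.5))
  })
  colnames(cents) <- morph_feature_names()
  rownames(cents) <- 1:6
  cg <- group_clusters_ward(cents, n_groups = "auto")
  expect_equal(cg$n_groups, 3)
  expect_equal(cg$cg_map$cg[1], cg$cg_map$cg[2])
  expect_equal(cg$cg_map$cg[3], cg$cg_map$cg[4])
  expect_equal(cg$cg_map$cg[5], cg$cg_map$cg[6])
  # CG1 has the largest mean cell_area
  sizes <- tapply(cents[, "cell_area"], cg$cg_map$cg, mean)
  expect_equal(order(sizes, decreasing = TRUE), 1:3)
})

test_that("row-order permutation does not change assignments after renumbering", {
  d <- blob_table(k = 3, n_per = 80)
  perm <- withr::with_seed(9, sample(nrow(d)))
  km1 <- cluster_kmeans(d, 3, seed = 5, n_init = 10)
  km2 <- cluster_kmeans(d[perm, ], 3, seed = 5, n_init = 10)
  expect_equal(km2$labels, km1$labels[perm])
})
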