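test_that("cluster fractions count directly and pad absent clusters with zero", {
  d <- tibble::tibble(population = "p", condition = "c",
                      cluster = c(1L, 1L, 2L, 3L))
  pr <- cluster_fractions(d, k = 4)
  expect_equal(unlist(pr[paste0("p_", 1:4)], use.names = FALSE),
               c(0.5, 0.25, 0.25, 0))
  expect_equal(pr$n_cells, 4)

  one_hot <- cluster_fractions(tibble::tibble(cluster = rep(7L, 12)), k = 10)
  expect_equal(unlist(one_hot[paste0("p_", 1:10)], use.names = FALSE),
               c(rep(0, 6), 1, 0, 0, 0))
  expect_equal(one_hot$entropy, 0)
})

test_that("empirical fractions of a large multinomial stay within the DKW bound", {
  p <- c(0.3, 0.25, 0.2, 0.15, 0.07, 0.03)
  n <- 10000L
  withr::with_seed(99, {
    labels <- sample.int(6L, n, replace = TRUE, prob = p)
  })
  pr <- cluster_fractions(tibble::tibble(cluster = labels), k = 6)
  phat <- unlist(pr[paste0("p_", 1:6)], use.names = FALSE)
  # DKW: P(sup |F_n - F| > eps) <= 2 exp(-2 n eps^2); 99% bound
  eps <- sqrt(log(2 / 0.01) / (2 * n))
  expect_lt(max(abs(cumsum(phat) - cumsum(p))), eps)
})

test_that("Shannon entropy reproduces its closed-form cases and bounds", {
  expect_equal(shannon_entropy(rep(0.1, 10)), log(10), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(1, rep(0, 9))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, rep(0, 8))), log(2), tolerance = 1e-12)
  expect_error(shannon_entropy(c(0.5, 0.6)), "sum to 1")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "nonnegative")
  # bounds on random simplex draws
  withr::with_seed(7, {
    for (i in 1:50) {
      k <- sample(2:12, 1)
      p <- stats::rexp(k); p <- p / sum(p)
      s <- shannon_entropy(p)
      expect_gte(s, 0)
      expect_lte(s, log(k) + 1e-12)
    }
  })
})

test_that("fraction vectors are conserved and CG aggregation is exact", {
  cells <- small_fixture(800)
  withr::with_seed(1, {
    cells$cluster <- sample.int(10L, nrow(cells), replace = TRUE)
  })
  cg_map <- tibble::tibble(cluster = 1:10, cg = c(1,1,1,2,2,2,3,3,3,3))
  pr <- cluster_fractions(cells, k = 10, cg_map = cg_map)
  pmat <- as.matrix(pr[paste0("p_", 1:10)])
  expect_equal(rowSums(pmat), rep(1, nrow(pr)), tolerance = 1e-9)
  cgmat <- as.matrix(pr[paste0("p_cg", 1:3)])
  expect_equal(rowSums(cgmat), rep(1, nrow(pr)), tolerance = 1e-9)
  for (g in 1:3) {
    expect_equal(unname(cgmat[, g]),
                 unname(rowSums(pmat[, cg_map$cluster[cg_map$cg == g],
                                     drop = FALSE])),
                 tolerance = 1e-12)
  }
})

test_that("merging two identical populations leaves fractions and entropy unchanged", {
  d1 <- tibble::tibble(population = "a", condition = "c",
                       cluster = rep(c(1L, 2L, 3L), times = c(5, 3, 2)))
  d2 <- dplyr::mutate(d1, population = "b")
  single <- cluster_fractions(d1, k = 3)
  merged <- cluster_fractions(dplyr::bind_rows(d1, d2), k = 3,
                              group_vars = "condition")
  expect_equal(unlist(merged[paste0("p_", 1:3)]), unlist(single[paste0("p_", 1:3)]))
  expect_equal(merged$entropy, single$entropy)
})

test_that("enrichment matrix columns are conditions with unit sums", {
  cells <- dplyr::bind_rows(
    tibble::tibble(condition = "c1", cluster = rep(1:4, times = c(4, 3, 2, 1))),
    tibble::tibble(condition = "c2", cluster = rep(1:4, times = c(1, 2, 3, 4)))
  )
  pr <- cluster_fractions(cells, k = 4, group_vars = "condition")
  em <- enrichment_matrix(pr)
  expect_equal(dim(em$matrix), c(4L, 2L))
  expect_equal(colSums(em$matrix), c(c1 = 1, c2 = 1))
  # identical conditions give identical columns and zero entropy difference
  pr2 <- cluster_fractions(dplyr::mutate(cells, condition = ifelse(
    condition == "c2", "c1dup", condition)) |>
      dplyr::mutate(cluster = rep(rep(1:4, times = c(4, 3, 2, 1)), 2)),
    k = 4, group_vars = "condition")
  em2 <- enrichment_matrix(pr2)
  expect_equal(em2$matrix[, 1], em2$matrix[, 2], ignore_attr = TRUE)
  expect_equal(diff(unname(em2$entropy)), 0)
})

test_that("damage means pool cells by cluster exactly", {
  d <- tibble::tibble(cluster = rep(c(1L, 2L), each = 20),
                      gh2ax = rep(c(0.2, 0.8), each = 20))
  dm <- damage_by_cluster(d)
  expect_equal(dm$by_cluster$mean_gh2ax, c(0.2, 0.8))
  all_equal <- damage_by_cluster(tibble::tibble(cluster = rep(1:5, 4),
                                                gh2ax = 0.3))
  expect_true(all(all_equal$by_cluster$mean_gh2ax == 0.3))
  expect_message(
    dm2 <- damage_by_cluster(tibble::tibble(cluster = c(1L, 1L, 2L),
                                            gh2ax = c(0.5, NA, 0.1))),
    "missing")
  expect_equal(dm2$by_cluster$n, c(1L, 1L))
})

test_that("pearson correlation matches closed forms and the direct-sum oracle", {
  expect_equal(pearson_correlation(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_correlation(1:3, c(3, 2, 1))$r, -1)
  withr::with_seed(12, {
    z <- stats::rnorm(8)
    x <- z + stats::rnorm(8, sd = 0.3)
    y <- 0.9 * z + stats::rnorm(8, sd = sqrt(1 - 0.81))
  })
  res <- pearson_correlation(x, y)
  expect_equal(res$r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(res$df, 6)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})
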