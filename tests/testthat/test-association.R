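test_that("contingency tables count intersections in the universe", {
  u <- paste0("g", 1:4)
  expect_equal(unname(contingency_table(c("g1", "g2"), c("g2", "g3"), u)),
               c(1L, 1L, 1L, 1L))
  expect_equal(contingency_table(c("g1"), c("g2"), u)[["a"]], 0L)
  expect_equal(unname(contingency_table(u, u, u)), c(4L, 0L, 0L, 0L))
  expect_error(contingency_table("g1", "g1", character()), "empty universe")
})

test_that("one-sided Fisher p matches exact enumeration on landmark tables", {
  expect_equal(fisher_one_sided(10, 0, 0, 10)$p, 1 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_one_sided(5, 5, 5, 5)$p, fisher_oracle(5, 5, 5, 5),
               tolerance = 1e-12)
  expect_equal(fisher_one_sided(0, 5, 5, 0)$p, 1)
  # zero margin carries no information
  r <- fisher_one_sided(0, 0, 3, 7)
  expect_equal(r$p, 1)
  expect_true(is.na(r$odds_ratio))
  expect_equal(fisher_one_sided(4, 1, 1, 4)$odds_ratio, 16)
  expect_equal(fisher_one_sided(4, 0, 1, 5)$odds_ratio, Inf)
})

test_that("one-sided Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(17)
  for (i in 1:40) {
    tb <- rpois(4, 6)
    p_ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE),
                                alternative = "greater")$p.value
    expect_equal(fisher_one_sided(tb[1], tb[2], tb[3], tb[4])$p, p_ref,
                 tolerance = 1e-10)
  }
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  p <- runif(200)
  q <- bh_fdr(p)
  expect_equal(q, bh_oracle(p), tolerance = 1e-12)
  # monotone non-decreasing in sorted-p order and bounded by [p, 1]
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p & q <= 1))
})

test_that("association grid reduces to a single Fisher test for 1x1 labels", {
  d <- tibble::tibble(gene_id = paste0("g", 1:10),
                      a = rep(c("X", "Y"), each = 5),
                      b = rep(c("U", "V"), 5))
  g <- association_grid(d, "a", "b")
  cell <- g[g$group_a == "X" & g$group_b == "U", ]
  ref <- fisher_one_sided(cell$a, cell$b, cell$c, cell$d)
  expect_equal(cell$p, ref$p)
  expect_equal(cell$odds_ratio, ref$odds_ratio)
  expect_equal(nrow(g), 4L)
  expect_true(all(g$a + g$b + g$c + g$d == 10))
  expect_error(association_grid(dplyr::mutate(d, a = replace(a, 1, NA)), "a", "b"),
               "both labels")
})

test_that("wilcoxon_greater is exact for small tie-free samples", {
  expect_equal(wilcoxon_greater(c(4, 5, 6), c(1, 2, 3)), 1 / choose(6, 3))
  x <- c(1, 2, 3.5)
  expect_gte(wilcoxon_greater(x, x + 1e-9), 0.5)
  set.seed(31)
  lo <- rnorm(40, 0); hi <- rnorm(40, 3)
  expect_gt(wilcoxon_greater(lo, hi), 0.999)
  expect_lt(wilcoxon_greater(hi, lo), 1e-6)
  expect_error(wilcoxon_greater(numeric(), 1), "non-empty")
})

test_that("z-scoring uses the population sd and is idempotent", {
  f <- tibble::tibble(id = c("a", "b", "c"), x = c(1, 2, 3), k = c(1, 1, 1))
  z <- zscore_columns(f, "x")
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(as.numeric(zscore_columns(tibble::tibble(id = c("a", "b", "c"),
                                                        x = as.numeric(z)), "x")),
               as.numeric(z), tolerance = 1e-12)
  expect_error(zscore_columns(f, "k"), "constant column: k")
})

test_that("k-means recovers planted blobs and honors degenerate limits", {
  set.seed(8)
  centers <- matrix(rnorm(6 * 3, sd = 6), 6, 3)
  X <- centers[rep(1:6, each = 40), ] + matrix(rnorm(240 * 3, sd = 0.5), 240, 3)
  rownames(X) <- paste0("g", 1:240)
  truth <- rep(1:6, each = 40)
  cl <- kmeans_clusters(X, k = 6, seed = 1)
  expect_gte(mclust::adjustedRandIndex(cl$cluster, truth), 0.8)
  one <- kmeans_clusters(X, k = 1, seed = 1)
  expect_equal(unique(one$cluster), 1L)
  expect_equal(attr(one, "wcss"), sum(scale(X, scale = FALSE)^2))
  dup <- X[rep(1:6, each = 10) + 234 * 0, ]  # 6 distinct rows repeated
  dup <- centers[rep(1:6, each = 10), ]
  rownames(dup) <- paste0("d", 1:60)
  z0 <- kmeans_clusters(dup, k = 6, seed = 2)
  expect_equal(attr(z0, "wcss"), 0)
  expect_error(kmeans_clusters(X[1:3, ], k = 6), "exceeds")
})

test_that("cluster labels are ordered by decreasing order_by means", {
  set.seed(9)
  X <- cbind(c(rnorm(30, 0), rnorm(30, 10)), rnorm(60))
  rownames(X) <- paste0("g", 1:60)
  cl <- kmeans_clusters(X, k = 2, seed = 3, order_by = X[, 1])
  m1 <- mean(X[cl$cluster == 1, 1]); m2 <- mean(X[cl$cluster == 2, 1])
  expect_gt(m1, m2)
})

test_that("group feature summaries z-score means across groups", {
  f <- tibble::tibble(id = paste0("g", 1:4), x = c(1, 1, 3, 3),
                      y = c(2, 2, 2, 2))
  expect_warning(s <- group_feature_summary(f, c("A", "A", "B", "B"),
                                            c("x", "y")),
                 "identical group means")
  expect_equal(sort(s$x), c(-1, 1))
  expect_equal(s$y, c(0, 0))
  # translation invariance
  f2 <- dplyr::mutate(f, x = x + 100)
  s2 <- suppressWarnings(group_feature_summary(f2, c("A", "A", "B", "B"),
                                               c("x", "y")))
  expect_equal(s2$x, s$x)
  expect_error(group_feature_summary(f, rep("A", 4), "x"), "two groups")
})
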