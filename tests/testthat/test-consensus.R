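pk <- function(start, end, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end))
}

test_that("consensus keeps >= min_support replicates and merges by maxgap", {
  same <- pk(100, 200)
  cp3 <- consensus_peaks(list(same, same, same))
  expect_equal(nrow(cp3), 1L)
  expect_equal(cp3$support, 3L)
  only1 <- consensus_peaks(list(same, pk(5000, 5100), pk(9000, 9100)))
  expect_equal(only1$support, integer(0))
  expect_error(consensus_peaks(list(same), min_support = 2), "exceeds")
})

test_that("the gap = maxgap boundary joins; maxgap + 1 splits", {
  r1 <- pk(100, 200)
  r2 <- pk(350, 400)          # gap exactly 150
  joined <- consensus_peaks(list(r1, r2), min_support = 2, maxgap = 150)
  expect_equal(c(joined$start, joined$end, joined$support), c(100L, 400L, 2L))
  r2b <- pk(351, 400)         # gap 151
  split <- consensus_peaks(list(r1, r2b), min_support = 2, maxgap = 150)
  expect_equal(nrow(split), 0L)
})

test_that("clustering is transitive through chains of nearby peaks", {
  # a-b gap 150, b-c gap 150: one cluster spanning all three
  chain <- consensus_peaks(list(pk(0, 100), pk(250, 300), pk(450, 500)),
                           min_support = 3, maxgap = 150)
  expect_equal(c(chain$start, chain$end, chain$support), c(0L, 500L, 3L))
})

test_that("consensus equals the O(n^2) transitive-closure oracle on random instances", {
  set.seed(77)
  for (i in 1:100) {
    reps <- lapply(1:3, function(r) {
      n <- sample(0:17, 1)
      if (n == 0) return(pk(integer(), integer()))
      s <- sort(sample(0:4000, n))
      pk(s, s + sample(30:300, n, replace = TRUE),
         chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    })
    got <- consensus_peaks(reps, min_support = 2, maxgap = 150)
    want <- consensus_oracle(reps, min_support = 2, maxgap = 150)
    expect_equal(as.data.frame(got[c("chrom", "start", "end", "support")]),
                 as.data.frame(want), info = paste("instance", i),
                 ignore_attr = TRUE)
  }
})

test_that("consensus is invariant under replicate order", {
  set.seed(78)
  reps <- lapply(1:3, function(r) {
    s <- sort(sample(0:3000, 12))
    pk(s, s + sample(40:250, 12, replace = TRUE))
  })
  a <- consensus_peaks(reps)
  b <- consensus_peaks(rev(reps))
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("spike-in factors anchor to the shallowest sample and are scale-free", {
  f <- spike_in_factors(c(s1 = 100, s2 = 100))
  expect_equal(f$factor, c(1, 1))
  f2 <- spike_in_factors(c(s1 = 100, s2 = 200))
  expect_equal(f2$factor, c(1, 0.5))
  expect_equal(spike_in_factors(c(only = 5000))$factor, 1)
  f3 <- spike_in_factors(c(s1 = 300, s2 = 600) * 17)
  expect_equal(f3$factor, f2$factor)
  expect_equal(f2$factor * f2$spike_reads, rep(100, 2))
  expect_error(spike_in_factors(c(s1 = 0, s2 = 10)), "positive")
})

test_that("feature counts integrate coverage with optional scaling", {
  tr <- flat_track(1, start = 0L, end = 1000L)
  feat <- pk(100, 300)
  expect_equal(feature_counts(tr, feat), 200)
  expect_equal(feature_counts(tr, feat, scale_factor = 0.5), 100)
  expect_equal(feature_counts(tr, pk(100, 300, chrom = "chrX")), 0)
})

test_that("differential test calls planted depletion and leaves nulls alone", {
  set.seed(55)
  n <- 400
  base <- rlnorm(n, log(200), 0.5)
  down <- seq_len(80)
  counts <- tibble::tibble(feature_id = paste0("f", 1:n))
  for (s in c("c1", "c2", "c3")) counts[[s]] <- base * rlnorm(n, 0, 0.1)
  for (s in c("t1", "t2", "t3")) {
    v <- base; v[down] <- v[down] / 4
    counts[[s]] <- v * rlnorm(n, 0, 0.1)
  }
  si <- tibble::tibble(sample = c("c1", "c2", "c3", "t1", "t2", "t3"),
                       condition = rep(c("control", "treated"), each = 3))
  res <- differential_test(counts, si)
  expect_gte(mean(res$call[down] == "down"), 0.8)
  expect_equal(mean(res$log2fc[down]), -2, tolerance = 0.15)
  expect_lte(mean(res$call[-down] != "ns"), 0.02)
  expect_error(differential_test(counts[c("feature_id", "c1", "t1")], si[c(1, 4), ]),
               ">= 2 replicates")
})

test_that("all-zero features are ns with log2fc 0", {
  counts <- tibble::tibble(feature_id = "f1", c1 = 0, c2 = 0, t1 = 0, t2 = 0)
  si <- tibble::tibble(sample = c("c1", "c2", "t1", "t2"),
                       condition = c("control", "control", "treated", "treated"))
  res <- differential_test(counts, si)
  expect_equal(res$log2fc, 0)
  expect_equal(res$call, "ns")
  expect_equal(res$p, 1)
})

test_that("call annotation tallies groups and the zygotic down fraction", {
  res <- structure(tibble::tibble(
    feature_id = paste0("g", 1:10),
    mean_control = 1, mean_treated = 1, log2fc = 0,
    p = 1, q = 1,
    call = c(rep("down", 4), rep("ns", 6))), class = c("premark_diff", "tbl_df", "tbl", "data.frame"))
  rna <- tibble::tibble(gene_id = paste0("g", 1:10),
                        group = factor(rep("GZ", 10), levels = c("GZ", "GS", "ZS", "ND")),
                        spermatid_specific = FALSE, zygotic = TRUE)
  dyn <- classify_dynamics(tibble::tibble(gene_id = paste0("g", 1:9),
                                          pattern = rep("1111", 9)))
  cc <- classify_calls(res, rna, dyn)
  expect_equal(cc$zygotic_down_fraction, 0.4)
  expect_equal(sum(cc$tally_rna$n), 10L)
  expect_true("unlabeled" %in% cc$annotated$dynamics_group)
  empty <- classify_calls(res[0, ], rna, dyn)
  expect_true(is.na(empty$zygotic_down_fraction))
  expect_equal(nrow(empty$tally_rna), 0L)
})
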