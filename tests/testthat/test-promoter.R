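ann1 <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                       gene_start = 5000L, gene_end = 6200L, tss = 5000L)

test_that("promoter windows are TSS-centered and clipped at edges", {
  w <- promoter_windows(ann1, flank = 1000)
  expect_equal(c(w$start, w$end), c(4000L, 6000L))
  edge <- dplyr::mutate(ann1, tss = 500L)
  w2 <- promoter_windows(edge, flank = 1000, chrom_lengths = c(chr1 = 10000L))
  expect_equal(c(w2$start, w2$end), c(0L, 1500L))
  expect_error(promoter_windows(ann1, flank = 0), "positive")
  expect_error(promoter_windows(edge, flank = 1000, chrom_lengths = c(chr2 = 1e4)),
               "missing")
})

test_that("replicate combination sums raw coverage per bp", {
  r1 <- flat_track(2, start = 0L, end = 100L)
  r2 <- flat_track(3, start = 50L, end = 150L)
  comb <- combine_replicates(list(r1, r2))
  expect_equal(track_value_at(comb, "chr1", c(10, 60, 120, 160)),
               c(2, 5, 3, 0))
  single <- combine_replicates(list(r1))
  expect_equal(track_value_at(single, "chr1", 10), 2)
  expect_error(combine_replicates(list()), "non-empty")
  bad <- flat_track(1, assay = "DNAme")
  expect_error(combine_replicates(list(r1, bad)), "assays")
})

test_that("log transform is log2(x + 1)", {
  tr <- new_track(tibble::tibble(chrom = "chr1", start = c(0L, 10L, 20L),
                                 end = c(10L, 20L, 30L), value = c(0, 1, 7)))
  expect_equal(log_signal(tr)$value, c(0, 1, 3))
  expect_error(log_signal(flat_track(-1)), "non-negative")
})

test_that("signal matrix bins means, orients minus strand, and shifts with the window", {
  # linear ramp: value = bin index over [0, 10000) in steps of 10
  ramp <- new_track(tibble::tibble(chrom = "chr1",
                                   start = seq(0L, 9990L, 10L),
                                   end = seq(10L, 10000L, 10L),
                                   value = seq(0, 999)))
  w_plus <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 4000L,
                           end = 6000L, strand = "+", tss = 5000L, flank = 1000L)
  m_plus <- signal_matrix(ramp, w_plus, bin_size = 50)
  vals <- as.numeric(m_plus[1, -1])
  expect_length(vals, 40)
  # ramp: bin means increase by exactly 5 per 50-bp bin
  expect_equal(diff(vals), rep(5, 39))
  # shifting the window by one bin shifts columns by one
  w_shift <- dplyr::mutate(w_plus, start = start + 50L, end = end + 50L,
                           tss = tss + 50L)
  m_shift <- signal_matrix(ramp, w_shift, bin_size = 50)
  expect_equal(as.numeric(m_shift[1, 2:40]), vals[2:40])
  # minus strand reverses the row
  w_minus <- dplyr::mutate(w_plus, strand = "-")
  m_minus <- signal_matrix(ramp, w_minus, bin_size = 50)
  expect_equal(as.numeric(m_minus[1, -1]), rev(vals))
})

test_that("signal matrix warns and zeros rows for unknown chromosomes", {
  w <- tibble::tibble(gene_id = "g", chrom = "chrZ", start = 0L, end = 2000L,
                      strand = "+", tss = 1000L, flank = 1000L)
  expect_warning(m <- signal_matrix(flat_track(2), w), "absent")
  expect_equal(sum(as.matrix(m[, -1])), 0)
})

test_that("enrichment is the row mean and consistent with the matrix", {
  w <- promoter_windows(ann1, flank = 1000)
  m <- signal_matrix(flat_track(2), w, bin_size = 50)
  expect_equal(promoter_enrichment(m)$enrichment, 2)
  set.seed(42)
  tr <- new_track(tibble::tibble(chrom = "chr1", start = seq(4000L, 5950L, 50L),
                                 end = seq(4050L, 6000L, 50L),
                                 value = runif(40, 0, 5)))
  m2 <- signal_matrix(tr, w, bin_size = 50)
  expect_equal(promoter_enrichment(m2)$enrichment,
               mean(as.numeric(m2[1, -1])))
})

test_that("strand flip reverses the matrix row but not the enrichment", {
  set.seed(7)
  tr <- new_track(tibble::tibble(chrom = "chr1", start = seq(4000L, 5950L, 50L),
                                 end = seq(4050L, 6000L, 50L),
                                 value = runif(40, 0, 5)))
  w <- promoter_windows(ann1, flank = 1000)
  w_flip <- dplyr::mutate(w, strand = "-")
  m <- signal_matrix(tr, w); m_f <- signal_matrix(tr, w_flip)
  expect_equal(as.numeric(m_f[1, -1]), rev(as.numeric(m[1, -1])))
  expect_equal(promoter_enrichment(m)$enrichment,
               promoter_enrichment(m_f)$enrichment)
})

test_that("cpg_density and gatc_count match their definitions", {
  expect_equal(cpg_density("CGCG"), 0.5)
  expect_equal(cpg_density("ATATAT"), 0)
  expect_equal(cpg_density("acgcgt"), 2 / 6)  # case-insensitive
  expect_equal(cpg_density("CNGCG"), 1 / 5)   # N never matches
  expect_equal(gatc_count("GATCGATC"), 2L)
  expect_equal(gatc_count("GATCATC"), 1L)
  expect_equal(gatc_count("gatcNATC"), 1L)
  expect_error(cpg_density(""), "empty")
})

test_that("cpg_density equals a brute-force dinucleotide scan", {
  set.seed(99)
  seqs <- vapply(1:1000, function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), sample(10:80, 1), replace = TRUE),
          collapse = "")
  }, "")
  brute <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch[-length(ch)] == "C" & ch[-1] == "G") / nchar(s)
  }, 1, USE.NAMES = FALSE)
  expect_equal(cpg_density(seqs), brute)
})

test_that("gatc normalization divides by max(count, 1)", {
  expect_equal(gatc_normalize(10, 5), 2)
  expect_equal(gatc_normalize(10, 0), 10)
  expect_equal(gatc_normalize(0, 7), 0)
  expect_error(gatc_normalize(-1, 3), "non-negative")
})

test_that("peak overlap uses half-open semantics", {
  w <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 1000L, end = 3000L,
                      strand = "+", tss = 2000L, flank = 1000L)
  touching <- tibble::tibble(chrom = "chr1", start = 900L, end = 1000L)
  overlapping <- tibble::tibble(chrom = "chr1", start = 900L, end = 1100L)
  expect_false(peak_promoter_overlap(w, touching)$present)
  expect_true(peak_promoter_overlap(w, overlapping)$present)
  expect_false(peak_promoter_overlap(w, overlapping[0, ])$present)
})

test_that("breadth takes the widest unclipped peak; asymmetry is strand-signed", {
  w <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 1000L, end = 3000L,
                      strand = "+", tss = 2000L, flank = 1000L)
  centered <- tibble::tibble(chrom = "chr1", start = 1800L, end = 2200L)
  expect_equal(peak_breadth_asymmetry(w, centered)$asymmetry, 0)
  downstream <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2600L)
  r <- peak_breadth_asymmetry(w, downstream)
  expect_equal(r$asymmetry, 1)
  expect_equal(r$breadth, 600)
  w_minus <- dplyr::mutate(w, strand = "-")
  expect_equal(peak_breadth_asymmetry(w_minus, downstream)$asymmetry, -1)
  two <- tibble::tibble(chrom = "chr1", start = c(1900L, 1500L),
                        end = c(2200L, 2300L))
  expect_equal(peak_breadth_asymmetry(w, two)$breadth, 800)
  none <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
  r0 <- peak_breadth_asymmetry(w, none)
  expect_equal(c(r0$breadth, r0$asymmetry), c(0, 0))
})
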