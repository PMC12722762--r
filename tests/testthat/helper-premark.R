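# Shared fixtures. The default-scale dataset (n = 2000 genes) is generated
# once per test run and reused; unit tests use small ad-hoc configs.

.premark_cache <- new.env(parent = emptyenv())

premark_test_sim <- function(noise = 1) {
  key <- paste0("sim_noise", noise)
  if (is.null(.premark_cache[[key]])) {
    .premark_cache[[key]] <- simulate_premark(premark_config(seed = 20260925L,
                                                             noise = noise))
  }
  .premark_cache[[key]]
}

premark_test_run <- function(noise = 1) {
  key <- paste0("run_noise", noise)
  if (is.null(.premark_cache[[key]])) {
    .premark_cache[[key]] <- premark_run(premark_test_sim(noise))
  }
  .premark_cache[[key]]
}

small_config <- function(seed = 1L, n_genes = 120L, ...) {
  premark_config(seed = seed, n_genes = n_genes, n_chroms = 2L, ...)
}

# A constant-value track on one chromosome for quantification tests.
flat_track <- function(value, chrom = "chr1", start = 0L, end = 10000L,
                       assay = "H3K4me3", stage = "preZGA", replicate = 1L) {
  new_track(tibble::tibble(chrom = chrom, start = start, end = end,
                           value = value),
            assay = assay, stage = stage, replicate = replicate)
}

# Independent O(n^2) transitive gap-clustering oracle for consensus peaks:
# flood-fill over the pairwise "gap <= maxgap" adjacency, then union spans
# of clusters with enough distinct replicates.
consensus_oracle <- function(replicate_peaks, min_support = 2L, maxgap = 150L) {
  pooled <- do.call(rbind, lapply(seq_along(replicate_peaks), function(i) {
    p <- replicate_peaks[[i]]
    if (nrow(p) == 0L) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end, rep = i)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), support = integer()))
  }
  res <- list()
  for (ch in unique(pooled$chrom)) {
    df <- pooled[pooled$chrom == ch, , drop = FALSE]
    n <- nrow(df)
    gap <- outer(df$start, df$end, `-`)      # gap[i,j] = start_i - end_j
    adj <- (gap <= maxgap) & (t(gap) <= maxgap)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      m <- df[comp == cc, , drop = FALSE]
      if (length(unique(m$rep)) >= min_support) {
        res[[length(res) + 1L]] <- tibble::tibble(
          chrom = ch, start = min(m$start), end = max(m$end),
          support = length(unique(m$rep)))
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), support = integer()))
  }
  dplyr::arrange(out, chrom, start)
}

# Exhaustive hypergeometric tail oracle for the one-sided Fisher p-value.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  xs <- a:min(m, k)
  xs <- xs[k - xs <= n & xs >= 0]
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}

# Step-up BH oracle evaluated from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}
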