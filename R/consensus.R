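# Replicate-consensus peak sets, spike-in scale factors, feature counting,
# and the differential engine for perturbation experiments.

#' Replicate-consensus peak set by transitive gap clustering
#'
#' Pools peaks from all replicates and clusters them transitively: two peaks
#' join one cluster when they overlap or are separated by a gap of at most
#' `maxgap` bp (a gap exactly equal to `maxgap` joins). Clusters supported
#' by at least `min_support` distinct replicates are emitted as the union
#' span of their members.
#'
#' @param replicate_peaks List of peak tibbles, one per replicate
#'   (`chrom`, `start`, `end`).
#' @param min_support Minimum number of distinct supporting replicates
#'   (default 2, i.e. ">= 2 out of 3").
#' @param maxgap Maximum gap in bp for peaks to cluster (default 150).
#' @return Tibble of consensus intervals with a `support` column, sorted by
#'   (`chrom`, `start`).
#' @export
consensus_peaks <- function(replicate_peaks, min_support = 2L, maxgap = 150L) {
  n_rep <- length(replicate_peaks)
  if (min_support > n_rep) abort("min_support exceeds the number of replicates")
  pooled <- imap(replicate_peaks, function(p, i) {
    if (nrow(p) == 0L) return(NULL)
    tibble(chrom = p$chrom, start = p$start, end = p$end, rep = as.integer(i))
  }) |> bind_rows()
  if (nrow(pooled) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  support = integer()))
  }
  pooled <- arrange(pooled, .data$chrom, .data$start, .data$end)
  out <- pooled |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      # sweep with running max end: start - cluster_end <= maxgap joins
      run_end <- cummax_end <- df$end[1]
      cl <- integer(nrow(df))
      cl[1] <- 1L
      cur <- 1L
      if (nrow(df) > 1L) {
        for (i in 2:nrow(df)) {
          if (df$start[i] - run_end <= maxgap) {
            run_end <- max(run_end, df$end[i])
          } else {
            cur <- cur + 1L
            run_end <- df$end[i]
          }
          cl[i] <- cur
        }
      }
      df |>
        mutate(cl = cl) |>
        group_by(.data$cl) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  support = dplyr::n_distinct(.data$rep), .groups = "drop") |>
        select(-"cl")
    }) |>
    ungroup() |>
    filter(.data$support >= min_support) |>
    arrange(.data$chrom, .data$start)
  attr(out, "min_support") <- as.integer(min_support)
  attr(out, "maxgap") <- as.integer(maxgap)
  attr(out, "n_replicates") <- n_rep
  out
}

#' Spike-in scale factors
#'
#' Scales each sample by the ratio of the smallest spike-in read count to
#' its own, so the deepest spike sample has factor 1 and no sample is scaled
#' up. Multiplying a sample's coverage by its factor equalizes spike-in
#' depth across samples.
#'
#' @param spike_reads Named numeric vector of spike-in (e.g. E. coli)
#'   aligned read counts per sample; all > 0.
#' @return Tibble with `sample`, `spike_reads`, `factor`.
#' @export
spike_in_factors <- function(spike_reads) {
  if (any(spike_reads <= 0)) abort("spike-in read counts must be positive")
  tibble(
    sample = names(spike_reads) %||% as.character(seq_along(spike_reads)),
    spike_reads = as.numeric(spike_reads),
    factor = min(spike_reads) / as.numeric(spike_reads)
  )
}

#' Total coverage per feature interval
#'
#' Sums coverage over each feature's span (the integral of the
#' piecewise-constant track over the interval), optionally multiplied by a
#' per-sample scale factor.
#'
#' @param track A `premark_track`.
#' @param features Tibble of intervals (`chrom`, `start`, `end`).
#' @param scale_factor Multiplier applied to all counts (default 1).
#' @return Numeric vector of counts, one per feature row.
#' @export
feature_counts <- function(track, features, scale_factor = 1) {
  counts <- numeric(nrow(features))
  for (ch in unique(features$chrom)) {
    fi <- which(features$chrom == ch)
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(tr) == 0L) next
    I <- .track_integral_fun(tr)
    counts[fi] <- I(features$end[fi]) - I(features$start[fi])
  }
  counts * scale_factor
}

#' Differential test between treated and control samples
#'
#' Per feature: `log2fc = log2((mean treated + 1) / (mean control + 1))` on
#' scaled counts; p from a two-sided Welch t-test on `log2(count + 1)`
#' across replicates; q from Benjamini-Hochberg over all features; calls
#' `up`/`down` when `q < alpha` with the matching fold-change sign, `ns`
#' otherwise. Features with zero variance and equal means in both
#' conditions get p = 1.
#'
#' @param counts Tibble: first column feature ids, then one numeric column
#'   per sample (already spike-in scaled if applicable).
#' @param sample_info Tibble with `sample` and `condition` (exactly two
#'   conditions; `control` must be one of them), >= 2 replicates each.
#' @param alpha FDR cutoff for calls (default 0.05).
#' @return A `premark_diff` tibble: `feature_id`, `mean_control`,
#'   `mean_treated`, `log2fc`, `p`, `q`, `call`.
#' @export
differential_test <- function(counts, sample_info, alpha = 0.05) {
  conds <- unique(sample_info$condition)
  if (length(conds) != 2L || !"control" %in% conds) {
    abort("sample_info needs exactly two conditions, one named 'control'")
  }
  treated_cond <- setdiff(conds, "control")
  ctrl_cols <- sample_info$sample[sample_info$condition == "control"]
  trt_cols <- sample_info$sample[sample_info$condition == treated_cond]
  if (length(ctrl_cols) < 2L || length(trt_cols) < 2L) {
    abort("need >= 2 replicates per condition")
  }
  cm <- as.matrix(counts[ctrl_cols])
  tm <- as.matrix(counts[trt_cols])
  lc <- log2(cm + 1)
  lt <- log2(tm + 1)
  pvals <- vapply(seq_len(nrow(cm)), function(i) {
    x <- lt[i, ]; y <- lc[i, ]
    if (sd(x) == 0 && sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    tryCatch(t.test(x, y, var.equal = FALSE)$p.value, error = function(e) 1)
  }, 1)
  mc <- rowMeans(cm)
  mt <- rowMeans(tm)
  out <- tibble(
    feature_id = counts[[1]],
    mean_control = mc,
    mean_treated = mt,
    log2fc = log2((mt + 1) / (mc + 1)),
    p = pvals,
    q = bh_fdr(pvals)
  )
  out$call <- case_when(
    out$q < alpha & out$log2fc > 0 ~ "up",
    out$q < alpha & out$log2fc < 0 ~ "down",
    .default = "ns"
  )
  class(out) <- c("premark_diff", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' @export
#' @method tidy premark_diff
tidy.premark_diff <- function(x, ...) as_tibble(x)

#' @export
#' @method glance premark_diff
glance.premark_diff <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_up = sum(x$call == "up"),
         n_down = sum(x$call == "down"),
         alpha = attr(x, "alpha"))
}

#' Volcano plot of a differential result
#'
#' @param object A `premark_diff` from [differential_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot premark_diff
autoplot.premark_diff <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(neglog_q = -log10(pmax(.data$q, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neglog_q,
                                   color = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(up = "firebrick", down = "steelblue",
                                           ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10(q)") +
    ggplot2::theme_minimal()
}

#' Annotate differential calls with RNA and dynamics groups
#'
#' Joins differential results with the RNA-dynamics and H3K4me3-dynamics
#' label tables, tallies calls per group, and reports the fraction of
#' zygotic genes (GZ + ZS) called down.
#'
#' @param results A `premark_diff` table (feature ids are gene ids).
#' @param rna_calls Output of [classify_rna()].
#' @param dynamics_calls Output of [classify_dynamics()] (with `gene_id`).
#' @return List with `annotated` (the joined table; missing labels become
#'   `"unlabeled"`), `tally_rna`, `tally_dynamics`, and
#'   `zygotic_down_fraction`.
#' @export
classify_calls <- function(results, rna_calls, dynamics_calls) {
  ann <- as_tibble(results) |>
    left_join(rna_calls |>
                select(gene_id = "gene_id", rna_group = "group", "zygotic"),
              by = c(feature_id = "gene_id")) |>
    left_join(dynamics_calls |>
                select(gene_id = "gene_id", dynamics_group = "group"),
              by = c(feature_id = "gene_id")) |>
    mutate(
      rna_group = ifelse(is.na(.data$rna_group), "unlabeled",
                         as.character(.data$rna_group)),
      dynamics_group = ifelse(is.na(.data$dynamics_group), "unlabeled",
                              as.character(.data$dynamics_group)),
      zygotic = !is.na(.data$zygotic) & .data$zygotic
    )
  tally_rna <- ann |> count(.data$rna_group, .data$call)
  tally_dyn <- ann |> count(.data$dynamics_group, .data$call)
  zyg <- ann |> filter(.data$zygotic)
  frac <- if (nrow(zyg) == 0L) NA_real_ else mean(zyg$call == "down")
  list(annotated = ann, tally_rna = tally_rna, tally_dynamics = tally_dyn,
       zygotic_down_fraction = frac)
}
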