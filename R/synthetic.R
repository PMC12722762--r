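# Fully synthetic multi-omic dataset with planted ground truth: genome
# sequence with controlled CpG/GATC composition, four-stage H3K4me3 peaks and
# coverage, DNAme and GATC-exposed accessibility tracks, wildtype expression
# across gametes and ZGA timepoints, a control/treated perturbation series,
# and CUT&RUN-style replicate peak sets with spike-in read counts.

#' Generator configuration
#'
#' All planted effect sizes and sampling regimes for [simulate_premark()].
#' Defaults emulate the statistical structure of early-embryo promoter
#' profiling: dynamics-group fractions (SHARED 0.39, ABSENT 0.48, the rest
#' dynamic), a strong GZ-SHARED coupling (P(SHARED | GZ) = 0.85), higher
#' H3K4me3 intensity and breadth for SHARED promoters, DNAme anti-correlated
#' with promoter H3K4me3, GATC-exposed accessibility, ZGA onset times spread
#' over 6-9 hpf, and a perturbation downregulating 25% of zygotic genes
#' 4-fold at 7.5 hpf.
#'
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param n_genes Number of genes (default 2000).
#' @param n_chroms Number of chromosomes genes are spread over.
#' @param gene_spacing Distance between consecutive TSSs in bp.
#' @param flank Promoter half-width in bp.
#' @param noise Scalar in \[0, 1\] scaling all technical noise (replicate
#'   lognormal noise, peak-edge jitter, Poisson coverage sampling, library
#'   factors). `noise = 0` gives a deterministic noise-free dataset from
#'   which every planted label is exactly recoverable.
#' @param dynamics_fracs Named fractions for the five dynamics groups
#'   (must sum to 1).
#' @param rna_fracs Named fractions for the four RNA groups (must sum to 1).
#' @param p_shared_given_gz Planted P(dynamics = SHARED | RNA = GZ).
#' @param p_spermatid_specific Fraction of GS genes expressed only in the
#'   spermatid.
#' @param first_hpf_probs Onset-time proportions over 6/7/8/9 hpf for
#'   zygotic genes.
#' @param down_fraction Fraction of zygotic genes downregulated by the
#'   perturbation.
#' @param down_fold Fold depletion of those genes in treated samples at
#'   7.5 hpf (half that effect at 6.5 hpf, none at 5.5 hpf).
#' @param shared_intensity,other_intensity `c(meanlog, sdlog)` of the peak
#'   intensity regimes (coverage units above background).
#' @param shared_breadth,other_breadth `c(meanlog, sdlog)` of peak breadth
#'   regimes in bp.
#' @param lambda_bg Background coverage per 50-bp bin.
#' @param sigma_rep Replicate-to-replicate lognormal sdlog on peak intensity.
#' @param jitter_sd Replicate peak-edge jitter sd in bp.
#' @param n_rep_chip,n_rep_expr,n_rep_cutrun Replicate counts.
#' @param dname_depth Coverage per bin of a fully methylated promoter.
#' @param access_scale Accessibility coverage per unit openness x GATC site.
#' @param sigma_expr Biological sdlog of expression levels.
#' @param sigma_tech Technical sdlog on expression counts (scaled by
#'   `noise`).
#' @param spike_depths Named spike-in read counts for the 6 CUT&RUN samples.
#' @return A `premark_config` list.
#' @export
premark_config <- function(
    seed = 1L,
    n_genes = 2000L,
    n_chroms = 4L,
    gene_spacing = 4000L,
    flank = 1000L,
    noise = 1,
    dynamics_fracs = c(SHARED = 0.39, ABSENT = 0.48, GAINED = 0.026,
                       LOST = 0.043, FLUCTUATING = 0.061),
    rna_fracs = c(GZ = 0.15, GS = 0.20, ZS = 0.12, ND = 0.53),
    p_shared_given_gz = 0.85,
    p_spermatid_specific = 0.3,
    first_hpf_probs = c(`6` = 183, `7` = 239, `8` = 260, `9` = 174) / 856,
    down_fraction = 0.25,
    down_fold = 4,
    shared_intensity = c(meanlog = log(30), sdlog = 0.25),
    other_intensity = c(meanlog = log(8), sdlog = 0.3),
    shared_breadth = c(meanlog = log(1500), sdlog = 0.15),
    other_breadth = c(meanlog = log(600), sdlog = 0.2),
    lambda_bg = 1,
    sigma_rep = 0.15,
    jitter_sd = 20,
    n_rep_chip = 2L,
    n_rep_expr = 3L,
    n_rep_cutrun = 3L,
    dname_depth = 20,
    access_scale = 0.05,
    sigma_expr = 0.5,
    sigma_tech = 0.1,
    spike_depths = c(control_1 = 220000, control_2 = 180000, control_3 = 200000,
                     treated_1 = 240000, treated_2 = 190000, treated_3 = 210000)) {
  cfg <- as.list(environment())
  if (abs(sum(dynamics_fracs) - 1) > 1e-6) abort("dynamics_fracs must sum to 1")
  if (abs(sum(rna_fracs) - 1) > 1e-6) abort("rna_fracs must sum to 1")
  if (abs(sum(first_hpf_probs) - 1) > 1e-6) abort("first_hpf_probs must sum to 1")
  stopifnot(noise >= 0, down_fold > 0, flank > 0)
  structure(cfg, class = "premark_config")
}

# Six planted chromatin configurations. Clusters 1-3 carry pre-ZGA H3K4me3
# (low DNAme, higher CpG), 4-6 do not. Openness/DNAme/CpG regimes are
# separated by >= ~4 within-cluster sd so the configuration is recoverable
# by k-means on z-scored features.
.premark_cluster_regimes <- function() {
  tibble(
    cluster = 1:6,
    k4_preZGA = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    openness = c(10, 4, 1.5, 6, 2, 0.7),
    dname = c(0.05, 0.15, 0.45, 0.30, 0.65, 0.90),
    cpg = c(0.090, 0.065, 0.040, 0.050, 0.020, 0.008)
  )
}

.dyn_patterns <- function() {
  pats <- vapply(0:15, function(i) {
    paste(as.integer(intToBits(i)[4:1] == 1), collapse = "")
  }, "")
  cls <- classify_dynamics(pats)
  split(pats, as.character(cls$group))
}

# lognormal draw helper honoring noise = 0 technical determinism where asked
.rln <- function(n, meanlog, sdlog) {
  if (sdlog <= 0) exp(rep(meanlog, n)) else rlnorm(n, meanlog, sdlog)
}

.rpois_or_mean <- function(lambda, noise) {
  if (noise > 0) rpois(length(lambda), lambda) else lambda
}

#' Plant per-gene ground-truth labels
#'
#' Draws the coupled label structure of the synthetic dataset: RNA dynamics
#' group, H3K4me3 dynamics group and pattern (with the planted
#' P(SHARED | GZ) coupling and marginals matching `dynamics_fracs`),
#' first-detection timepoint for zygotic genes, chromatin-configuration
#' cluster conditioned on pre-ZGA H3K4me3 presence, and perturbation
#' de_status. Used internally by [simulate_premark()]; exposed for tests.
#'
#' @param config A [premark_config()].
#' @return A tibble with one row per gene (the `SyntheticTruth` skeleton).
#' @export
plant_truth <- function(config) {
  n <- config$n_genes
  gene_id <- sprintf("gene%04d", seq_len(n))
  rna <- sample(names(config$rna_fracs), n, replace = TRUE,
                prob = config$rna_fracs)
  df <- config$dynamics_fracs
  f_gz <- mean(rna == "GZ")
  # conditional dynamics distributions preserving the target marginals
  p_sh_gz <- config$p_shared_given_gz
  rest_gz <- df[names(df) != "SHARED"]
  p_gz <- c(SHARED = unname(p_sh_gz), (1 - p_sh_gz) * rest_gz / sum(rest_gz))
  p_sh_non <- (df[["SHARED"]] - p_sh_gz * f_gz) / (1 - f_gz)
  if (p_sh_non < 0) p_sh_non <- 0
  p_non <- c(SHARED = unname(p_sh_non), (1 - p_sh_non) * rest_gz / sum(rest_gz))
  if (df[["SHARED"]] == 0) { p_gz["SHARED"] <- 0; p_gz <- p_gz / sum(p_gz) }
  dyn <- character(n)
  is_gz <- rna == "GZ"
  dyn[is_gz] <- sample(names(p_gz), sum(is_gz), replace = TRUE, prob = p_gz)
  dyn[!is_gz] <- sample(names(p_non), sum(!is_gz), replace = TRUE, prob = p_non)
  # concrete presence pattern per dynamics group
  pats <- .dyn_patterns()
  pattern <- vapply(dyn, function(g) {
    p <- pats[[g]]
    if (length(p) == 1L) p else sample(p, 1L)
  }, "")
  zygotic <- rna %in% c("GZ", "ZS")
  first_hpf <- rep(NA_integer_, n)
  first_hpf[zygotic] <- sample(c(6L, 7L, 8L, 9L), sum(zygotic), replace = TRUE,
                               prob = config$first_hpf_probs)
  spermatid_specific <- rna == "GS" & runif(n) < config$p_spermatid_specific
  # chromatin configuration conditioned on pre-ZGA H3K4me3 presence (bit 3)
  pre_present <- substr(pattern, 3, 3) == "1"
  cluster_id <- integer(n)
  cluster_id[pre_present] <- sample(1:3, sum(pre_present), replace = TRUE)
  cluster_id[!pre_present] <- sample(4:6, sum(!pre_present), replace = TRUE)
  de_status <- ifelse(zygotic & runif(n) < config$down_fraction, "down", "ns")
  reg <- .premark_cluster_regimes()
  openness <- .rln(n, log(reg$openness[cluster_id]), 0.2)
  dname_level <- rbeta(n, reg$dname[cluster_id] * 150,
                       (1 - reg$dname[cluster_id]) * 150)
  cpg_rate <- pmax(0.002, rnorm(n, reg$cpg[cluster_id], 0.004))
  gatc_planted <- round(exp(runif(n, log(5), log(120))))
  shared <- dyn == "SHARED"
  intensity <- ifelse(shared,
                      .rln(n, config$shared_intensity[1], config$shared_intensity[2]),
                      .rln(n, config$other_intensity[1], config$other_intensity[2]))
  breadth <- pmin(2600, round(ifelse(
    shared,
    .rln(n, config$shared_breadth[1], config$shared_breadth[2]),
    .rln(n, config$other_breadth[1], config$other_breadth[2]))))
  expr_level <- .rln(n, log(150), config$sigma_expr)
  tibble(
    gene_id = gene_id, rna_label = rna, dynamics_label = dyn, pattern = pattern,
    zygotic = zygotic, first_hpf = first_hpf,
    spermatid_specific = spermatid_specific, cluster_id = cluster_id,
    de_status = de_status, openness = openness, dname_level = dname_level,
    cpg_rate = cpg_rate, gatc_planted = gatc_planted,
    intensity = intensity, breadth = breadth, expr_level = expr_level
  )
}

# CG-free iid background sequence with planted CG/GATC motifs in disjoint
# 6-bp slots. Returns the chromosome sequences (character) after planting.
.build_genome <- function(truth, annotation, chrom_lengths, flank) {
  genome <- lapply(chrom_lengths, function(L) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    cg <- which(s[-L] == "C" & s[-1] == "G")
    if (length(cg) > 0L) s[cg + 1L] <- sample(c("A", "T"), length(cg), replace = TRUE)
    s
  })
  width <- 2L * flank
  slot_w <- 6L
  n_slots <- width %/% slot_w
  for (i in seq_len(nrow(annotation))) {
    ch <- annotation$chrom[i]
    w0 <- annotation$tss[i] - flank          # 0-based window start
    n_cg <- min(round(truth$cpg_rate[i] * width), n_slots - truth$gatc_planted[i])
    n_ga <- truth$gatc_planted[i]
    slots <- sample(n_slots, n_cg + n_ga)
    pos <- w0 + (slots - 1L) * slot_w + 1L    # 1-based slot starts
    cg_pos <- pos[seq_len(n_cg)]
    ga_pos <- pos[n_cg + seq_len(n_ga)]
    s <- genome[[ch]]
    s[cg_pos] <- "C"; s[cg_pos + 1L] <- "G"
    # flanking A/T bases keep motif junctions from forming spurious CpGs
    s[pmax(ga_pos - 1L, 1L)] <- "T"
    s[ga_pos] <- "G"; s[ga_pos + 1L] <- "A"; s[ga_pos + 2L] <- "T"
    s[ga_pos + 3L] <- "C"; s[ga_pos + 4L] <- "A"
    genome[[ch]] <- s
  }
  vapply(genome, paste, "", collapse = "")
}

# Peak intervals for one stage/replicate. Post-ZGA peaks of zygotic or
# GAINED genes extend downstream into the gene body (planted asymmetry).
.stage_peaks <- function(truth, annotation, stage, config, rep_jitter = TRUE) {
  bit <- match(stage, PREMARK_STAGES)
  present <- substr(truth$pattern, bit, bit) == "1"
  idx <- which(present)
  if (length(idx) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  b <- truth$breadth[idx]
  tss <- annotation$tss[idx]
  ext_genes <- stage == "postZGA" &
    (truth$zygotic[idx] | truth$dynamics_label[idx] == "GAINED")
  ext <- ifelse(ext_genes, round(0.6 * b), 0)
  jit <- function(n) {
    if (rep_jitter && config$noise > 0 && config$jitter_sd > 0) {
      round(rnorm(n, 0, config$jitter_sd * config$noise))
    } else rep(0L, n)
  }
  plus <- annotation$strand[idx] == "+"
  start <- ifelse(plus, tss - floor(b / 2), tss - floor(b / 2) - ext) + jit(length(idx))
  end <- ifelse(plus, tss + ceiling(b / 2) + ext, tss + ceiling(b / 2)) + jit(length(idx))
  tibble(chrom = annotation$chrom[idx],
         start = as.integer(pmax(0, start)),
         end = as.integer(pmax(0, start) + pmax(1, end - pmax(0, start))),
         name = truth$gene_id[idx])
}

# Binned coverage track over all promoter neighbourhoods for one assay.
# lambda_fun(i) gives the per-bin baseline for gene i; peaks add
# intensity * overlap fraction on top.
.binned_track <- function(annotation, flank, bin = 50L, lambda_gene, peaks = NULL,
                          intensity = NULL, config, assay, stage = NA, replicate = 1L) {
  n <- nrow(annotation)
  n_bins <- as.integer(2L * flank / bin)
  gidx <- rep(seq_len(n), each = n_bins)
  bs <- rep(annotation$tss, each = n_bins) - flank + rep(seq(0L, by = bin, length.out = n_bins), n)
  be <- bs + bin
  lam <- rep(lambda_gene, each = n_bins)
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    pk <- peaks[match(annotation$gene_id[gidx], peaks$name), , drop = FALSE]
    frac <- pmax(0, pmin(be, pk$end) - pmax(bs, pk$start)) / bin
    frac[is.na(frac)] <- 0
    lam <- lam + rep(intensity, each = n_bins) * frac
  }
  val <- .rpois_or_mean(lam, config$noise)
  keep <- val > 0
  new_track(
    tibble(chrom = annotation$chrom[gidx][keep],
           start = as.integer(bs[keep]), end = as.integer(be[keep]),
           value = as.numeric(val[keep])),
    assay = assay, stage = stage, replicate = replicate
  )
}

#' Generate the full synthetic dataset
#'
#' Draws planted truth via [plant_truth()], then materialises every input
#' the pipeline consumes: gene annotation, genome sequence, per-stage and
#' per-replicate H3K4me3 peak calls and coverage, DNAme and accessibility
#' coverage, wildtype expression (transcript-level counts with isoforms,
#' egg/spermatid plus nascent 6-9 hpf), the control/treated perturbation
#' count table (5.5/6.5/7.5 hpf, 3 technical replicates), CUT&RUN-style
#' replicate peak sets and spike-in read counts. Everything is reproducible
#' from `config$seed`. Use [write_premark_dataset()] to write files.
#'
#' @param config A [premark_config()].
#' @return A list with elements `config`, `truth`, `annotation`,
#'   `chrom_lengths`, `genome`, `peaks`, `tracks`, `expression`,
#'   `perturbation`, `cutrun`.
#' @export
simulate_premark <- function(config = premark_config()) {
  stopifnot(inherits(config, "premark_config"))
  set.seed(config$seed)
  n <- config$n_genes
  per_chrom <- ceiling(n / config$n_chroms)
  chrom <- paste0("chr", rep(seq_len(config$n_chroms), each = per_chrom))[seq_len(n)]
  pos_in_chrom <- sequence(rle(chrom)$lengths)
  tss <- as.integer(config$flank + 500L + (pos_in_chrom - 1L) * config$gene_spacing)
  strand <- rep(c("+", "-"), length.out = n)
  gene_len <- 1200L
  truth <- plant_truth(config)
  annotation <- tibble(
    gene_id = truth$gene_id, chrom = chrom, strand = strand,
    gene_start = ifelse(strand == "+", tss, tss - gene_len + 1L),
    gene_end = ifelse(strand == "+", tss + gene_len, tss + 1L),
    tss = tss
  )
  chrom_lengths <- annotation |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$tss) + config$flank + 500L) |>
    (\(d) setNames(as.integer(d$len), d$chrom))()

  genome <- .build_genome(truth, annotation, chrom_lengths, config$flank)
  # re-measure composition from the realised sequence; the measured GATC
  # count is the accessibility exposure the pipeline must normalise away
  windows <- promoter_windows(annotation, flank = config$flank,
                              chrom_lengths = chrom_lengths)
  seqs <- window_sequences(windows, Biostrings::DNAStringSet(genome))
  truth$cpg_measured <- cpg_density(seqs)
  truth$gatc_measured <- gatc_count(seqs)

  # H3K4me3 peaks and coverage per stage/replicate
  peaks <- list(); tracks <- list(h3k4me3 = list())
  for (stage in PREMARK_STAGES) {
    peaks[[stage]] <- list()
    tracks$h3k4me3[[stage]] <- list()
    bit <- match(stage, PREMARK_STAGES)
    present <- substr(truth$pattern, bit, bit) == "1"
    for (r in seq_len(config$n_rep_chip)) {
      pk <- .stage_peaks(truth, annotation, stage, config)
      rep_noise <- if (config$noise > 0) {
        rlnorm(n, 0, config$sigma_rep * config$noise)
      } else rep(1, n)
      inten <- ifelse(present, truth$intensity * rep_noise, 0)
      peaks[[stage]][[r]] <- pk
      tracks$h3k4me3[[stage]][[r]] <- .binned_track(
        annotation, config$flank, 50L,
        lambda_gene = rep(config$lambda_bg, n),
        peaks = pk, intensity = inten, config = config,
        assay = "H3K4me3", stage = stage, replicate = r)
    }
  }
  # DNAme and accessibility (pre-ZGA assays)
  tracks$dname <- lapply(seq_len(config$n_rep_chip), function(r) {
    .binned_track(annotation, config$flank, 50L,
                  lambda_gene = config$dname_depth * truth$dname_level,
                  config = config, assay = "DNAme", stage = "preZGA", replicate = r)
  })
  tracks$accessibility <- lapply(seq_len(config$n_rep_chip), function(r) {
    .binned_track(annotation, config$flank, 50L,
                  lambda_gene = config$access_scale * truth$openness * truth$gatc_measured,
                  config = config, assay = "accessibility", stage = "preZGA",
                  replicate = r)
  })

  expression <- .simulate_expression(truth, config)
  perturbation <- .simulate_perturbation(truth, config)

  # CUT&RUN-style wildtype replicate peak sets at the post-ZGA stage with
  # per-replicate dropout, plus spike-in depths for control/treated samples
  cutrun_peaks <- lapply(seq_len(config$n_rep_cutrun), function(r) {
    pk <- .stage_peaks(truth, annotation, "postZGA", config)
    if (config$noise > 0) pk <- pk[runif(nrow(pk)) > 0.1, , drop = FALSE]
    pk
  })
  spike <- if (config$noise > 0) {
    round(config$spike_depths * rlnorm(length(config$spike_depths), 0, 0.05 * config$noise))
  } else config$spike_depths
  list(config = config, truth = truth, annotation = annotation,
       chrom_lengths = chrom_lengths, genome = genome,
       windows = windows, peaks = peaks, tracks = tracks,
       expression = expression, perturbation = perturbation,
       cutrun = list(replicate_peaks = cutrun_peaks, spike_reads = spike))
}

# Wildtype expression: transcript-level counts with isoform structure for
# egg, spermatid (total RNA) and nascent hpf6..hpf9, n_rep_expr replicates.
.simulate_expression <- function(truth, config) {
  n <- nrow(truth)
  det <- matrix(FALSE, n, length(PREMARK_SOURCES),
                dimnames = list(truth$gene_id, PREMARK_SOURCES))
  gz <- truth$rna_label == "GZ"; gs <- truth$rna_label == "GS"
  egg <- (gz | gs) & runif(n) < 0.8
  spt <- (gz | gs) & runif(n) < 0.6
  ss <- truth$spermatid_specific
  egg[ss] <- FALSE; spt[ss] <- TRUE
  none <- (gz | gs) & !egg & !spt
  egg[none & !ss] <- TRUE
  det[, "egg"] <- egg
  det[, "spermatid"] <- spt
  for (h in 6:9) {
    det[, paste0("hpf", h)] <- truth$zygotic & !is.na(truth$first_hpf) &
      truth$first_hpf <= h
  }
  # isoform structure
  n_iso <- sample(1:3, n, replace = TRUE)
  tx <- tibble(
    gene_id = rep(truth$gene_id, n_iso),
    transcript_id = paste0(rep(truth$gene_id, n_iso), ".t",
                           sequence(n_iso)),
    length = round(runif(sum(n_iso), 500, 3000))
  )
  share <- unlist(lapply(n_iso, function(k) { s <- runif(k, 0.2, 1); s / sum(s) }))
  tx$share <- share
  samples <- tidyr::expand_grid(source = PREMARK_SOURCES,
                                replicate = seq_len(config$n_rep_expr)) |>
    mutate(sample = paste0(.data$source, "_r", .data$replicate))
  counts <- tibble(transcript_id = tx$transcript_id)
  base <- truth$expr_level
  low_meanlog <- log(0.001)
  for (i in seq_len(nrow(samples))) {
    src <- samples$source[i]
    e <- ifelse(det[, src], base, .rln(n, low_meanlog, config$sigma_expr))
    tech <- if (config$noise > 0) {
      rlnorm(nrow(tx), 0, config$sigma_tech * config$noise)
    } else rep(1, nrow(tx))
    gi <- match(tx$gene_id, truth$gene_id)
    counts[[samples$sample[i]]] <- e[gi] * tx$share * tx$length / 1000 * tech
  }
  list(transcript_counts = counts,
       tx2gene = tx[c("transcript_id", "gene_id")],
       lengths = setNames(tx$length, tx$transcript_id),
       sample_info = samples[c("sample", "source", "replicate")],
       detected = det)
}

# Perturbation series: gene-level counts, control vs treated at 5.5/6.5/7.5
# hpf, 3 technical replicates. Planted-down genes' treated samples are
# scaled by 1/down_fold at 7.5 hpf, half the effect at 6.5 hpf.
.simulate_perturbation <- function(truth, config) {
  n <- nrow(truth)
  onset <- function(hpf) {
    w <- rep(0, n)
    fh <- truth$first_hpf
    zy <- truth$zygotic & !is.na(fh)
    if (hpf == 5.5) w[zy & fh == 6] <- 0.3
    if (hpf == 6.5) { w[zy & fh == 6] <- 1; w[zy & fh == 7] <- 0.5 }
    if (hpf == 7.5) {
      w[zy & fh <= 7] <- 1; w[zy & fh == 8] <- 0.7; w[zy & fh == 9] <- 0.5
    }
    w
  }
  maternal <- ifelse(truth$rna_label %in% c("GZ", "GS"),
                     truth$expr_level * 0.8, 0)
  samples <- tidyr::expand_grid(condition = c("control", "treated"),
                                hpf = c(5.5, 6.5, 7.5),
                                replicate = 1:3) |>
    mutate(sample = sprintf("%s_%.1fhpf_r%d", .data$condition, .data$hpf,
                            .data$replicate))
  counts <- tibble(gene_id = truth$gene_id)
  down <- truth$de_status == "down"
  for (i in seq_len(nrow(samples))) {
    hpf <- samples$hpf[i]
    level <- maternal + truth$expr_level * onset(hpf)
    if (samples$condition[i] == "treated") {
      fold <- if (hpf == 7.5) 1 / config$down_fold
              else if (hpf == 6.5) 2 / config$down_fold else 1
      level[down] <- level[down] * fold
    }
    tech <- if (config$noise > 0) {
      rlnorm(n, 0, config$sigma_tech * config$noise)
    } else rep(1, n)
    counts[[samples$sample[i]]] <- level * tech
  }
  list(counts = counts,
       sample_info = samples[c("sample", "condition", "hpf", "replicate")])
}

#' Null expression tables for differential-test calibration
#'
#' Draws a gene-by-sample count table in which both conditions share one
#' lognormal mean per feature (no true effects), with the generator's
#' replicate-noise model. Used to measure the empirical false-call rate of
#' [differential_test()].
#'
#' @param n_features Number of features.
#' @param n_rep Replicates per condition.
#' @param sigma_tech Technical lognormal sdlog.
#' @return A list with `counts` and `sample_info` ready for
#'   [differential_test()].
#' @export
simulate_expression_null <- function(n_features = 300L, n_rep = 3L,
                                     sigma_tech = 0.1) {
  base <- rlnorm(n_features, log(150), 0.5)
  samples <- tidyr::expand_grid(condition = c("control", "treated"),
                                replicate = seq_len(n_rep)) |>
    mutate(sample = paste0(.data$condition, "_r", .data$replicate))
  counts <- tibble(feature_id = sprintf("f%04d", seq_len(n_features)))
  for (s in samples$sample) {
    counts[[s]] <- base * rlnorm(n_features, 0, sigma_tech)
  }
  list(counts = counts, sample_info = samples[c("sample", "condition", "replicate")])
}

#' Write a simulated dataset to disk
#'
#' Materialises the plain-text file set: genome FASTA, annotation TSV,
#' truth TSV, per-stage/replicate peak BEDs, bedGraph coverage for every
#' assay, transcript counts/lengths/tx2gene/sample tables, perturbation
#' counts, and spike-in read counts.
#'
#' @param sim Output of [simulate_premark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_premark_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), p("genome.fa"))
  write_premark_table(sim$annotation |>
                        transmute(gene_id = .data$gene_id, chrom = .data$chrom,
                                  strand = .data$strand,
                                  start = .data$gene_start + 1L,
                                  end = .data$gene_end),
                      p("annotation.tsv"))
  write_premark_table(sim$truth, p("truth.tsv"))
  for (stage in names(sim$peaks)) {
    for (r in seq_along(sim$peaks[[stage]])) {
      write_bed(sim$peaks[[stage]][[r]], p(sprintf("h3k4me3_%s_rep%d.bed", stage, r)))
      write_bedgraph(sim$tracks$h3k4me3[[stage]][[r]],
                     p(sprintf("h3k4me3_%s_rep%d.bedgraph", stage, r)))
    }
  }
  for (r in seq_along(sim$tracks$dname)) {
    write_bedgraph(sim$tracks$dname[[r]], p(sprintf("dname_rep%d.bedgraph", r)))
    write_bedgraph(sim$tracks$accessibility[[r]],
                   p(sprintf("accessibility_rep%d.bedgraph", r)))
  }
  write_premark_table(sim$expression$transcript_counts, p("transcript_counts.tsv"))
  write_premark_table(sim$expression$tx2gene, p("tx2gene.tsv"))
  write_premark_table(tibble(transcript_id = names(sim$expression$lengths),
                             length = unname(sim$expression$lengths)),
                      p("transcript_lengths.tsv"))
  write_premark_table(sim$expression$sample_info, p("expression_samples.tsv"))
  write_premark_table(sim$perturbation$counts, p("perturbation_counts.tsv"))
  write_premark_table(sim$perturbation$sample_info, p("perturbation_samples.tsv"))
  for (r in seq_along(sim$cutrun$replicate_peaks)) {
    write_bed(sim$cutrun$replicate_peaks[[r]], p(sprintf("cutrun_wt_rep%d.bed", r)))
  }
  write_premark_table(tibble(sample = names(sim$cutrun$spike_reads),
                             spike_reads = unname(sim$cutrun$spike_reads)),
                      p("spike_reads.tsv"))
  invisible(dir)
}
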