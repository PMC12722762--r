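# End-to-end orchestration: simulate (optional) -> quantify ->
# classify-dynamics -> classify-rna -> associate -> cluster -> consensus ->
# diff, with a machine-readable summary.

#' Run the full promoter-dynamics pipeline
#'
#' Executes every stage on a dataset in the layout produced by
#' [simulate_premark()] (or assembled by hand from the same components):
#' promoter quantification, H3K4me3 dynamics classification, RNA-dynamics
#' classification with first-detection timing, the dynamics x RNA
#' association grid, chromatin-configuration k-means clustering, the
#' replicate-consensus peak set with spike-in factors, and the differential
#' test on the perturbation series at its latest timepoint. When the
#' dataset carries a `truth` table, label-recovery rates are added to the
#' summary.
#'
#' @param data Dataset list (see [simulate_premark()] for the layout).
#' @param flank Promoter half-width in bp.
#' @param bin_size Signal-matrix bin width in bp.
#' @param detection_threshold Detection floor in TPM.
#' @param k Number of k-means clusters.
#' @param seed Seed for the clustering restarts.
#' @param min_support,maxgap Consensus peak-set parameters.
#' @param alpha FDR cutoff for differential calls.
#' @return A list with `features`, `dynamics`, `rna`, `first_detection`,
#'   `grid`, `clusters`, `consensus`, `scale_factors`, `differential`,
#'   `call_annotation`, and `summary` (a one-row tibble).
#' @export
premark_run <- function(data, flank = 1000L, bin_size = 50L,
                        detection_threshold = 1, k = 6L, seed = 1L,
                        min_support = 2L, maxgap = 150L, alpha = 0.05) {
  for (field in c("annotation", "genome", "peaks", "tracks", "expression",
                  "perturbation", "cutrun")) {
    if (is.null(data[[field]])) abort(paste("dataset is missing", field))
  }
  windows <- promoter_windows(data$annotation, flank = flank,
                              chrom_lengths = data$chrom_lengths)
  features <- promoter_features(
    windows,
    h3k4me3_tracks = data$tracks$h3k4me3,
    h3k4me3_peaks = data$peaks,
    dname_tracks = data$tracks$dname,
    accessibility_tracks = data$tracks$accessibility,
    genome = Biostrings::DNAStringSet(data$genome),
    bin_size = bin_size
  )
  pres <- presence_vectors(windows, data$peaks)
  dynamics <- classify_dynamics(pres)

  tpm <- tpm_normalize(
    data$expression$transcript_counts, data$expression$lengths) |>
    aggregate_isoforms(data$expression$tx2gene)
  rna <- classify_rna(tpm, data$expression$sample_info,
                      threshold = detection_threshold)
  fd <- first_detection(tpm, data$expression$sample_info,
                        threshold = detection_threshold)

  labels <- dynamics |>
    inner_join(rna, by = "gene_id", suffix = c("_dyn", "_rna")) |>
    filter(.data$group_dyn != "FLUCTUATING")
  grid <- association_grid(labels, "group_rna", "group_dyn", id_col = "gene_id")

  z <- zscore_columns(
    features |>
      mutate(log_access = log2(.data$accessibility_gatc_norm + 0.01)),
    c("h3k4me3_preZGA", "log_access", "dname_enrichment", "cpg_density"))
  rownames(z) <- features$gene_id
  clusters <- kmeans_clusters(z, k = k, seed = seed,
                              order_by = features$h3k4me3_preZGA)

  consensus <- consensus_peaks(data$cutrun$replicate_peaks,
                               min_support = min_support, maxgap = maxgap)
  sf <- spike_in_factors(data$cutrun$spike_reads)

  pert <- data$perturbation
  late <- max(pert$sample_info$hpf)
  si <- pert$sample_info[pert$sample_info$hpf == late, , drop = FALSE]
  differential <- differential_test(
    pert$counts[c(names(pert$counts)[1], si$sample)], si, alpha = alpha)
  calls <- classify_calls(differential, rna, dynamics)

  summary <- tibble(
    n_genes = nrow(features),
    n_shared = sum(dynamics$group == "SHARED"),
    n_absent = sum(dynamics$group == "ABSENT"),
    n_gained = sum(dynamics$group == "GAINED"),
    n_lost = sum(dynamics$group == "LOST"),
    n_fluctuating = sum(dynamics$group == "FLUCTUATING"),
    n_gz = sum(rna$group == "GZ"),
    n_gs = sum(rna$group == "GS"),
    n_zs = sum(rna$group == "ZS"),
    n_nd = sum(rna$group == "ND"),
    gz_shared_q = grid$q[grid$group_a == "GZ" & grid$group_b == "SHARED"],
    n_consensus_peaks = nrow(consensus),
    n_down = sum(differential$call == "down"),
    n_up = sum(differential$call == "up"),
    zygotic_down_fraction = calls$zygotic_down_fraction
  )
  if (!is.null(data$truth)) {
    tr <- data$truth
    summary$dynamics_recovery <-
      mean(as.character(dynamics$group[match(tr$gene_id, dynamics$gene_id)]) ==
             tr$dynamics_label)
    summary$rna_recovery <-
      mean(as.character(rna$group[match(tr$gene_id, rna$gene_id)]) ==
             tr$rna_label)
    fd_m <- fd$first_hpf[match(tr$gene_id, fd$gene_id)]
    summary$first_hpf_recovery <-
      mean((is.na(fd_m) & is.na(tr$first_hpf)) |
             (!is.na(fd_m) & !is.na(tr$first_hpf) & fd_m == tr$first_hpf))
  }
  list(features = features, windows = windows, dynamics = dynamics,
       rna = rna, first_detection = fd, tpm = tpm, grid = grid,
       clusters = clusters, consensus = consensus, scale_factors = sf,
       differential = differential, call_annotation = calls,
       summary = summary)
}
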