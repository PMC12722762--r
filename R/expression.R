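# Expression normalization and the ZGA expression-dynamics classifiers:
# isoform aggregation, TPM, detection calls, GZ/GS/ZS/ND grouping with the
# spermatid-specific subgroup, first-detection timing, and log2 fold changes
# against control replicates.

PREMARK_RNA_GROUPS <- c("GZ", "GS", "ZS", "ND")

#' Aggregate transcript-level values to genes
#'
#' Sums isoform rows per gene, per sample column.
#'
#' @param transcripts Tibble with `transcript_id` plus one numeric column per
#'   sample.
#' @param tx2gene Tibble with `transcript_id`, `gene_id`; every transcript in
#'   `transcripts` must map to exactly one gene.
#' @return Tibble with `gene_id` plus the summed sample columns.
#' @export
aggregate_isoforms <- function(transcripts, tx2gene) {
  unmapped <- setdiff(transcripts$transcript_id, tx2gene$transcript_id)
  if (length(unmapped) > 0L) {
    abort(paste("unmapped transcripts:", paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  if (anyDuplicated(tx2gene$transcript_id)) {
    abort("a transcript maps to more than one gene")
  }
  transcripts |>
    inner_join(tx2gene, by = "transcript_id") |>
    select(-"transcript_id") |>
    group_by(.data$gene_id) |>
    summarise(across(where(is.numeric), sum), .groups = "drop")
}

#' Transcripts-per-million normalization
#'
#' `tpm_i = (count_i / len_i) / sum_j(count_j / len_j) * 1e6` per sample.
#' All-zero samples stay all-zero with a warning.
#'
#' @param counts Tibble with a feature id column (first column) plus numeric
#'   sample columns.
#' @param lengths Named numeric vector of effective lengths (bp) covering all
#'   features, or a tibble with the id column and `length`.
#' @return Tibble of the same shape on the TPM scale; every non-degenerate
#'   sample column sums to 1e6.
#' @export
tpm_normalize <- function(counts, lengths) {
  id_col <- names(counts)[1]
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths[[id_col]])
  }
  len <- unname(lengths[counts[[id_col]]])
  if (anyNA(len)) abort("length missing for some features")
  if (any(len <= 0)) abort("effective lengths must be positive")
  out <- counts
  for (s in names(counts)[-1]) {
    rate <- counts[[s]] / len
    tot <- sum(rate)
    if (tot == 0) {
      warn(sprintf("sample %s has zero counts; TPM left all-zero", s))
      next
    }
    out[[s]] <- rate / tot * 1e6
  }
  out
}

# mean TPM per (gene, source) across that source's replicates
.source_means <- function(expr, sample_info, sources = NULL) {
  id_col <- names(expr)[1]
  si <- sample_info
  if (!is.null(sources)) si <- si[si$source %in% sources, , drop = FALSE]
  miss <- setdiff(si$sample, names(expr))
  if (length(miss) > 0L) abort(paste("samples missing from matrix:", paste(miss, collapse = ", ")))
  out <- tibble(gene_id = expr[[id_col]])
  for (src in unique(si$source)) {
    cols <- si$sample[si$source == src]
    out[[src]] <- rowMeans(as.matrix(expr[cols]))
  }
  out
}

#' Detection call for one expression source
#'
#' A gene is detected in a source iff its mean TPM across that source's
#' replicates is >= `threshold` (boundary counts as detected).
#'
#' @param expr Expression tibble (first column = gene id, TPM-scale sample
#'   columns).
#' @param sample_info Tibble with `sample`, `source` (see
#'   [premark_sources()]), and optionally `condition`, `replicate`.
#' @param source Source label to test.
#' @param threshold Detection floor in TPM (default 1).
#' @return Tibble with `gene_id`, `detected`.
#' @export
detect_expression <- function(expr, sample_info, source, threshold = 1) {
  if (!source %in% sample_info$source) abort(paste("unknown source:", source))
  m <- .source_means(expr, sample_info, sources = source)
  tibble(gene_id = m$gene_id, detected = m[[source]] >= threshold)
}

#' Classify genes by gamete/zygotic expression dynamics
#'
#' Genes detected in either gamete and at any ZGA timepoint are
#' Gamete-Zygotic (GZ); detected only in gametes, Gamete-Specific (GS);
#' only at ZGA, Zygotic-Specific (ZS); nowhere, Not-Detected (ND).
#' Spermatid-Specific (SS) flags GS genes detected in the spermatid but not
#' the egg. "Zygotic genes" downstream means GZ + ZS.
#'
#' @inheritParams detect_expression
#' @param threshold Detection floor in TPM (default 1).
#' @return Tibble with `gene_id`, `group` (factor GZ/GS/ZS/ND),
#'   `spermatid_specific`, `zygotic`.
#' @export
classify_rna <- function(expr, sample_info, threshold = 1) {
  need <- c("egg", "spermatid")
  miss <- setdiff(need, sample_info$source)
  if (length(miss) > 0L) abort(paste("missing source:", paste(miss, collapse = ", ")))
  zga_sources <- intersect(PREMARK_ZGA_SOURCES, sample_info$source)
  if (length(zga_sources) == 0L) abort("no ZGA source (hpf6..hpf9) present")
  m <- .source_means(expr, sample_info, sources = c(need, zga_sources))
  egg <- m$egg >= threshold
  sperm <- m$spermatid >= threshold
  zga <- rowSums(as.matrix(m[zga_sources]) >= threshold) > 0L
  gamete <- egg | sperm
  group <- case_when(
    gamete & zga ~ "GZ",
    gamete & !zga ~ "GS",
    !gamete & zga ~ "ZS",
    .default = "ND"
  )
  out <- tibble(
    gene_id = m$gene_id,
    group = factor(group, levels = PREMARK_RNA_GROUPS),
    spermatid_specific = sperm & !egg & !zga,
    zygotic = group %in% c("GZ", "ZS")
  )
  class(out) <- c("premark_rna", class(out))
  out
}

#' @export
#' @method glance premark_rna
glance.premark_rna <- function(x, ...) {
  x |>
    count(.data$group, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n") |>
    mutate(n_zygotic = sum(x$zygotic),
           n_spermatid_specific = sum(x$spermatid_specific))
}

#' First ZGA timepoint at which each gene is detected
#'
#' @inheritParams detect_expression
#' @param threshold Detection floor in TPM (default 1).
#' @return Tibble with `gene_id` and `first_hpf` (6, 7, 8, 9 or NA when the
#'   gene is never detected during ZGA).
#' @export
first_detection <- function(expr, sample_info, threshold = 1) {
  zga_sources <- intersect(PREMARK_ZGA_SOURCES, sample_info$source)
  if (length(zga_sources) < length(PREMARK_ZGA_SOURCES)) {
    abort("all ZGA sources hpf6..hpf9 must be present")
  }
  m <- .source_means(expr, sample_info, sources = zga_sources)
  det <- as.matrix(m[PREMARK_ZGA_SOURCES]) >= threshold
  hpf <- c(6L, 7L, 8L, 9L)
  first <- apply(det, 1L, function(x) if (any(x)) hpf[which(x)[1]] else NA_integer_)
  tibble(gene_id = m$gene_id, first_hpf = as.integer(first))
}

#' Log2 fold change against mean control expression
#'
#' `log2((treated + pseudocount) / (mean(control) + pseudocount))` on the
#' TPM scale.
#'
#' @param treated Numeric vector of treated values (one per feature).
#' @param control Numeric matrix or vector of control replicate values; for a
#'   matrix, rows are features and the row mean is used.
#' @param pseudocount Added to both sides before the ratio (default 1).
#' @return Numeric vector of log2 fold changes.
#' @export
log2fc_vs_control <- function(treated, control, pseudocount = 1) {
  if (is.matrix(control) || is.data.frame(control)) {
    control <- rowMeans(as.matrix(control))
  } else if (length(control) != length(treated) && length(treated) == 1L) {
    control <- mean(control)
  }
  if (any(treated < 0) || any(control < 0)) abort("expression values must be non-negative")
  log2((treated + pseudocount) / (control + pseudocount))
}
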