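# Promoter-window quantification: oriented TSS signal matrices, enrichment,
# peak overlap/breadth/asymmetry, CpG and GATC sequence features, and the
# GATC normalization of DamID-style accessibility.

#' Derive promoter windows around each TSS
#'
#' One window per gene, nominally `tss - flank .. tss + flank` (0-based
#' half-open), clipped at chromosome edges when `chrom_lengths` is supplied.
#'
#' @param genes Gene table from [read_gene_annotation()].
#' @param flank Half-width in bp (default 1000, i.e. TSS +/- 1 kb).
#' @param chrom_lengths Optional named integer vector of chromosome lengths;
#'   required if any window would run past an edge.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`,
#'   `flank`.
#' @export
promoter_windows <- function(genes, flank = 1000L, chrom_lengths = NULL) {
  if (flank <= 0) abort("`flank` must be positive")
  flank <- as.integer(flank)
  w <- tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = genes$tss - flank,
    end = genes$tss + flank,
    strand = genes$strand,
    tss = genes$tss,
    flank = flank
  )
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[w$chrom])
    if (anyNA(len)) abort("chromosome missing from `chrom_lengths`")
    w$end <- pmin(w$end, as.integer(len))
  }
  w$start <- pmax(w$start, 0L)
  if (any(w$end <= w$start)) abort("window entirely off chromosome")
  w
}

#' Sum coverage across replicates
#'
#' Per-bp sum of raw replicate coverages for one assay and stage, computed on
#' the union of interval breakpoints. Summation happens on the raw scale;
#' apply [log_signal()] afterwards.
#'
#' @param tracks List of `premark_track` objects sharing `assay` and `stage`.
#' @return A combined `premark_track` with `replicate = NA`.
#' @export
combine_replicates <- function(tracks) {
  if (length(tracks) == 0L) abort("`tracks` must be a non-empty list")
  assays <- unique(vapply(tracks, function(t) attr(t, "assay"), ""))
  if (length(assays) > 1L) abort("cannot combine tracks from different assays")
  stages <- unique(vapply(tracks, function(t) as.character(attr(t, "stage") %||% NA), ""))
  if (length(stages) > 1L) abort("cannot combine tracks from different stages")
  if (length(tracks) == 1L) {
    return(new_track(tracks[[1]], assay = assays, stage = stages, replicate = NA))
  }
  chroms <- unique(unlist(lapply(tracks, function(t) unique(t$chrom))))
  pieces <- lapply(chroms, function(ch) {
    subs <- lapply(tracks, function(t) t[t$chrom == ch, , drop = FALSE])
    bounds <- sort(unique(unlist(lapply(subs, function(s) c(s$start, s$end)))))
    if (length(bounds) < 2L) return(NULL)
    s <- bounds[-length(bounds)]
    e <- bounds[-1]
    mid <- s  # value at elementary interval = value at its start position
    total <- rep(0, length(s))
    for (sub in subs) {
      if (nrow(sub) == 0L) next
      j <- findInterval(mid, sub$start)
      hit <- j >= 1L
      hit[hit] <- mid[hit] < sub$end[j[hit]]
      total[hit] <- total[hit] + sub$value[j[hit]]
    }
    keep <- total != 0
    tibble(chrom = ch, start = s[keep], end = e[keep], value = total[keep])
  })
  out <- bind_rows(pieces)
  new_track(out, assay = assays, stage = stages, replicate = NA)
}

#' Log-transform a coverage track
#'
#' Maps every value to `log2(value + 1)` (pseudo-count of 1).
#'
#' @param track A `premark_track` with non-negative values.
#' @return A `premark_track` on the log2 scale.
#' @export
log_signal <- function(track) {
  if (any(track$value < 0)) abort("coverage values must be non-negative")
  out <- as_tibble(track)
  out$value <- log2(out$value + 1)
  new_track(out, assay = attr(track, "assay"), stage = attr(track, "stage"),
            replicate = attr(track, "replicate"))
}

# Cumulative-integral evaluation of a piecewise-constant track. Returns the
# integral of coverage over [0, pos) for a vector of positions; gaps between
# records contribute 0.
.track_integral_fun <- function(track_chrom) {
  s <- track_chrom$start
  e <- track_chrom$end
  v <- track_chrom$value
  wsum <- c(0, cumsum(v * (e - s)))
  function(pos) {
    j <- findInterval(pos, s)
    out <- numeric(length(pos))
    inb <- j >= 1L
    out[inb] <- wsum[j[inb]] +
      v[j[inb]] * pmin(pmax(pos[inb] - s[j[inb]], 0), e[j[inb]] - s[j[inb]])
    out
  }
}

#' Binned promoter signal matrix, oriented 5'->3'
#'
#' Averages track signal in fixed-width bins across each promoter window and
#' flips minus-strand rows so that column order always runs 5' to 3' relative
#' to the gene. Windows on chromosomes absent from the track yield all-zero
#' rows with a warning.
#'
#' @param track A `premark_track` (typically log2 scale, see [log_signal()]).
#' @param windows Promoter windows from [promoter_windows()]; all windows must
#'   share one width.
#' @param bin_size Bin width in bp (default 50).
#' @return A tibble with `gene_id` plus `bin_1 .. bin_n` columns
#'   (n = window width / bin_size); bin centers relative to the TSS are in
#'   `attr(, "bin_mid")`.
#' @export
signal_matrix <- function(track, windows, bin_size = 50L) {
  widths <- windows$end - windows$start
  if (length(unique(widths)) != 1L) {
    abort("all promoter windows must share one width (clipped windows unsupported here)")
  }
  width <- widths[1]
  n_bins <- as.integer(ceiling(width / bin_size))
  offs <- pmin(seq(0L, by = bin_size, length.out = n_bins + 1L), width)
  mat <- matrix(0, nrow = nrow(windows), ncol = n_bins)
  missing_chrom <- FALSE
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(tr) == 0L) { missing_chrom <- TRUE; next }
    I <- .track_integral_fun(tr)
    starts <- windows$start[wi]
    for (b in seq_len(n_bins)) {
      a <- starts + offs[b]
      z <- starts + offs[b + 1L]
      mat[wi, b] <- (I(z) - I(a)) / (z - a)
    }
  }
  if (missing_chrom) warn("windows on chromosomes absent from track: rows set to 0")
  neg <- windows$strand == "-"
  mat[neg, ] <- mat[neg, n_bins:1, drop = FALSE]
  out <- bind_cols(tibble(gene_id = windows$gene_id),
                   as_tibble(mat, .name_repair = ~ paste0("bin_", seq_len(n_bins))))
  attr(out, "bin_size") <- as.integer(bin_size)
  attr(out, "bin_mid") <- (offs[-length(offs)] + offs[-1]) / 2 - width / 2
  attr(out, "assay") <- attr(track, "assay")
  attr(out, "stage") <- attr(track, "stage")
  out
}

#' Per-gene promoter enrichment score
#'
#' Mean over a gene's signal-matrix bins: one scalar summarising promoter
#' signal in the TSS +/- flank window.
#'
#' @param matrix A signal matrix from [signal_matrix()].
#' @return Tibble with `gene_id` and `enrichment`.
#' @export
promoter_enrichment <- function(matrix) {
  if (nrow(matrix) == 0L) abort("empty signal matrix")
  bins <- as.matrix(matrix[grepl("^bin_", names(matrix))])
  tibble(gene_id = matrix$gene_id, enrichment = rowMeans(bins))
}

#' CpG density and GATC count of a DNA sequence
#'
#' @description
#' `cpg_density()` counts CG dinucleotide start positions divided by sequence
#' length; `gatc_count()` counts GATC motif occurrences (overlaps are
#' impossible). Both are case-insensitive; N never matches.
#'
#' @param sequence Character vector of DNA strings over \{A,C,G,T,N\}.
#' @return Numeric (density) or integer (count) vector, one per sequence.
#' @export
cpg_density <- function(sequence) {
  if (any(!nzchar(sequence))) abort("empty sequence")
  x <- Biostrings::DNAStringSet(toupper(sequence))
  Biostrings::vcountPattern("CG", x, fixed = TRUE) / Biostrings::width(x)
}

#' @rdname cpg_density
#' @export
gatc_count <- function(sequence) {
  if (any(!nzchar(sequence))) abort("empty sequence")
  x <- Biostrings::DNAStringSet(toupper(sequence))
  Biostrings::vcountPattern("GATC", x, fixed = TRUE)
}

#' Normalize accessibility enrichment to promoter GATC frequency
#'
#' DamID-style accessibility signal is organised in GATC-delimited fragments,
#' so raw promoter coverage scales with the number of GATC sites in the
#' window. Dividing by `max(gatc_count, 1)` removes this exposure.
#'
#' @param accessibility_enrichment Non-negative enrichment values
#'   (linear-scale mean coverage).
#' @param gatc_count Integer GATC counts for the same windows.
#' @return Normalized enrichment values.
#' @export
gatc_normalize <- function(accessibility_enrichment, gatc_count) {
  if (any(accessibility_enrichment < 0)) abort("enrichment must be non-negative")
  accessibility_enrichment / pmax(gatc_count, 1)
}

#' Extract promoter window sequences from a genome
#'
#' @param windows Promoter windows from [promoter_windows()].
#' @param genome A named `Biostrings::DNAStringSet` (or named character
#'   vector) of chromosome sequences.
#' @return Character vector of window sequences, one per window.
#' @export
window_sequences <- function(windows, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!all(windows$chrom %in% names(genome))) {
    abort("window chromosome missing from genome")
  }
  vapply(seq_len(nrow(windows)), function(i) {
    as.character(Biostrings::subseq(genome[[windows$chrom[i]]],
                                    start = windows$start[i] + 1L,
                                    end = windows$end[i]))
  }, "")
}

#' Binarized peak overlap at promoter windows
#'
#' A promoter is `present` iff at least one peak shares >= 1 bp with its
#' window (half-open semantics: a peak ending exactly at the window start
#' does not overlap).
#'
#' @param windows Promoter windows.
#' @param peaks Tibble of peak intervals (`chrom`, `start`, `end`).
#' @return Tibble with `gene_id`, `present` (logical), `n_peaks`.
#' @export
peak_promoter_overlap <- function(windows, peaks) {
  if (nrow(peaks) == 0L) {
    return(tibble(gene_id = windows$gene_id, present = FALSE, n_peaks = 0L))
  }
  hits <- GenomicRanges::countOverlaps(.as_granges(windows), .as_granges(peaks),
                                       minoverlap = 1L)
  tibble(gene_id = windows$gene_id, present = hits > 0L, n_peaks = as.integer(hits))
}

#' Peak breadth and strand-oriented asymmetry at promoters
#'
#' For each window, takes the single widest overlapping peak (full peak
#' width, not clipped to the window; ties broken by leftmost start).
#' Breadth is that peak's width. Asymmetry is
#' (bp strand-downstream of the TSS - bp strand-upstream) / width, in
#' \[-1, 1\]: positive values mean the peak extends into the gene body.
#' Windows without an overlapping peak get breadth 0 and asymmetry 0.
#'
#' @param windows Promoter windows (with `tss` and `strand`).
#' @param peaks Tibble of peak intervals.
#' @return Tibble with `gene_id`, `present`, `breadth`, `asymmetry`.
#' @export
peak_breadth_asymmetry <- function(windows, peaks) {
  out <- tibble(gene_id = windows$gene_id, present = FALSE,
                breadth = 0, asymmetry = 0)
  if (nrow(peaks) == 0L) return(out)
  ov <- GenomicRanges::findOverlaps(.as_granges(windows), .as_granges(peaks),
                                    minoverlap = 1L)
  if (length(ov) == 0L) return(out)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  pw <- peaks$end[sh] - peaks$start[sh]
  # widest peak per window, ties -> leftmost start
  ord <- order(qh, -pw, peaks$start[sh])
  first <- !duplicated(qh[ord])
  wi <- qh[ord][first]
  pi <- sh[ord][first]
  ps <- peaks$start[pi]; pe <- peaks$end[pi]
  tss <- windows$tss[wi]
  down <- pmax(0, pe - tss)   # bp of peak right of tss (coordinate sense)
  up <- pmax(0, tss - ps)
  asym <- (down - up) / (pe - ps)
  neg <- windows$strand[wi] == "-"
  asym[neg] <- -asym[neg]
  out$present[wi] <- TRUE
  out$breadth[wi] <- pe - ps
  out$asymmetry[wi] <- asym
  out
}

#' Quantify the full promoter feature table
#'
#' One-stop quantification feeding the chromatin-configuration clustering and
#' group summaries: per-stage H3K4me3 enrichment (log2 scale, replicates
#' summed on the raw scale first), peak breadth/asymmetry per stage (from the
#' union of replicate peak sets), DNAme enrichment (log2), accessibility
#' enrichment (linear mean coverage) with its GATC-normalized version, CpG
#' density and GATC count of the window sequence.
#'
#' @param windows Promoter windows.
#' @param h3k4me3_tracks Named list (stage -> list of replicate
#'   `premark_track`s) of raw H3K4me3 coverage.
#' @param h3k4me3_peaks Named list (stage -> list of replicate peak tibbles).
#' @param dname_tracks List of replicate DNAme coverage tracks.
#' @param accessibility_tracks List of replicate accessibility tracks.
#' @param genome Named `DNAStringSet` of chromosome sequences.
#' @param bin_size Bin width for signal matrices (default 50 bp).
#' @return A tibble keyed by `gene_id` with one column per feature
#'   (`h3k4me3_<stage>`, `breadth_<stage>`, `asymmetry_<stage>`,
#'   `present_<stage>`, `dname_enrichment`, `accessibility_enrichment`,
#'   `accessibility_gatc_norm`, `cpg_density`, `gatc_count`).
#' @export
promoter_features <- function(windows, h3k4me3_tracks, h3k4me3_peaks,
                              dname_tracks, accessibility_tracks, genome,
                              bin_size = 50L) {
  feat <- tibble(gene_id = windows$gene_id)
  for (stage in names(h3k4me3_tracks)) {
    comb <- log_signal(combine_replicates(h3k4me3_tracks[[stage]]))
    sm <- signal_matrix(comb, windows, bin_size = bin_size)
    feat[[paste0("h3k4me3_", stage)]] <- promoter_enrichment(sm)$enrichment
    pk <- bind_rows(h3k4me3_peaks[[stage]])
    ba <- peak_breadth_asymmetry(windows, pk)
    feat[[paste0("present_", stage)]] <- ba$present
    feat[[paste0("breadth_", stage)]] <- ba$breadth
    feat[[paste0("asymmetry_", stage)]] <- ba$asymmetry
  }
  dn <- log_signal(combine_replicates(dname_tracks))
  feat$dname_enrichment <-
    promoter_enrichment(signal_matrix(dn, windows, bin_size = bin_size))$enrichment
  # accessibility stays linear so GATC division removes fragment exposure
  ac <- combine_replicates(accessibility_tracks)
  feat$accessibility_enrichment <-
    promoter_enrichment(signal_matrix(ac, windows, bin_size = bin_size))$enrichment
  seqs <- window_sequences(windows, genome)
  feat$cpg_density <- cpg_density(seqs)
  feat$gatc_count <- gatc_count(seqs)
  feat$accessibility_gatc_norm <-
    gatc_normalize(feat$accessibility_enrichment, feat$gatc_count)
  feat
}
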