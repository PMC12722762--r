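# Readers and writers for the plain-text genomic formats the pipeline
# consumes. All internal coordinates are 0-based half-open (BED convention);
# 1-based inclusive inputs (GFF3, annotation TSV) are converted on ingest.

#' Read a BED file of genomic intervals
#'
#' Reads BED3/BED6 into a tibble of intervals, keeping BED's native 0-based
#' half-open coordinates verbatim and preserving input order. Lines starting
#' with `#`, `track` or `browser` are skipped.
#'
#' @param path Path to a tab-separated BED file with at least 3 columns.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpk1\t50\t+", tf)
#' read_bed(tf)
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 columns",
                  line_no[which(ncols < 3L)[1]]))
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(starts) | is.na(ends)
  if (any(bad)) {
    abort(sprintf("BED parse error at line %d: non-integer coordinates",
                  line_no[which(bad)[1]]))
  }
  bad <- ends <= starts | starts < 0L
  if (any(bad)) {
    abort(sprintf("BED parse error at line %d: end <= start or negative start",
                  line_no[which(bad)[1]]))
  }
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = starts,
    end = ends
  )
  if (all(ncols >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(ncols >= 5L)) out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (all(ncols >= 6L)) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: writes `chrom`, `start`, `end` plus any of
#' `name`, `score`, `strand` present, tab-separated without a header.
#'
#' @param intervals Tibble of intervals (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  # BED columns are positional: can't emit strand without name/score fillers
  need <- c("chrom", "start", "end")
  upto <- max(c(3L, which(c("chrom", "start", "end", "name", "score", "strand") %in% cols)))
  want <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(upto)]
  df <- as_tibble(intervals)
  for (w in setdiff(want, names(df))) df[[w]] <- if (w == "score") 0 else "."
  readr::write_tsv(df[want], path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Reads a 4-column bedGraph into a coverage track: a tibble of non-overlapping
#' 0-based half-open intervals with a non-negative `value` column. Positions
#' not covered by any record have implicit value 0. The `assay`, `stage` and
#' `replicate` labels are attached as attributes and carried through
#' downstream operations.
#'
#' @param path Path to a bedGraph file.
#' @param assay Assay label, e.g. `"H3K4me3"`, `"DNAme"`, `"accessibility"`.
#' @param stage Stage label (see [premark_stages()]).
#' @param replicate Replicate index (>= 1).
#' @return A `premark_track` tibble with columns `chrom`, `start`, `end`,
#'   `value`, sorted by chromosome and start.
#' @export
read_bedgraph <- function(path, assay = "other", stage = NA_character_,
                          replicate = 1L) {
  stopifnot(file.exists(path))
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "ciid", comment = "#", progress = FALSE)
  new_track(df, assay = assay, stage = stage, replicate = replicate)
}

#' Construct a coverage track from a data frame
#'
#' Validates bedGraph-style interval coverage (0-based half-open,
#' non-overlapping per chromosome, values >= 0) and attaches assay metadata.
#'
#' @param data Tibble with columns `chrom`, `start`, `end`, `value`.
#' @inheritParams read_bedgraph
#' @return A `premark_track` tibble sorted by (`chrom`, `start`).
#' @export
new_track <- function(data, assay = "other", stage = NA_character_,
                      replicate = 1L) {
  df <- as_tibble(data)[, c("chrom", "start", "end", "value")]
  if (any(df$value < 0)) abort("coverage values must be non-negative")
  if (any(df$end <= df$start)) abort("coverage intervals must satisfy start < end")
  df <- arrange(df, .data$chrom, .data$start)
  ov <- df |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]))
  if (any(ov$bad, na.rm = TRUE)) {
    abort(sprintf("overlapping coverage records on %s",
                  ov$chrom[which(ov$bad)[1]]))
  }
  structure(df,
            class = c("premark_track", class(df)),
            assay = assay, stage = stage, replicate = replicate)
}

#' Write a coverage track as bedGraph
#'
#' @param track A `premark_track` (see [read_bedgraph()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(as_tibble(track)[, c("chrom", "start", "end", "value")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Query a coverage track at single positions
#'
#' Piecewise-constant lookup: returns the record value covering each 0-based
#' position, 0 where no record covers it (including at a record's half-open
#' end).
#'
#' @param track A `premark_track`.
#' @param chrom Chromosome name (exact string match).
#' @param pos Integer vector of 0-based positions.
#' @return Numeric vector of coverage values.
#' @export
track_value_at <- function(track, chrom, pos) {
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tr) == 0L) return(rep(0, length(pos)))
  j <- findInterval(pos, tr$start)
  val <- rep(0, length(pos))
  hit <- j >= 1L
  hit[hit] <- pos[hit] < tr$end[j[hit]]
  val[hit] <- tr$value[j[hit]]
  val
}

#' Read gene models into a TSS-annotated gene table
#'
#' Parses gene annotation from GFF3 (`gene` features with an `ID` attribute)
#' or a 5-column TSV (`gene_id`, `chrom`, `strand`, `start`, `end`; 1-based
#' inclusive). Coordinates are converted to 0-based half-open and the TSS is
#' derived by strand: `gene_start` on `+`, `gene_end - 1` on `-`.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `gene_start`,
#'   `gene_end`, `tss` (all coordinates 0-based half-open).
#' @export
read_gene_annotation <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    req <- c("gene_id", "chrom", "strand", "start", "end")
    if (!all(req %in% names(df))) {
      abort(paste("annotation TSV must have columns:", paste(req, collapse = ", ")))
    }
    ann <- tibble(
      gene_id = as.character(df$gene_id),
      chrom = as.character(df$chrom),
      strand = as.character(df$strand),
      gene_start = as.integer(df$start) - 1L,
      gene_end = as.integer(df$end)
    )
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, length, 1L) >= 9L]
    is_gene <- vapply(f, function(x) x[[3]] == "gene", TRUE)
    f <- f[is_gene]
    if (length(f) == 0L) abort("no gene features found in GFF3")
    ids <- vapply(f, function(x) {
      m <- regmatches(x[[9]], regexpr("ID=[^;]+", x[[9]]))
      if (length(m) == 0L) NA_character_ else sub("^ID=", "", m)
    }, "")
    if (anyNA(ids)) abort("GFF3 gene feature without ID attribute")
    ann <- tibble(
      gene_id = ids,
      chrom = vapply(f, `[[`, "", 1L),
      strand = vapply(f, `[[`, "", 7L),
      gene_start = as.integer(vapply(f, `[[`, "", 4L)) - 1L,
      gene_end = as.integer(vapply(f, `[[`, "", 5L))
    )
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    abort("every gene needs strand '+' or '-'")
  }
  if (anyDuplicated(ann$gene_id)) {
    abort(sprintf("duplicate gene_id: %s",
                  ann$gene_id[anyDuplicated(ann$gene_id)]))
  }
  if (any(ann$gene_start >= ann$gene_end)) abort("gene start must precede end")
  ann$tss <- ifelse(ann$strand == "+", ann$gene_start, ann$gene_end - 1L)
  ann
}

#' Write a result table as TSV
#'
#' Writes any tibble tab-separated with a header. Numeric columns round-trip
#' through [read_premark_table()] to within 1e-9.
#'
#' @param rows A data frame; all rows must share one schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_premark_table <- function(rows, path) {
  if (!is.data.frame(rows)) abort("`rows` must be a data frame")
  readr::write_tsv(as_tibble(rows), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_premark_table
#' @export
read_premark_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

# tibble -> GRanges (0-based half-open -> 1-based inclusive)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}
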