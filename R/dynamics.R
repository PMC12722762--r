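# Classification of four-stage promoter H3K4me3 presence patterns into the
# SHARED / GAINED / LOST / ABSENT / FLUCTUATING dynamics groups.

PREMARK_DYNAMICS_GROUPS <- c("SHARED", "GAINED", "LOST", "ABSENT", "FLUCTUATING")

#' Binarized peak presence across the four stages
#'
#' For every promoter window, records whether at least one H3K4me3 peak
#' overlaps it at each of the four stages (spermatid, sperm, pre-ZGA,
#' post-ZGA). A stage's peak set is the union of its replicates' peaks
#' (set `mode = "intersection"` to require a peak in every replicate).
#'
#' @param windows Promoter windows from [promoter_windows()].
#' @param stage_peaks Named list mapping each stage in [premark_stages()] to
#'   either a peak tibble or a list of replicate peak tibbles.
#' @param mode `"union"` (default) or `"intersection"` across replicates.
#' @return Tibble with `gene_id`, one logical column per stage, and the
#'   4-character `pattern` string (e.g. `"0011"`).
#' @export
presence_vectors <- function(windows, stage_peaks, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  missing_stage <- setdiff(PREMARK_STAGES, names(stage_peaks))
  if (length(missing_stage) > 0L) {
    abort(paste("missing stage peak set:", paste(missing_stage, collapse = ", ")))
  }
  out <- tibble(gene_id = windows$gene_id)
  for (stage in PREMARK_STAGES) {
    pk <- stage_peaks[[stage]]
    if (is.data.frame(pk)) pk <- list(pk)
    if (mode == "union") {
      present <- peak_promoter_overlap(windows, bind_rows(pk))$present
    } else {
      per_rep <- lapply(pk, function(p) peak_promoter_overlap(windows, p)$present)
      present <- Reduce(`&`, per_rep)
    }
    out[[stage]] <- present
  }
  out$pattern <- apply(as.matrix(out[PREMARK_STAGES]), 1L,
                       function(x) paste(as.integer(x), collapse = ""))
  out
}

#' Classify a presence pattern into a dynamics group
#'
#' Deterministic rule over the 16 possible four-stage patterns:
#' `1111` is SHARED, `0000` is ABSENT, monotone non-increasing patterns with
#' at least one loss (`1000`, `1100`, `1110`) are LOST, monotone
#' non-decreasing patterns with at least one gain (`0001`, `0011`, `0111`)
#' are GAINED, and the eight non-monotone patterns are FLUCTUATING.
#' FLUCTUATING promoters are excluded from downstream group statistics but
#' keep their pattern string.
#'
#' @param pattern Character vector of 4-character 0/1 patterns, or a tibble
#'   from [presence_vectors()] (its `pattern` column is used).
#' @return Tibble with `pattern` and `group` (factor over the five groups);
#'   when a tibble was supplied, `gene_id` is carried through.
#' @examples
#' classify_dynamics(c("1111", "0011", "1010"))
#' @export
classify_dynamics <- function(pattern) {
  gene_id <- NULL
  if (is.data.frame(pattern)) {
    gene_id <- pattern$gene_id
    pattern <- pattern$pattern
  }
  if (!all(grepl("^[01]{4}$", pattern))) {
    abort("patterns must be 4-character strings of 0/1")
  }
  bits <- matrix(as.integer(unlist(strsplit(pattern, ""))), ncol = 4L, byrow = TRUE)
  nd <- rowSums(matrix(bits[, -1] < bits[, -4], ncol = 3L)) == 0L  # non-decreasing
  ni <- rowSums(matrix(bits[, -1] > bits[, -4], ncol = 3L)) == 0L  # non-increasing
  total <- rowSums(bits)
  group <- rep("FLUCTUATING", length(pattern))
  group[total == 4L] <- "SHARED"
  group[total == 0L] <- "ABSENT"
  group[ni & total >= 1L & total <= 3L] <- "LOST"
  group[nd & total >= 1L & total <= 3L] <- "GAINED"
  out <- tibble(pattern = pattern,
                group = factor(group, levels = PREMARK_DYNAMICS_GROUPS))
  if (!is.null(gene_id)) out <- bind_cols(tibble(gene_id = gene_id), out)
  class(out) <- c("premark_dynamics", class(out))
  out
}

#' Fraction of genes in each dynamics group
#'
#' @param calls Output of [classify_dynamics()] (or any tibble with a
#'   `group` column).
#' @return Tibble with `group`, `n`, `fraction`; fractions sum to 1 over all
#'   genes (FLUCTUATING included).
#' @export
group_ratios <- function(calls) {
  if (nrow(calls) == 0L) abort("no dynamics calls supplied")
  calls |>
    count(.data$group, .drop = FALSE, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n))
}

#' @export
#' @method glance premark_dynamics
glance.premark_dynamics <- function(x, ...) {
  group_ratios(x) |>
    select("group", "fraction") |>
    tidyr::pivot_wider(names_from = "group", values_from = "fraction") |>
    mutate(n_genes = nrow(x))
}

#' Bar chart of dynamics group ratios
#'
#' @param data Output of [classify_dynamics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_group_ratios <- function(data, ...) {
  group_ratios(data) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$group, y = .data$fraction,
                                 fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "fraction of promoters") +
    ggplot2::theme_minimal()
}
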