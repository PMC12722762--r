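# Cross-classification statistics: one-vs-rest Fisher association grids with
# BH-FDR, one-sided rank-sum comparisons, z-scored group summaries, and
# k-means chromatin-configuration clustering.

#' 2x2 contingency table of two gene sets in a universe
#'
#' @param setA,setB Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all gene ids under test.
#' @return Named integer vector `(a, b, c, d)`: `a = |A & B|`, `b = |A \ B|`,
#'   `c = |B \ A|`, `d` = the rest of the universe.
#' @export
contingency_table <- function(setA, setB, universe) {
  if (length(universe) == 0L) abort("empty universe")
  setA <- intersect(setA, universe)
  setB <- intersect(setB, universe)
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c <- length(setB) - a
  d <- length(universe) - a - b - c
  c(a = a, b = b, c = c, d = d)
}

#' One-sided Fisher's exact test for positive association
#'
#' Hypergeometric upper tail: `p = P(X >= a)` given the table's margins,
#' testing for positive association between the row and column sets. The
#' odds ratio is the sample cross-product `(a d)/(b c)`, `Inf` when
#' `b c = 0` and `a d > 0`. A table with a zero margin carries no
#' information: `p = 1`, odds ratio `NA`.
#'
#' @param a,b,c,d Non-negative cell counts (see [contingency_table()]).
#' @return Tibble with `odds_ratio` and `p`; vectorised over cells.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  m <- a + b        # size of set A
  n <- c + d        # complement of A
  k <- a + c        # size of set B
  p <- phyper(a - 1, m, n, k, lower.tail = FALSE)
  or <- ifelse(b * c > 0, (a * d) / (b * c),
               ifelse(a * d > 0, Inf, NA_real_))
  zero_margin <- m == 0 | n == 0 | k == 0 | (b + d) == 0
  p[zero_margin] <- 1
  or[zero_margin] <- NA_real_
  tibble(odds_ratio = or, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1,
#' returned in the original order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' One-vs-rest Fisher association grid between two label sets
#'
#' For every pair of groups (one from each labelling), builds the 2x2 table
#' of that group versus the rest of its labelling, runs the one-sided Fisher
#' test for positive association, and adjusts all cells of the grid jointly
#' by Benjamini-Hochberg.
#'
#' @param data Tibble with one row per gene carrying both labels (genes to
#'   exclude, e.g. FLUCTUATING promoters, should be filtered out first).
#' @param a_col,b_col Column names (strings or bare names) of the two label
#'   columns.
#' @param id_col Gene id column (default first column).
#' @return A `premark_grid` tibble in long format: `group_a`, `group_b`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p`, `q`.
#' @export
association_grid <- function(data, a_col, b_col, id_col = names(data)[1]) {
  a_col <- as_name(enquo(a_col)); b_col <- as_name(enquo(b_col))
  la <- as.character(data[[a_col]])
  lb <- as.character(data[[b_col]])
  if (anyNA(la) || anyNA(lb)) abort("every gene in the universe needs both labels")
  ids <- as.character(data[[id_col]])
  groups_a <- sort(unique(la))
  groups_b <- sort(unique(lb))
  cells <- tidyr::expand_grid(group_a = groups_a, group_b = groups_b)
  tab <- pmap(cells, function(group_a, group_b) {
    a <- sum(la == group_a & lb == group_b)
    b <- sum(la == group_a & lb != group_b)
    c <- sum(la != group_a & lb == group_b)
    d <- length(ids) - a - b - c
    tibble(a = a, b = b, c = c, d = d)
  }) |> list_rbind()
  out <- bind_cols(cells, tab)
  ft <- fisher_one_sided(out$a, out$b, out$c, out$d)
  out$odds_ratio <- ft$odds_ratio
  out$p <- ft$p
  out$q <- bh_fdr(out$p)
  class(out) <- c("premark_grid", class(out))
  attr(out, "n_genes") <- length(ids)
  out
}

#' @export
#' @method tidy premark_grid
tidy.premark_grid <- function(x, ...) as_tibble(x)

#' @export
#' @method glance premark_grid
glance.premark_grid <- function(x, ...) {
  tibble(n_cells = nrow(x), n_genes = attr(x, "n_genes"),
         n_significant = sum(x$q < 0.05), min_q = min(x$q))
}

#' Balloon-style plot of an association grid
#'
#' Dot size scales with -log10(q); filled dots mark q < 0.05.
#'
#' @param object A `premark_grid` from [association_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot premark_grid
autoplot.premark_grid <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(neglog_q = -log10(pmax(.data$q, 1e-300)),
           significant = .data$q < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group_b, y = .data$group_a,
                                   size = .data$neglog_q,
                                   color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(name = "-log10(q)") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                                name = "q < 0.05") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' One-sided Wilcoxon rank-sum test (x tends larger than y)
#'
#' Exact rank-sum distribution for small tie-free samples
#' (`|x| + |y| <= 20`); otherwise the tie-corrected normal approximation
#' with 0.5 continuity correction.
#'
#' @param x,y Numeric vectors; the alternative is that `x` is
#'   stochastically greater than `y`.
#' @return The one-sided p-value.
#' @export
wilcoxon_greater <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be non-empty")
  use_exact <- (length(x) + length(y) <= 20L) && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "greater", exact = use_exact,
                correct = TRUE)$p.value
  )
}

#' Z-score selected feature columns
#'
#' Centers and scales each column to mean 0 and population standard
#' deviation 1 (divisor n, not n-1).
#'
#' @param features Tibble of per-gene features.
#' @param columns Character vector of numeric columns to standardize.
#' @return Numeric matrix (genes x columns) with `rownames` from the first
#'   column of `features` when it is character.
#' @export
zscore_columns <- function(features, columns) {
  miss <- setdiff(columns, names(features))
  if (length(miss) > 0L) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  m <- as.matrix(features[columns])
  n <- nrow(m)
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  if (any(sigma == 0)) {
    abort(paste("constant column:", paste(columns[sigma == 0], collapse = ", ")))
  }
  z <- sweep(sweep(m, 2L, mu), 2L, sigma, `/`)
  if (is.character(features[[1]])) rownames(z) <- features[[1]]
  z
}

#' K-means chromatin-configuration clustering
#'
#' Hartigan-Wong k-means with random restarts on a z-scored feature matrix
#' (GATC density is excluded upstream by the caller's column choice).
#' Clusters are relabeled in decreasing order of `order_by` (typically mean
#' H3K4me3 enrichment) so labels are reproducible across runs.
#'
#' @param z Numeric matrix from [zscore_columns()].
#' @param k Number of clusters (default 6).
#' @param seed Integer seed for the restarts.
#' @param n_restarts Random restarts; the lowest within-cluster
#'   sum-of-squares solution wins (default 25).
#' @param order_by Numeric vector (one per row) whose cluster means define
#'   the label order; defaults to the first column of `z`.
#' @return Tibble with `gene_id` (rownames of `z`, or row index) and
#'   `cluster`; `k`, `seed` and total WCSS are attached as attributes.
#' @export
kmeans_clusters <- function(z, k = 6L, seed = 1L, n_restarts = 25L,
                            order_by = NULL) {
  if (k > nrow(z)) abort("k exceeds the number of rows")
  if (is.null(order_by)) order_by <- z[, 1]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  fit <- kmeans(z, centers = k, nstart = n_restarts, iter.max = 100L,
                algorithm = "Hartigan-Wong")
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  means <- tapply(order_by, fit$cluster, mean)
  relabel <- integer(k)
  relabel[order(means, decreasing = TRUE)] <- seq_len(k)
  out <- tibble(
    gene_id = rownames(z) %||% as.character(seq_len(nrow(z))),
    cluster = relabel[fit$cluster]
  )
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  attr(out, "wcss") <- fit$tot.withinss
  out
}

#' Z-scored group means of promoter features
#'
#' For each feature, computes the mean within each group and z-scores the
#' group means across groups (population sd). Groups with zero members are
#' dropped with a warning; features whose group means are all equal get 0s.
#'
#' @param features Tibble of per-gene features (first column = gene id).
#' @param groups Vector of group labels, one per row of `features`.
#' @param columns Feature columns to summarise (default: all numeric).
#' @return Tibble with `group` plus one z-scored column per feature.
#' @export
group_feature_summary <- function(features, groups, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(features)[vapply(features, is.numeric, TRUE)]
  }
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) abort("need at least two groups")
  df <- features[columns]
  df$group <- groups
  means <- df |>
    group_by(.data$group) |>
    summarise(across(everything(), mean), .groups = "drop")
  for (col in columns) {
    x <- means[[col]]
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    means[[col]] <- if (sigma == 0) {
      warn(sprintf("feature %s has identical group means; z-scores set to 0", col))
      rep(0, length(x))
    } else (x - mu) / sigma
  }
  means
}
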