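#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed as the median, over genes
#' with no zero count, of the ratio of the sample's count to the
#' gene's geometric mean across samples.  This is the standard
#' median-of-ratios library-size estimator for count matrices.
#'
#' @param counts integer gene x sample matrix, or a `count_matrix`.
#' @return Named numeric vector of positive size factors, one per
#'   sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m)  # ~ (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (!is.matrix(m) || any(m < 0)) {
    stop_goscape("counts must be a non-negative matrix",
                 class = "goscape_invalid_input")
  }
  ok <- rowSums(m == 0) == 0
  if (!any(ok)) {
    stop_goscape(
      "no gene has all counts > 0; median-of-ratios is infeasible",
      class = "goscape_normalization_infeasible")
  }
  mk <- m[ok, , drop = FALSE]
  geo <- exp(rowMeans(log(mk)))
  sf <- apply(mk / geo, 2, stats::median)
  stats::setNames(sf, colnames(m))
}

# rowwise means and variances, base R
.row_mean_var <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (n - 1)
  list(mean = m, var = v, n = n)
}

#' Two-group differential expression on normalized counts
#'
#' A documented simplified count-based test: counts are divided by
#' median-of-ratios size factors, the log2 fold change is the log
#' ratio of treated to control means of normalized counts (a 0.5
#' pseudocount is added to both means only when either is zero), and
#' the p-value comes from Welch's two-sample t-test on
#' `log2(normalized + 1)`.  An externally produced DE table (e.g. from
#' a negative-binomial GLM fit) can be supplied to the downstream
#' sweep instead via [read_de_table()].
#'
#' @param counts integer gene x sample matrix, or a `count_matrix`.
#' @param group 0/1 group indicator per sample (0 = control,
#'   1 = treated); taken from the `count_matrix` if omitted.
#' @param sf size factors; computed with [size_factors()] if omitted.
#' @return A `de_table` data frame with columns `gene`, `base_mean`,
#'   `log2fc`, `p` (no adjustment or rank yet; see [bh_adjust()] and
#'   [rank_genes()]).
#' @examples
#' ex <- simulate_experiment(sim_config(n_genes = 200, n_terms = 0,
#'   n_de_genes = 20, n_planted_terms = 0, seed = 2))
#' de <- de_test(ex$counts)
#' head(de)
#' @export
de_test <- function(counts, group = NULL, sf = NULL) {
  if (inherits(counts, "count_matrix")) {
    group <- group %||% counts$group
    counts <- counts$counts
  }
  if (is.null(group)) {
    stop_goscape("group labels are required",
                 class = "goscape_invalid_input")
  }
  group <- as.integer(group)
  if (!all(group %in% c(0L, 1L)) || length(group) != ncol(counts)) {
    stop_goscape("group must be a 0/1 vector, one entry per sample",
                 class = "goscape_invalid_input")
  }
  if (sum(group == 0L) < 2 || sum(group == 1L) < 2) {
    stop_goscape("each group needs >= 2 samples for a Welch test",
                 class = "goscape_degrees_of_freedom")
  }
  sf <- sf %||% size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  m0 <- rowMeans(norm[, group == 0L, drop = FALSE])
  m1 <- rowMeans(norm[, group == 1L, drop = FALSE])
  zero <- m0 == 0 | m1 == 0
  num <- ifelse(zero, m1 + 0.5, m1)
  den <- ifelse(zero, m0 + 0.5, m0)
  log2fc <- log2(num / den)

  lx <- log2(norm + 1)
  a <- .row_mean_var(lx[, group == 0L, drop = FALSE])
  b <- .row_mean_var(lx[, group == 1L, drop = FALSE])
  se2 <- a$var / a$n + b$var / b$n
  tstat <- (b$mean - a$mean) / sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) +
                 (b$var / b$n)^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # both groups constant: zero within-group variance has no t scale;
  # identical means are a perfect null, different means a perfect hit
  flat <- se2 == 0
  p[flat] <- ifelse(a$mean[flat] == b$mean[flat], 1, 0)

  structure(
    data.frame(gene = rownames(counts),
               base_mean = rowMeans(norm),
               log2fc = log2fc,
               p = p,
               row.names = NULL,
               stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical BH false-discovery-rate adjustment:
#' `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in
#' input order.  Input values must lie in `[0, 1]`.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_goscape("p-values must lie in [0, 1]",
                 class = "goscape_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Applies the selection rule: adjusted p-value at most `alpha` and
#' linear fold change strictly above `fc_threshold` in either
#' direction (`|log2fc| > log2(fc_threshold)`).  Defaults are the
#' conventional `alpha = 0.05`, `fc_threshold = 1.5`.
#'
#' @param de_table a `de_table` with a populated `padj` column.
#' @param alpha adjusted p-value cutoff (inclusive).
#' @param fc_threshold linear fold-change cutoff (exclusive, both
#'   directions).
#' @return Character vector of selected gene ids.
#' @examples
#' tab <- data.frame(gene = c("a", "b"), log2fc = c(1, 0.1),
#'                   padj = c(0.01, 0.01))
#' select_de(tab)
#' @export
select_de <- function(de_table, alpha = 0.05, fc_threshold = 1.5) {
  if (alpha <= 0 || alpha > 1 || fc_threshold < 1) {
    stop_goscape("alpha must be in (0,1] and fc_threshold >= 1",
                 class = "goscape_invalid_config")
  }
  if (is.null(de_table$padj)) {
    stop_goscape("de_table has no padj column; run bh_adjust first",
                 class = "goscape_invalid_input")
  }
  keep <- de_table$padj <= alpha &
    abs(de_table$log2fc) > log2(fc_threshold)
  de_table$gene[keep]
}

#' Rank genes by differential-expression significance
#'
#' Adds `padj` (BH over all genes, if missing) and `rank` columns.
#' Ranking is by ascending raw p-value, ties broken by larger
#' `|log2fc|`, then lexicographic gene id, so the order is total and
#' reproducible.
#'
#' @param de_table a `de_table` with `p` populated.
#' @return The table with `padj` and `rank` columns, sorted by rank.
#' @examples
#' tab <- data.frame(gene = c("a", "b", "c"), log2fc = c(1, 2, 1),
#'                   p = c(0.5, 0.001, 0.02))
#' rank_genes(tab)$gene
#' @export
rank_genes <- function(de_table) {
  if (is.null(de_table$p)) {
    stop_goscape("de_table has no p column",
                 class = "goscape_invalid_input")
  }
  if (is.null(de_table$padj)) de_table$padj <- bh_adjust(de_table$p)
  ord <- order(de_table$p, -abs(de_table$log2fc), de_table$gene)
  out <- de_table[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("de_table", "data.frame"))
}

#' Full DE stage in one call
#'
#' Runs [size_factors()], [de_test()], [bh_adjust()] and
#' [rank_genes()] and returns the ranked table.
#'
#' @inheritParams de_test
#' @return Ranked `de_table` with columns `gene`, `base_mean`,
#'   `log2fc`, `p`, `padj`, `rank`.
#' @export
de_analysis <- function(counts, group = NULL) {
  rank_genes(de_test(counts, group))
}
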