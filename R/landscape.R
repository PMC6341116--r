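#' Step grid over the significance-ranked gene list
#'
#' Builds the sequence of top-n selection sizes at which enrichment is
#' evaluated: multiples of `step_size` up to the number of genes with
#' raw p-value at most `max_alpha`, with that endpoint always
#' included.  Sweeping stops at `max_alpha` (default 0.5) so the scan
#' covers the whole range of nominal significance without walking into
#' pure noise.
#'
#' @param p raw p-values of the universe genes, in rank order.
#' @param step_size grid spacing in genes.
#' @param max_alpha raw-p cutoff defining the sweep endpoint.
#' @return Strictly increasing integer vector of selection sizes.
#' @examples
#' build_step_grid(rep(0.01, 103), step_size = 25)
#' @export
build_step_grid <- function(p, step_size = 25, max_alpha = 0.5) {
  if (length(p) == 0) {
    stop_goscape("empty universe: no ranked genes to sweep",
                 class = "goscape_empty_universe")
  }
  if (!is_count(step_size) || step_size < 1) {
    stop_goscape("step_size must be a positive integer",
                 class = "goscape_invalid_config")
  }
  if (is.unsorted(p)) {
    stop_goscape("p must be in rank (ascending) order",
                 class = "goscape_invalid_input")
  }
  end <- sum(p <= max_alpha)
  if (end < 1) end <- 1L   # degenerate: nothing nominally significant
  grid <- if (end >= step_size) {
    seq.int(step_size, end, by = step_size)
  } else integer(0)
  if (length(grid) == 0 || grid[length(grid)] != end) {
    grid <- c(grid, end)
  }
  as.integer(grid)
}

#' 2x2 contingency counts for one term at one step
#'
#' Counts underlying the per-step over-representation test: universe
#' size `N`, term size within the universe `K`, selection size `n`
#' (the top-n ranked genes) and overlap `k`.
#'
#' @param step_n selection size (top-n genes).
#' @param term term identifier.
#' @param annotation an [annotation_map].
#' @param ranked_universe character vector of universe gene ids in
#'   rank order (see [landscape_universe()]).
#' @return List of class `contingency` with fields `N`, `K`, `n`, `k`.
#' @examples
#' ann <- annotation_map(c("g1", "g2", "g3"), rep("T1", 3))
#' contingency(3, "T1", ann, c("g1", "g2", "g3", "g4"))
#' @export
contingency <- function(step_n, term, annotation, ranked_universe) {
  if (!term %in% names(annotation$term2gene)) {
    stop_goscape("unknown term '%s'", term,
                 class = "goscape_unknown_term")
  }
  N <- length(ranked_universe)
  if (step_n > N) {
    stop_goscape("step_n (%d) exceeds universe size (%d)", step_n, N,
                 class = "goscape_invalid_input")
  }
  members <- intersect(annotation$term2gene[[term]], ranked_universe)
  structure(
    list(N = N, K = length(members), n = as.integer(step_n),
         k = sum(ranked_universe[seq_len(step_n)] %in% members)),
    class = "contingency")
}

#' Hypergeometric upper-tail probability
#'
#' Exact over-representation p-value `P(X >= k)` for the overlap
#' `X ~ Hypergeometric(N, K, n)` of a size-`n` selection with a
#' size-`K` category in a size-`N` universe.  Computed via the
#' log-space tail of the hypergeometric distribution.
#'
#' @param N universe size, or a `contingency` object (then the other
#'   arguments are ignored).
#' @param K category size.
#' @param n selection size.
#' @param k observed overlap.
#' @return The one-sided p-value; 1 when `k = 0`.
#' @examples
#' hypergeom_tail(20, 5, 5, 3)  # 1126/15504
#' @export
hypergeom_tail <- function(N, K = NULL, n = NULL, k = NULL) {
  if (inherits(N, "contingency") || (is.list(N) && is.null(K))) {
    cc <- N
    N <- cc$N; K <- cc$K; n <- cc$n; k <- cc$k
  }
  bad <- anyNA(c(N, K, n, k)) | K > N | n > N | k > pmin(n, K) | k < 0
  if (any(bad)) {
    stop_goscape("inconsistent contingency counts",
                 class = "goscape_domain_error")
  }
  ifelse(k == 0, 1,
         stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Universe of a landscape sweep
#'
#' Genes eligible for the 2x2 tables: present in both the ranked DE
#' table and the annotation, returned in rank order.
#'
#' @param de_table a ranked `de_table` (see [rank_genes()]).
#' @param annotation an [annotation_map].
#' @return Character vector of gene ids in rank order.
#' @export
landscape_universe <- function(de_table, annotation) {
  if (is.null(de_table$rank)) de_table <- rank_genes(de_table)
  g <- de_table$gene[order(de_table$rank)]
  g[g %in% annotation$genes]
}

#' Fit a threshold-free enrichment landscape
#'
#' The core procedure: instead of testing over-representation at one
#' arbitrary DE cutoff, the significance-ranked gene list is swept
#' with a grid of top-n selections covering the whole range of DE
#' significance.  At every step each annotation term receives an
#' exact hypergeometric over-representation p-value, adjusted by
#' Benjamini-Hochberg across terms within the step.  A term's score
#' is its best (minimum) adjusted p-value over the sweep; because the
#' minimum is not further adjusted across steps it is reported as an
#' exploratory score.
#'
#' @param de_table a `de_table`; ranked with [rank_genes()] if the
#'   `rank` column is absent.
#' @param annotation an [annotation_map].
#' @param step_size sweep grid spacing in genes (default 25).
#' @param max_alpha raw-p endpoint of the sweep (default 0.5).
#' @param min_term_size smallest in-universe term size tested
#'   (default 3); smaller terms give unstable tails.
#' @param direction `"both"` (default) sweeps the p-ranked list;
#'   `"up"` / `"down"` restrict the list to one fold-change sign
#'   before sweeping.
#' @return An object of class `go_landscape` with elements `raw` and
#'   `adj` (term x step p-value matrices), `k` (overlap counts),
#'   `grid`, `universe`, `term_sizes`, `ranked` (the ranked universe
#'   table), `annotation` and `params`, with print, summary and plot
#'   methods.
#' @examples
#' ex <- simulate_experiment(sim_config(n_genes = 400, n_terms = 40,
#'   term_size_range = c(5, 15), n_de_genes = 60, n_planted_terms = 2,
#'   seed = 4))
#' fit <- go_landscape(de_analysis(ex$counts), ex$annotation)
#' summary(fit)[1:3, ]
#' @export
go_landscape <- function(de_table, annotation, step_size = 25,
                         max_alpha = 0.5, min_term_size = 3,
                         direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (length(annotation$terms) == 0) {
    stop_goscape("annotation is empty",
                 class = "goscape_empty_landscape")
  }
  if (is.null(de_table$rank)) de_table <- rank_genes(de_table)
  de_table <- de_table[order(de_table$rank), , drop = FALSE]
  de_table <- switch(direction,
    both = de_table,
    up   = de_table[de_table$log2fc > 0, , drop = FALSE],
    down = de_table[de_table$log2fc < 0, , drop = FALSE])

  in_univ <- de_table$gene %in% annotation$genes
  ranked <- de_table[in_univ, , drop = FALSE]
  universe <- ranked$gene
  N <- length(universe)
  if (N == 0) {
    stop_goscape("empty universe: no ranked gene is annotated",
                 class = "goscape_empty_universe")
  }
  grid <- build_step_grid(ranked$p, step_size, max_alpha)

  pos <- seq_len(N)
  names(pos) <- universe
  member_pos <- lapply(annotation$term2gene, function(g) {
    sort(unname(pos[g[g %in% universe]]))
  })
  K <- lengths(member_pos)
  eligible <- K >= min_term_size
  if (!any(eligible)) {
    stop_goscape("no term has >= %d genes in the universe",
                 min_term_size, class = "goscape_empty_landscape")
  }
  member_pos <- member_pos[eligible]
  K <- K[eligible]
  terms <- names(member_pos)

  k <- t(vapply(member_pos, function(mp) findInterval(grid, mp),
                integer(length(grid))))
  if (length(grid) == 1L) k <- matrix(k, ncol = 1L,
                                      dimnames = list(terms, NULL))
  Kmat <- matrix(K, nrow = length(terms), ncol = length(grid))
  nmat <- matrix(grid, nrow = length(terms), ncol = length(grid),
                 byrow = TRUE)
  raw <- matrix(hypergeom_tail(N, Kmat, nmat, k),
                nrow = length(terms))
  adj <- raw
  for (j in seq_len(ncol(raw))) adj[, j] <- bh_adjust(raw[, j])
  dn <- list(terms, paste0("n", grid))
  dimnames(raw) <- dimnames(adj) <- dimnames(k) <- dn

  structure(
    list(raw = raw, adj = adj, k = k, grid = grid,
         universe = universe, term_sizes = K, ranked = ranked,
         annotation = annotation,
         params = list(step_size = step_size, max_alpha = max_alpha,
                       min_term_size = min_term_size,
                       direction = direction)),
    class = "go_landscape")
}

#' Score terms over the sweep
#'
#' Per-term summary of a fitted landscape: the best (minimum)
#' within-step BH-adjusted p-value over all steps, the smallest step
#' attaining it, and the enrichment fold `(k/n) / (K/N)` at that
#' step.  The best-over-steps score is exploratory (not adjusted
#' across steps).
#'
#' @param landscape a `go_landscape` fit.
#' @return Data frame with columns `term`, `K`, `best_step`, `best_k`,
#'   `best_raw_p`, `best_adj_p`, `enrichment_fold`, ordered as in the
#'   fit.
#' @export
score_terms <- function(landscape) {
  stopifnot(inherits(landscape, "go_landscape"))
  adj <- landscape$adj
  best_col <- apply(adj, 1, which.min)   # first index ties to smallest step
  i <- seq_len(nrow(adj))
  best_n <- landscape$grid[best_col]
  best_k <- landscape$k[cbind(i, best_col)]
  N <- length(landscape$universe)
  K <- landscape$term_sizes
  data.frame(
    term = rownames(adj),
    K = unname(K),
    best_step = best_n,
    best_k = best_k,
    best_raw_p = landscape$raw[cbind(i, best_col)],
    best_adj_p = adj[cbind(i, best_col)],
    enrichment_fold = (best_k / best_n) / (unname(K) / N),
    row.names = NULL,
    stringsAsFactors = FALSE)
}

#' Select the most significant terms of the sweep
#'
#' Orders term summaries by ascending best adjusted p-value, ties by
#' smaller best step, then lexicographic term id, and returns the
#' first `top_t` term ids.
#'
#' @param summaries output of [score_terms()], or a `go_landscape`.
#' @param top_t number of terms to return.
#' @return Character vector of term ids, best first.
#' @export
select_top_terms <- function(summaries, top_t = 5) {
  if (inherits(summaries, "go_landscape")) {
    summaries <- score_terms(summaries)
  }
  if (!is_count(top_t) || top_t < 1) {
    stop_goscape("top_t must be a positive integer",
                 class = "goscape_invalid_config")
  }
  ord <- order(summaries$best_adj_p, summaries$best_step,
               summaries$term)
  utils::head(summaries$term[ord], top_t)
}

#' Most represented genes within selected terms
#'
#' For every universe gene annotated to at least one selected term,
#' counts the selected terms containing it.  Genes are ordered by
#' descending term count, then better DE rank, then id.
#'
#' @param selected_terms character vector of term ids (e.g. from
#'   [select_top_terms()]).
#' @param annotation an [annotation_map].
#' @param ranked a ranked `de_table` (rank column populated).
#' @return Data frame with columns `gene`, `n_selected_terms`,
#'   `best_rank`.
#' @export
gene_representation <- function(selected_terms, annotation, ranked) {
  if (length(selected_terms) == 0) {
    stop_goscape("selected_terms must be non-empty",
                 class = "goscape_invalid_input")
  }
  if (is.null(ranked$rank)) ranked <- rank_genes(ranked)
  members <- unlist(annotation$term2gene[selected_terms],
                    use.names = FALSE)
  members <- members[members %in% ranked$gene]
  if (length(members) == 0) {
    return(data.frame(gene = character(0),
                      n_selected_terms = integer(0),
                      best_rank = integer(0)))
  }
  cnt <- table(members)
  rk <- stats::setNames(ranked$rank, ranked$gene)
  out <- data.frame(gene = names(cnt),
                    n_selected_terms = as.integer(cnt),
                    best_rank = as.integer(rk[names(cnt)]),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$n_selected_terms, out$best_rank, out$gene), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Gene-by-term heatmap matrix
#'
#' Cell `(g, t)` is `-log10(best adjusted p of t)` when gene `g` is
#' annotated to term `t`, else 0 — each gene is shown at the maximum
#' significance its processes reach anywhere in the sweep.
#'
#' @param top_genes character vector of gene ids (row order).
#' @param top_terms character vector of term ids (column order).
#' @param summaries output of [score_terms()].
#' @param annotation an [annotation_map].
#' @return Numeric `length(top_genes)` x `length(top_terms)` matrix.
#' @export
heatmap_matrix <- function(top_genes, top_terms, summaries,
                           annotation) {
  best <- stats::setNames(summaries$best_adj_p, summaries$term)
  if (!all(top_terms %in% names(best))) {
    stop_goscape("summaries are missing some of top_terms",
                 class = "goscape_invalid_input")
  }
  m <- matrix(0, nrow = length(top_genes), ncol = length(top_terms),
              dimnames = list(top_genes, top_terms))
  for (t in top_terms) {
    hit <- top_genes %in% annotation$term2gene[[t]]
    m[hit, t] <- -log10(best[[t]])
  }
  m
}

#' @export
print.go_landscape <- function(x, ...) {
  cat(sprintf(
    "go_landscape: %d terms x %d steps (universe %d genes, grid %d..%d by %d)\n",
    nrow(x$raw), length(x$grid), length(x$universe),
    x$grid[1], x$grid[length(x$grid)], x$params$step_size))
  s <- score_terms(x)
  best <- s[order(s$best_adj_p, s$best_step, s$term), ][1, ]
  cat(sprintf("top term: %s (best adj p %.3g at step %d, %.2g-fold)\n",
              best$term, best$best_adj_p, best$best_step,
              best$enrichment_fold))
  cat("best-over-steps scores are exploratory (not adjusted across steps)\n")
  invisible(x)
}

#' Summarize a landscape fit
#'
#' @param object a `go_landscape`.
#' @param ... unused.
#' @return [score_terms()] output ordered by selection order (best
#'   adjusted p first).
#' @export
summary.go_landscape <- function(object, ...) {
  s <- score_terms(object)
  s <- s[order(s$best_adj_p, s$best_step, s$term), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Plot a landscape as a gene-by-term heatmap
#'
#' Draws the [heatmap_matrix()] of the `top_genes` most represented
#' genes within the `top_t` most significant terms; cell intensity is
#' `-log10` of the term's best adjusted p-value where the gene is
#' annotated to the term.
#'
#' @param x a `go_landscape`.
#' @param top_t number of terms to show.
#' @param top_genes number of genes to show.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return Invisibly, the plotted matrix.
#' @export
plot.go_landscape <- function(x, top_t = 5, top_genes = 25, ...) {
  terms <- select_top_terms(x, top_t)
  rep <- gene_representation(terms, x$annotation, x$ranked)
  genes <- utils::head(rep$gene, top_genes)
  m <- heatmap_matrix(genes, terms, score_terms(x), x$annotation)
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     main = "-log10(best adjusted p)", ...)
  invisible(m)
}
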