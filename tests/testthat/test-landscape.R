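# helper: a 10-gene ranked table where exactly the top 3 genes are
# nominally significant, plus an annotation putting them in one term
ranked10 <- function() {
  rank_genes(data.frame(
    gene = sprintf("g%02d", 1:10),
    log2fc = rep(1, 10),
    p = c(0.01, 0.02, 0.03, rep(0.6, 7))))
}

ann10 <- function() {
  annotation_map(
    c("g01", "g02", "g03", sprintf("g%02d", 4:10)),
    c(rep("TOP", 3), rep("REST", 7)))
}

test_that("step grid covers the significance range and keeps the endpoint", {
  expect_identical(build_step_grid(rep(0.01, 100), 25),
                   c(25L, 50L, 75L, 100L))
  expect_identical(build_step_grid(rep(0.01, 10), 25), 10L)
  expect_identical(build_step_grid(rep(0.01, 103), 25),
                   c(25L, 50L, 75L, 100L, 103L))
  # endpoint is the last gene with raw p <= max_alpha
  p <- c(rep(0.2, 30), rep(0.9, 70))
  expect_identical(build_step_grid(p, 25), c(25L, 30L))
  expect_error(build_step_grid(numeric(0), 25),
               class = "goscape_empty_universe")
})

test_that("contingency counts come straight from set overlaps", {
  ann <- ann10()
  univ <- ranked10()$gene
  cc <- contingency(3, "TOP", ann, univ)
  expect_equal(unclass(cc), list(N = 10, K = 3, n = 3L, k = 3L))
  expect_equal(contingency(3, "REST", ann, univ)$k, 0)
  expect_equal(contingency(10, "REST", ann, univ)$k, 7)
  expect_error(contingency(3, "NOPE", ann, univ),
               class = "goscape_unknown_term")
  expect_error(contingency(11, "TOP", ann, univ),
               class = "goscape_invalid_input")
})

test_that("hypergeometric tail is exact against enumeration", {
  expect_equal(hypergeom_tail(20, 5, 5, 0), 1)
  expect_equal(hypergeom_tail(20, 5, 5, 3), 1126 / 15504,
               tolerance = 1e-12)
  # full-support oracle on a modest sweep of configurations
  for (N in 1:9) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in max(0, n + K - N):min(n, K)) {
          expect_equal(hypergeom_tail(N, K, n, k),
                       bf_hyper_tail(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
  # accepts a contingency object
  cc <- contingency(3, "TOP", ann10(), ranked10()$gene)
  expect_equal(hypergeom_tail(cc), 1 / choose(10, 3),
               tolerance = 1e-12)
  expect_error(hypergeom_tail(10, 12, 3, 1),
               class = "goscape_domain_error")
})

test_that("landscape fit reproduces direct combinatorial counts", {
  fit <- go_landscape(ranked10(), ann10(), step_size = 25,
                      min_term_size = 3)
  # endpoint grid: only 3 genes have p <= 0.5
  expect_identical(fit$grid, 3L)
  expect_equal(fit$raw["TOP", 1], 1 / 120, tolerance = 1e-12)
  # a term whose members are never selected scores 1
  expect_equal(fit$raw["REST", 1], 1)
  # column-wise BH across terms
  expect_equal(as.vector(fit$adj[, 1]),
               bh_adjust(as.vector(fit$raw[, 1])), tolerance = 1e-12)
  # min_term_size excludes small terms entirely
  ann_small <- annotation_map(
    c("g01", "g02", "g03", "g04", "g05", sprintf("g%02d", 1:10)),
    c(rep("SMALL", 2), rep("MID", 3), rep("ALL", 10)))
  fit2 <- go_landscape(ranked10(), ann_small, min_term_size = 3)
  expect_false("SMALL" %in% rownames(fit2$raw))
  expect_setequal(rownames(fit2$raw), c("MID", "ALL"))
  expect_error(go_landscape(ranked10(), ann10(), min_term_size = 99),
               class = "goscape_empty_landscape")
})

test_that("every adjusted column of a fitted landscape equals BH of its raw column", {
  ex <- simulate_experiment(tiny_config(seed = 19))
  fit <- go_landscape(de_analysis(ex$counts), ex$annotation,
                      step_size = 10)
  for (j in seq_along(fit$grid)) {
    expect_equal(as.vector(fit$adj[, j]),
                 bh_adjust(as.vector(fit$raw[, j])),
                 tolerance = 1e-12)
  }
  expect_true(all(fit$raw >= 0 & fit$raw <= 1))
  expect_true(all(fit$adj >= 0 & fit$adj <= 1))
})

test_that("term scoring takes the row minimum at the smallest step", {
  mk_fit <- function(adj) {
    raw <- adj
    k <- matrix(1L, nrow(adj), ncol(adj), dimnames = dimnames(adj))
    structure(list(raw = raw, adj = adj, k = k,
                   grid = c(10L, 20L, 30L),
                   universe = sprintf("g%03d", 1:100),
                   term_sizes = stats::setNames(rep(5L, nrow(adj)),
                                                rownames(adj)),
                   ranked = NULL, annotation = NULL, params = NULL),
              class = "go_landscape")
  }
  adj <- matrix(c(0.2, 0.05, 0.01), nrow = 1,
                dimnames = list("A", NULL))
  s <- score_terms(mk_fit(adj))
  expect_equal(s$best_adj_p, 0.01)
  expect_equal(s$best_step, 30)
  # tie across steps resolves to the smaller step
  adj2 <- matrix(c(0.2, 0.01, 0.01), nrow = 1,
                 dimnames = list("A", NULL))
  expect_equal(score_terms(mk_fit(adj2))$best_step, 20)
  # constant row: first step
  adj3 <- matrix(c(1, 1, 1), nrow = 1, dimnames = list("A", NULL))
  s3 <- score_terms(mk_fit(adj3))
  expect_equal(s3$best_adj_p, 1)
  expect_equal(s3$best_step, 10)
})

test_that("term selection orders by p, step, then id", {
  s <- data.frame(term = c("T1", "T2", "T3"),
                  best_adj_p = c(0.3, 0.001, 0.02),
                  best_step = c(10, 10, 10))
  expect_identical(select_top_terms(s, 2), c("T2", "T3"))
  expect_identical(select_top_terms(s, 10), c("T2", "T3", "T1"))
  tie <- data.frame(term = c("B", "A"),
                    best_adj_p = c(0.01, 0.01),
                    best_step = c(10, 10))
  expect_identical(select_top_terms(tie, 2), c("A", "B"))
  tie2 <- data.frame(term = c("B", "A"),
                     best_adj_p = c(0.01, 0.01),
                     best_step = c(10, 20))
  expect_identical(select_top_terms(tie2, 2), c("B", "A"))
})

test_that("gene representation counts selected terms and breaks ties by rank", {
  ann <- annotation_map(
    c("x", "x", "x", "y", "y", "z", "w"),
    c("T1", "T2", "T3", "T1", "T2", "T5", "T1"))
  ranked <- rank_genes(data.frame(
    gene = c("x", "y", "z", "w"), log2fc = c(2, 1.5, 1, 0.5),
    p = c(0.001, 0.004, 0.002, 0.003)))
  rep <- gene_representation(c("T1", "T2", "T3"), ann, ranked)
  expect_identical(rep$gene, c("x", "y", "w"))  # z only in T5
  expect_identical(rep$n_selected_terms, c(3L, 2L, 1L))
  # tie on count: better (smaller) DE rank first
  ranked2 <- rank_genes(data.frame(
    gene = c("x", "y", "z", "w"), log2fc = c(2, 1.5, 1, 0.5),
    p = c(0.004, 0.001, 0.002, 0.003)))
  ann2 <- annotation_map(c("x", "x", "y", "y"),
                         c("T1", "T2", "T1", "T2"))
  rep2 <- gene_representation(c("T1", "T2"), ann2, ranked2)
  expect_identical(rep2$gene, c("y", "x"))
  expect_error(gene_representation(character(0), ann, ranked),
               class = "goscape_invalid_input")
})

test_that("heatmap cells are -log10 best p where annotated, else zero", {
  ann <- annotation_map(c("x", "y"), c("T1", "T1"))
  s <- data.frame(term = "T1", best_adj_p = 0.01, best_step = 10)
  m <- heatmap_matrix(c("x", "q"), "T1", s, ann)
  expect_equal(m["x", "T1"], 2)
  expect_equal(m["q", "T1"], 0)
  s1 <- data.frame(term = "T1", best_adj_p = 1, best_step = 10)
  expect_true(all(heatmap_matrix(c("x", "y"), "T1", s1, ann) == 0))
})

test_that("relabeling gene ids changes no p-value", {
  ex <- simulate_experiment(tiny_config(seed = 23))
  de <- de_analysis(ex$counts)
  fit <- go_landscape(de, ex$annotation, step_size = 10)

  # apply a bijection to all gene ids
  set.seed(1)
  genes <- de$gene
  relabel <- stats::setNames(sprintf("perm_%04d", sample(seq_along(genes))),
                             genes)
  de2 <- de
  de2$gene <- unname(relabel[de2$gene])
  pairs_g <- rep(names(ex$annotation$gene2term),
                 lengths(ex$annotation$gene2term))
  pairs_t <- unlist(ex$annotation$gene2term, use.names = FALSE)
  ann2 <- annotation_map(unname(relabel[pairs_g]), pairs_t)
  fit2 <- go_landscape(rank_genes(de2), ann2, step_size = 10)

  expect_identical(fit2$grid, fit$grid)
  expect_equal(fit2$raw[rownames(fit$raw), ], fit$raw,
               tolerance = 1e-12)
})

test_that("direction-restricted sweeps only see one fold-change sign", {
  ex <- simulate_experiment(tiny_config(seed = 29))
  de <- de_analysis(ex$counts)
  fit_dn <- go_landscape(de, ex$annotation, direction = "down")
  lfc <- stats::setNames(de$log2fc, de$gene)
  expect_true(all(lfc[fit_dn$universe] < 0))
  fit_up <- go_landscape(de, ex$annotation, direction = "up")
  expect_true(all(lfc[fit_up$universe] > 0))
})
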