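#' Simulation configuration
#'
#' Parameters for the synthetic two-group RNA-seq experiment used to
#' benchmark the pipeline.  The defaults emulate an aldosterone-vs-
#' vehicle whole-retina design: two groups of 3 biological replicates,
#' negative-binomial gene-level counts, one focal decorin-like gene
#' down-regulated 2.64-fold in the treated group, and a handful of
#' annotation terms whose members are enriched among the
#' differentially expressed (DE) genes.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group biological replicates per group.
#' @param baseline_mean_log_range range (log10) from which per-gene
#'   baseline mean counts are drawn uniformly; the default
#'   `c(1, 4)` spans typical expressed-gene depths (10 to 10,000).
#' @param dispersion negative-binomial dispersion `phi` in the
#'   variance function `var = mu + phi * mu^2`.
#' @param n_de_genes number of planted DE genes (0 for a null
#'   experiment with no signal).
#' @param de_log2fc_magnitude absolute log2 fold change given to
#'   planted DE genes other than the focal gene (random sign).
#' @param focal_gene_factor linear down-regulation factor of the focal
#'   gene in the treated group; the default mirrors the 2.64-fold
#'   decorin effect the benchmark recovers.
#' @param n_terms number of annotation terms to simulate.
#' @param term_size_range inclusive range of term sizes.
#' @param n_planted_terms number of terms planted as enriched.
#' @param planted_overlap_fraction minimum fraction of each planted
#'   term's members that are DE.
#' @param seed integer seed; one global seed is expanded into
#'   per-stage child seeds so each stage is reproducible on its own.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 7)
#' cfg$focal_gene_factor
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_per_group = 3,
                       baseline_mean_log_range = c(1, 4),
                       dispersion = 0.1,
                       n_de_genes = 150,
                       de_log2fc_magnitude = 1.5,
                       focal_gene_factor = 2.64,
                       n_terms = 200,
                       term_size_range = c(10, 30),
                       n_planted_terms = 5,
                       planted_overlap_fraction = 0.8,
                       seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1) {
    stop_goscape("n_genes must be a positive integer",
                 class = "goscape_invalid_config")
  }
  if (!is_count(n_samples_per_group) || n_samples_per_group < 1) {
    stop_goscape("n_samples_per_group must be a positive integer",
                 class = "goscape_invalid_config")
  }
  if (length(baseline_mean_log_range) != 2 ||
      diff(baseline_mean_log_range) < 0) {
    stop_goscape("baseline_mean_log_range must be an increasing pair",
                 class = "goscape_invalid_config")
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop_goscape("dispersion must be > 0",
                 class = "goscape_invalid_config")
  }
  if (!is_count(n_de_genes) || n_de_genes > n_genes) {
    stop_goscape("n_de_genes must be an integer in [0, n_genes]",
                 class = "goscape_invalid_config")
  }
  if (de_log2fc_magnitude <= 0 || focal_gene_factor <= 0) {
    stop_goscape("effect sizes must be positive",
                 class = "goscape_invalid_config")
  }
  if (!is_count(n_terms)) {
    stop_goscape("n_terms must be a non-negative integer",
                 class = "goscape_invalid_config")
  }
  term_size_range <- as.integer(round(term_size_range))
  if (length(term_size_range) != 2 || term_size_range[1] < 1 ||
      term_size_range[2] > n_genes || diff(term_size_range) < 0) {
    stop_goscape("term_size_range must lie within [1, n_genes]",
                 class = "goscape_invalid_config")
  }
  if (!is_count(n_planted_terms) || n_planted_terms > n_terms) {
    stop_goscape("n_planted_terms must be an integer in [0, n_terms]",
                 class = "goscape_invalid_config")
  }
  if (planted_overlap_fraction < 0 || planted_overlap_fraction > 1) {
    stop_goscape("planted_overlap_fraction must be in [0, 1]",
                 class = "goscape_invalid_config")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_samples_per_group = as.integer(n_samples_per_group),
      baseline_mean_log_range = as.numeric(baseline_mean_log_range),
      dispersion = as.numeric(dispersion),
      n_de_genes = as.integer(n_de_genes),
      de_log2fc_magnitude = as.numeric(de_log2fc_magnitude),
      focal_gene_factor = as.numeric(focal_gene_factor),
      n_terms = as.integer(n_terms),
      term_size_range = term_size_range,
      n_planted_terms = as.integer(n_planted_terms),
      planted_overlap_fraction = as.numeric(planted_overlap_fraction),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  cat(sprintf("  %d genes, %d + %d samples, NB dispersion %g\n",
              x$n_genes, x$n_samples_per_group, x$n_samples_per_group,
              x$dispersion))
  cat(sprintf("  %d DE genes (|log2FC| %g), focal factor %g down\n",
              x$n_de_genes, x$de_log2fc_magnitude, x$focal_gene_factor))
  cat(sprintf("  %d terms (sizes %d-%d), %d planted at overlap >= %g\n",
              x$n_terms, x$term_size_range[1], x$term_size_range[2],
              x$n_planted_terms, x$planted_overlap_fraction))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Simulate a flat gene-to-term annotation
#'
#' Draws `n_terms` term member sets independently: each term's size is
#' uniform on `term_size_range` and its members are sampled without
#' replacement from the `n_genes` gene universe.  Genes may belong to
#' any number of terms, including none.  No term hierarchy is modelled.
#'
#' @param n_genes number of genes in the universe.
#' @param n_terms number of terms to draw (0 gives an empty map).
#' @param term_size_range inclusive integer range of term sizes.
#' @param seed integer seed; identical inputs reproduce the map.
#' @return An [annotation_map]; the full gene universe (including
#'   unannotated genes) is available as `attr(, "ref_genes")`.
#' @examples
#' ann <- simulate_annotation(50, 20, c(5, 10), seed = 1)
#' range(ann$term_sizes)
#' @export
simulate_annotation <- function(n_genes, n_terms, term_size_range,
                                seed = 1L) {
  term_size_range <- as.integer(round(term_size_range))
  if (term_size_range[1] < 1 || term_size_range[2] > n_genes ||
      diff(term_size_range) < 0) {
    stop_goscape("term_size_range must lie within [1, n_genes]",
                 class = "goscape_invalid_config")
  }
  genes <- gene_ids(n_genes)
  pairs <- list(gene = character(0), term = character(0))
  if (n_terms > 0) {
    tids <- term_ids(n_terms)
    pairs <- with_seed(seed, {
      width <- term_size_range[2] - term_size_range[1] + 1L
      sizes <- term_size_range[1] - 1L +
        sample.int(width, n_terms, replace = TRUE)
      members <- lapply(sizes, function(k) sample(genes, k))
      list(gene = unlist(members, use.names = FALSE),
           term = rep(tids, times = sizes))
    })
  }
  out <- annotation_map(pairs$gene, pairs$term)
  attr(out, "ref_genes") <- genes
  out
}

#' Plant differential-expression and enrichment ground truth
#'
#' Selects the DE gene set, assigns signed log2 effects, chooses the
#' planted (enriched) terms and the focal gene.  For every planted
#' term at least `ceiling(planted_overlap_fraction * size)` of its
#' members are DE.  The focal gene receives log2 effect
#' `-log2(focal_gene_factor)` (down in the treated group); all other
#' DE genes receive `de_log2fc_magnitude` with random sign.
#'
#' @param annotation an [annotation_map] over the config's gene ids.
#' @param config a [sim_config].
#' @param seed integer seed; defaults to the config's truth-stage
#'   child seed.
#' @return An object of class `truth_record`: list with `beta` (named
#'   log2 effects, all genes), `de_genes`, `focal_gene`,
#'   `focal_factor`, `planted_terms`, `group` (named 0/1 sample
#'   indicator) and `samples`.
#' @examples
#' cfg <- sim_config(n_genes = 300, n_terms = 20,
#'                   term_size_range = c(5, 10), n_de_genes = 60,
#'                   n_planted_terms = 2, seed = 3)
#' ann <- simulate_annotation(300, 20, c(5, 10), seed = 3)
#' tr <- plant_signal(ann, cfg)
#' tr$focal_gene %in% tr$de_genes
#' @export
plant_signal <- function(annotation, config,
                         seed = stage_seed(config$seed, "truth")) {
  stopifnot(inherits(config, "sim_config"))
  genes <- attr(annotation, "ref_genes") %||% gene_ids(config$n_genes)
  if (length(genes) != config$n_genes) {
    stop_goscape("annotation universe does not match config n_genes",
                 class = "goscape_invalid_config")
  }
  n_de <- config$n_de_genes

  with_seed(seed, {
    planted <- character(0)
    forced <- character(0)
    if (config$n_planted_terms > 0) {
      if (length(annotation$terms) < config$n_planted_terms) {
        stop_goscape("fewer terms than n_planted_terms",
                     class = "goscape_invalid_config")
      }
      planted <- sort(sample(annotation$terms, config$n_planted_terms))
      forced_list <- lapply(planted, function(t) {
        mem <- annotation$term2gene[[t]]
        need <- ceiling(config$planted_overlap_fraction * length(mem))
        if (need == 0) character(0) else sample(mem, need)
      })
      forced <- unique(unlist(forced_list, use.names = FALSE))
    }
    if (length(forced) > n_de) {
      stop_goscape(
        "planted terms require %d DE genes but n_de_genes is %d",
        length(forced), n_de, class = "goscape_invalid_config")
    }
    pool <- setdiff(genes, forced)
    extra <- if (n_de > length(forced)) {
      sample(pool, n_de - length(forced))
    } else character(0)
    de <- c(forced, extra)
    beta <- stats::setNames(numeric(length(genes)), genes)
    focal <- NA_character_
    if (n_de > 0) {
      signs <- sample(c(-1, 1), length(de), replace = TRUE)
      beta[de] <- signs * config$de_log2fc_magnitude
      focal <- if (length(de) == 1L) de else sample(de, 1L)
      beta[focal] <- -log2(config$focal_gene_factor)
    }
    n <- config$n_samples_per_group
    samples <- c(sprintf("ctrl_%d", seq_len(n)),
                 sprintf("trt_%d", seq_len(n)))
    group <- stats::setNames(rep(c(0L, 1L), each = n), samples)
    structure(
      list(beta = beta,
           de_genes = sort(de),
           focal_gene = focal,
           focal_factor = config$focal_gene_factor,
           planted_terms = planted,
           group = group,
           samples = samples),
      class = "truth_record")
  })
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf(
    "truth_record: %d DE genes, focal %s (%.3g-fold down), %d planted terms\n",
    length(x$de_genes),
    ifelse(is.na(x$focal_gene), "<none>", x$focal_gene),
    x$focal_factor, length(x$planted_terms)))
  invisible(x)
}

#' Simulate negative-binomial counts from planted truth
#'
#' Draws gene-level integer counts
#' `K[g, j] ~ NB(mean = s_j * q_g * 2^(beta_g * x_j), dispersion = phi)`
#' with variance `mu + phi * mu^2`.  Per-gene baselines `q_g` are
#' log10-uniform on the config's baseline range; per-sample scale
#' factors `s_j` are log2-uniform on `[-0.2, 0.2]`, so library-size
#' normalization is required but benign.
#'
#' @param truth a `truth_record` from [plant_signal()].
#' @param config the matching [sim_config].
#' @param seed integer seed; defaults to the config's counts-stage
#'   child seed.
#' @return An object of class `count_matrix`: list with `counts`
#'   (integer gene x sample matrix), `group` (named 0/1 vector) and
#'   `size_factors_true` (the simulated `s_j`).
#' @examples
#' cfg <- sim_config(n_genes = 100, n_terms = 0, n_de_genes = 0,
#'                   n_planted_terms = 0, seed = 5)
#' ann <- simulate_annotation(100, 0, c(1, 1), seed = 5)
#' tr <- plant_signal(ann, cfg)
#' cm <- simulate_counts(tr, cfg)
#' dim(cm$counts)
#' @export
simulate_counts <- function(truth, config,
                            seed = stage_seed(config$seed, "counts")) {
  stopifnot(inherits(truth, "truth_record"),
            inherits(config, "sim_config"))
  genes <- names(truth$beta)
  n_g <- length(genes)
  n_s <- length(truth$samples)
  lo <- config$baseline_mean_log_range[1]
  hi <- config$baseline_mean_log_range[2]
  drawn <- with_seed(seed, {
    q <- 10^stats::runif(n_g, lo, hi)
    s <- 2^stats::runif(n_s, -0.2, 0.2)
    mu <- outer(q, s) * 2^(truth$beta %o% as.numeric(truth$group))
    counts <- matrix(
      stats::rnbinom(n_g * n_s, mu = mu, size = 1 / config$dispersion),
      nrow = n_g, dimnames = list(genes, truth$samples))
    list(counts = counts, s = s)
  })
  counts <- drawn$counts
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts,
         group = truth$group,
         size_factors_true = stats::setNames(drawn$s, truth$samples)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d vs %d)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$group == 0), sum(x$group == 1)))
  invisible(x)
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper running [simulate_annotation()],
#' [plant_signal()] and [simulate_counts()] with per-stage child seeds
#' derived from the config seed.
#'
#' @param config a [sim_config].
#' @return List of class `sim_experiment` with elements `annotation`,
#'   `truth`, `counts` and `config`.
#' @examples
#' ex <- simulate_experiment(sim_config(n_genes = 300, n_terms = 30,
#'   term_size_range = c(5, 10), n_de_genes = 60, seed = 11))
#' ex$truth$focal_gene
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ann <- simulate_annotation(config$n_genes, config$n_terms,
                             config$term_size_range,
                             seed = stage_seed(config$seed, "annotation"))
  truth <- plant_signal(ann, config)
  counts <- simulate_counts(truth, config)
  structure(list(annotation = ann, truth = truth, counts = counts,
                 config = config),
            class = "sim_experiment")
}
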