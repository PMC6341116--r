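#' Run the full analysis pipeline
#'
#' End-to-end driver: differential expression (or an externally
#' supplied DE table), gene selection at the adjusted-p/fold-change
#' thresholds, the threshold-free enrichment sweep, term and gene
#' selection, and the heatmap.  All results are written as TSV under
#' `outdir` together with a plain-text manifest; identical inputs and
#' seed give bit-identical numeric outputs.  Partial outputs are
#' removed if a stage fails.
#'
#' Exactly one of `counts` (with `groups`) or `de_table` must be
#' supplied; each may be an in-memory object or a file path.
#'
#' @param counts a `count_matrix`, or the path of a counts TSV.
#' @param groups path of the sample-to-group TSV (only when `counts`
#'   is a path).
#' @param de_table a ranked or unranked `de_table`, or the path of a
#'   DE-table TSV, replacing the count-based DE stage.
#' @param annotation an [annotation_map], or the path of a
#'   gene-to-term TSV (GAF files: read with [read_gaf_subset()]
#'   first).
#' @param outdir output directory, created if needed.
#' @param alpha,fc_threshold DE selection thresholds (see
#'   [select_de()]).
#' @param step_size,max_alpha,min_term_size,direction sweep
#'   parameters (see [go_landscape()]).
#' @param top_t,top_genes numbers of terms and genes on the heatmap.
#' @param heatmap_image write `heatmap.png` in addition to the TSV
#'   matrix.
#' @return Invisibly, a list with the fitted objects (`de`,
#'   `landscape`, `top_terms`, `gene_rep`, `heatmap`) and `files`,
#'   the named vector of written paths.
#' @examples
#' ex <- simulate_experiment(sim_config(n_genes = 300, n_terms = 30,
#'   term_size_range = c(5, 10), n_de_genes = 50, n_planted_terms = 2,
#'   seed = 9))
#' out <- run_pipeline(counts = ex$counts, annotation = ex$annotation,
#'                     outdir = tempfile(), heatmap_image = FALSE)
#' out$top_terms
#' @export
run_pipeline <- function(counts = NULL, groups = NULL,
                         de_table = NULL, annotation,
                         outdir = "goscape_out",
                         alpha = 0.05, fc_threshold = 1.5,
                         step_size = 25, max_alpha = 0.5,
                         min_term_size = 3, direction = "both",
                         top_t = 5, top_genes = 25,
                         heatmap_image = TRUE) {
  if (is.null(counts) == is.null(de_table)) {
    stop_goscape(
      "supply exactly one of counts(+groups) or de_table",
      class = "goscape_invalid_config")
  }
  if (is.character(annotation)) {
    annotation <- read_gene2term(annotation)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    written <<- c(written, stats::setNames(path, name))
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_goscape("stage '%s' failed: %s", name, conditionMessage(e),
                   class = "goscape_stage_error")
    })
  }

  de <- stage("de", {
    if (!is.null(de_table)) {
      if (is.character(de_table)) de_table <- read_de_table(de_table)
      rank_genes(de_table)
    } else {
      if (is.character(counts)) {
        if (is.null(groups)) {
          stop_goscape("a groups file is required with a counts file",
                       class = "goscape_invalid_config")
        }
        counts <- read_counts(counts, groups)
      }
      de_analysis(counts)
    }
  })
  emit("de_table.tsv", function(p) write_de_table(de, p))

  selected <- stage("select_de", select_de(de, alpha, fc_threshold))
  emit("selected_genes.txt", function(p) writeLines(selected, p))

  fit <- stage("landscape",
               go_landscape(de, annotation, step_size = step_size,
                            max_alpha = max_alpha,
                            min_term_size = min_term_size,
                            direction = direction))
  emit("landscape.tsv", function(p) write_landscape(fit, p))

  summaries <- score_terms(fit)
  top_terms <- select_top_terms(summaries, top_t)
  ord <- match(top_terms, summaries$term)
  emit("term_summary.tsv",
       function(p) .write_tsv(summaries[ord, , drop = FALSE], p))

  rep <- stage("gene_representation",
               gene_representation(top_terms, annotation, fit$ranked))
  emit("gene_representation.tsv", function(p) .write_tsv(rep, p))

  hm_genes <- utils::head(rep$gene, top_genes)
  hm <- stage("heatmap",
              heatmap_matrix(hm_genes, top_terms, summaries,
                             annotation))
  emit("heatmap.tsv", function(p) {
    .write_tsv(data.frame(gene = rownames(hm), hm,
                          check.names = FALSE,
                          stringsAsFactors = FALSE), p)
  })
  if (heatmap_image && nrow(hm) > 0) {
    emit("heatmap.png", function(p) {
      grDevices::png(p, width = 1200, height = 900, res = 150)
      on.exit(grDevices::dev.off(), add = TRUE)
      pheatmap::pheatmap(hm, cluster_rows = FALSE,
                         cluster_cols = FALSE,
                         main = "-log10(best adjusted p)")
    })
  }

  emit("manifest.txt", function(p) {
    writeLines(c(
      sprintf("goscape_version\t%s",
              as.character(utils::packageVersion("goscape"))),
      sprintf("r_version\t%s", R.version.string),
      sprintf("alpha\t%s", .fmt_num(alpha)),
      sprintf("fc_threshold\t%s", .fmt_num(fc_threshold)),
      sprintf("step_size\t%d", as.integer(step_size)),
      sprintf("max_alpha\t%s", .fmt_num(max_alpha)),
      sprintf("min_term_size\t%d", as.integer(min_term_size)),
      sprintf("direction\t%s", direction),
      sprintf("top_t\t%d", as.integer(top_t)),
      sprintf("top_genes\t%d", as.integer(top_genes)),
      sprintf("n_genes_tested\t%d", nrow(de)),
      sprintf("n_selected\t%d", length(selected)),
      sprintf("universe_size\t%d", length(fit$universe))), p)
  })

  ok <- TRUE
  invisible(list(de = de, selected = selected, landscape = fit,
                 top_terms = top_terms, gene_rep = rep, heatmap = hm,
                 files = written))
}

#' Simulate an experiment and write it to disk
#'
#' Runs [simulate_experiment()] and writes counts, group labels,
#' annotation and ground truth as TSV/text, ready for
#' [run_pipeline()].
#'
#' @param config a [sim_config].
#' @param outdir output directory, created if needed.
#' @return Invisibly, the `sim_experiment` with a `files` element of
#'   written paths.
#' @export
simulate_to_dir <- function(config = sim_config(),
                            outdir = "goscape_sim") {
  ex <- simulate_experiment(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    counts = file.path(outdir, "counts.tsv"),
    groups = file.path(outdir, "groups.tsv"),
    annotation = file.path(outdir, "annotation.tsv"),
    truth = file.path(outdir, "truth.txt"))
  write_counts(ex$counts, files[["counts"]], files[["groups"]])
  write_gene2term(ex$annotation, files[["annotation"]])
  write_truth(ex$truth, files[["truth"]])
  ex$files <- files
  invisible(ex)
}
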