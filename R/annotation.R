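#' Gene/term annotation map
#'
#' Container for a bidirectional gene-to-term membership map, the
#' structure a flat gene-to-GO annotation provides.  Both directions
#' are stored explicitly and kept exact transposes of each other;
#' duplicate (gene, term) pairs collapse to a single membership.
#'
#' @param gene character vector of gene identifiers (one per pair).
#' @param term character vector of term identifiers, same length.
#' @param term_names optional named character vector of human-readable
#'   term names, named by term id.
#'
#' @return An object of class `annotation_map` with elements
#'   `gene2term` (named list of character vectors), `term2gene`
#'   (named list), `genes`, `terms`, `term_sizes` and `term_names`.
#' @examples
#' ann <- annotation_map(c("g1", "g1", "g2"), c("T1", "T2", "T1"))
#' ann$term2gene[["T1"]]
#' @export
annotation_map <- function(gene, term, term_names = NULL) {
  if (length(gene) != length(term)) {
    stop_goscape("gene and term vectors must have equal length",
                 class = "goscape_invalid_config")
  }
  gene <- as.character(gene)
  term <- as.character(term)
  if (length(gene)) {
    keep <- !duplicated(paste0(gene, "\r", term))
    gene <- gene[keep]
    term <- term[keep]
  }
  ord <- order(gene, term)
  gene <- gene[ord]
  term <- term[ord]
  g2t <- lapply(split(term, gene), sort)
  t2g <- lapply(split(gene, term), sort)
  structure(
    list(
      gene2term  = g2t,
      term2gene  = t2g,
      genes      = sort(unique(gene)),
      terms      = sort(unique(term)),
      term_sizes = lengths(t2g),
      term_names = term_names
    ),
    class = "annotation_map"
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d genes, %d terms, %d memberships\n",
              length(x$genes), length(x$terms),
              sum(x$term_sizes)))
  if (length(x$terms)) {
    cat(sprintf("term sizes: min %d, median %g, max %d\n",
                min(x$term_sizes), stats::median(x$term_sizes),
                max(x$term_sizes)))
  }
  invisible(x)
}

# genes annotated to at least one term
annotated_genes <- function(annotation) annotation$genes
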