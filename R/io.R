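# TSV readers/writers.  All files are tab-delimited UTF-8 with '#'
# comment lines and '.' decimal; numeric columns are written with 17
# significant digits so write/read round-trips are lossless.

.fmt_num <- function(x) sprintf("%.17g", x)

.read_tsv <- function(path, header = TRUE) {
  utils::read.delim(path, header = header, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read a two-column gene-to-term annotation file
#'
#' Expects tab-separated lines `gene<TAB>term`; lines starting with
#' `#` are comments and an optional header line is detected (a first
#' line whose second field does not recur as a term is treated as
#' data — use `header = NA` for auto-detection by the conventional
#' column names `gene`/`term`).  Duplicate pairs collapse to one
#' membership.
#'
#' @param path file path.
#' @param header `TRUE`, `FALSE`, or `NA` to auto-detect a
#'   `gene<TAB>term` header line (default).
#' @return An [annotation_map]; empty files give an empty map with a
#'   warning.
#' @export
read_gene2term <- function(path, header = NA) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("annotation file '", path, "' is empty")
    return(annotation_map(character(0), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    stop_goscape("line %d of '%s' has %d fields (expected 2)",
                 bad, path, nf[bad], class = "goscape_parse_error")
  }
  if (is.na(header)) {
    header <- identical(tolower(trimws(parts[[1]])),
                        c("gene", "term"))
  }
  if (header) parts <- parts[-1]
  gene <- vapply(parts, `[`, character(1), 1)
  term <- vapply(parts, `[`, character(1), 2)
  annotation_map(gene, term)
}

#' Read a GAF 2.x annotation subset
#'
#' Minimal GO Annotation File reader: `!`-prefixed lines are
#' comments, data rows are tab-separated with at least 15 columns;
#' column 2 (DB Object ID) and column 5 (GO ID) define memberships.
#' Rows whose qualifier (column 4) contains `NOT` are skipped;
#' evidence codes are ignored.
#'
#' @param path file path.
#' @return An [annotation_map].
#' @export
read_gaf_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    warning("GAF file '", path, "' has no data rows")
    return(annotation_map(character(0), character(0)))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 15)) {
    bad <- which(nf < 15)[1]
    stop_goscape("line %d of '%s' has %d columns (GAF needs >= 15)",
                 idx[bad], path, nf[bad],
                 class = "goscape_parse_error")
  }
  gene <- vapply(parts, `[`, character(1), 2)
  qual <- vapply(parts, `[`, character(1), 4)
  term <- vapply(parts, `[`, character(1), 5)
  ok <- !grepl("(^|\\|)NOT($|\\|)", qual)
  annotation_map(gene[ok], term[ok])
}

#' Write / read a count matrix with group labels
#'
#' The counts file has a `gene` id column followed by one integer
#' column per sample; the groups file maps each sample to group 0
#' (control) or 1 (treated).  Sample order may differ between the
#' two files; columns are realigned by sample id on read.
#'
#' @param x a `count_matrix` (counts + group labels).
#' @param counts_path,groups_path file paths.
#' @return `write_counts` returns the paths invisibly; `read_counts`
#'   returns a `count_matrix`.
#' @export
write_counts <- function(x, counts_path, groups_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, counts_path)
  .write_tsv(data.frame(sample = names(x$group),
                        group = as.integer(x$group)), groups_path)
  invisible(c(counts_path, groups_path))
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, groups_path) {
  df <- .read_tsv(counts_path)
  if (ncol(df) < 3) {
    stop_goscape("counts file needs a gene column and >= 2 samples",
                 class = "goscape_parse_error")
  }
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop_goscape("duplicate gene id '%s' in counts file",
                 genes[duplicated(genes)][1],
                 class = "goscape_consistency_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(m < 0) || any(m != round(m))) {
    stop_goscape("counts must be non-negative integers",
                 class = "goscape_consistency_error")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes

  gr <- .read_tsv(groups_path)
  if (!all(c("sample", "group") %in% names(gr))) {
    stop_goscape("groups file needs 'sample' and 'group' columns",
                 class = "goscape_parse_error")
  }
  missing <- setdiff(colnames(m), gr$sample)
  if (length(missing)) {
    stop_goscape("sample '%s' missing from groups file", missing[1],
                 class = "goscape_consistency_error")
  }
  grp <- stats::setNames(as.integer(gr$group), gr$sample)[colnames(m)]
  if (!all(grp %in% c(0L, 1L))) {
    stop_goscape("groups must be 0 or 1",
                 class = "goscape_consistency_error")
  }
  structure(list(counts = m, group = grp, size_factors_true = NULL),
            class = "count_matrix")
}

#' Write / read a differential-expression table
#'
#' Columns `gene`, `base_mean`, `log2fc`, `p` and, when present,
#' `padj` and `rank`.  Reals round-trip to better than 1e-12
#' relative error.
#'
#' @param de_table a `de_table` data frame.
#' @param path file path.
#' @return `write_de_table` returns the path invisibly;
#'   `read_de_table` returns a `de_table`.
#' @export
write_de_table <- function(de_table, path) {
  cols <- intersect(c("gene", "base_mean", "log2fc", "p", "padj",
                      "rank"), names(de_table))
  .write_tsv(de_table[, cols, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene", "log2fc", "p")
  if (!all(need %in% names(df))) {
    stop_goscape("DE table must have columns %s",
                 paste(need, collapse = ", "),
                 class = "goscape_parse_error")
  }
  df$gene <- as.character(df$gene)
  structure(df, class = c("de_table", "data.frame"))
}

#' Write a fitted landscape in long format
#'
#' One row per (term, step): columns `term`, `step`, `k`, `raw_p`,
#' `adj_p`.
#'
#' @param landscape a `go_landscape`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "go_landscape"))
  long <- data.frame(
    term = rep(rownames(landscape$raw), times = ncol(landscape$raw)),
    step = rep(landscape$grid, each = nrow(landscape$raw)),
    k = as.vector(landscape$k),
    raw_p = as.vector(landscape$raw),
    adj_p = as.vector(landscape$adj),
    stringsAsFactors = FALSE)
  .write_tsv(long, path)
  invisible(path)
}

#' Write synthetic ground truth as flat key-value text
#'
#' @param truth a `truth_record`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  lines <- c(
    sprintf("focal_gene\t%s", truth$focal_gene),
    sprintf("focal_factor\t%s", .fmt_num(truth$focal_factor)),
    sprintf("planted_terms\t%s",
            paste(truth$planted_terms, collapse = ",")),
    sprintf("de_genes\t%s", paste(truth$de_genes, collapse = ",")),
    sprintf("samples\t%s", paste(truth$samples, collapse = ",")),
    sprintf("group\t%s", paste(truth$group, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write an annotation map as a two-column TSV
#'
#' @param annotation an [annotation_map].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_gene2term <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_map"))
  gene <- rep(names(annotation$gene2term),
              times = lengths(annotation$gene2term))
  term <- unlist(annotation$gene2term, use.names = FALSE)
  .write_tsv(data.frame(gene = gene, term = term,
                        stringsAsFactors = FALSE), path)
  invisible(path)
}
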