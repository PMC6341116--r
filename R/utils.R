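# internal helpers shared across the package

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Expand one global seed into per-stage child seeds so individual
# simulation stages are reproducible on their own.  Affine scheme,
# kept below 2^31 - 1; documented in the methods vignette.
stage_seed <- function(seed, stage = c("annotation", "truth", "counts")) {
  stage <- match.arg(stage)
  offset <- c(annotation = 101L, truth = 211L, counts = 307L)[[stage]]
  as.integer((as.double(seed) * 1009 + offset) %% 2147483629)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

term_ids <- function(n) sprintf("T%04d", seq_len(n))

stop_goscape <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "goscape_error")))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 0

`%||%` <- function(a, b) if (is.null(a)) b else a
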