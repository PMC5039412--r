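# Internal helpers shared across the package.

# Run `expr` under a fixed RNG seed without disturbing the caller's
# generator state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force initialisation so we have a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Format doubles so that read-back reproduces them bit-for-bit.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.17g", v)
  }, character(1))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# Canonical unordered-pair key for fast membership tests.
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Weighted adjacency matrix of an igraph network (dense, named).
weighted_adjacency <- function(network) {
  as.matrix(igraph::as_adjacency_matrix(network, attr = "weight", sparse = TRUE))
}
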