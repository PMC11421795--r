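#' @useDynLib cmipage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats phyper p.adjust qnorm pnorm runif lm coef sd
NULL

# Deterministic 31-bit stream seeds derived from a single user seed.  Each
# logical component (profile simulation, set sizes, permutations of set k, ...)
# gets its own stream so adding permutations never perturbs simulation draws.
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(seed %% 2147483647)
  for (p in parts) {
    for (ch in utf8ToInt(p)) h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# Salted polynomial hash of gene identifiers; used as the tie-break key in
# equal-frequency binning so that bin labels depend on gene identity, not on
# the row order of the input.
gene_hash <- function(genes, seed = 0L) {
  salt <- as.double(seed %% 2147483647)
  vapply(genes, function(g) {
    h <- salt
    for (ch in utf8ToInt(g)) h <- (h * 131 + ch) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# n items into k rank-chunks with sizes differing by at most one;
# the remainder goes to the lowest-index bins.
bin_sizes <- function(n, k) {
  base <- n %/% k
  base + as.integer(seq_len(k) <= n %% k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
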