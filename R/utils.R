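#' @useDynLib miuflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rpois qlnorm qexp qunif pnorm rnorm sd quantile
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed
#'
#' Deterministically mixes a base seed with a stream index so that
#' replications, dataset rows and pipeline stages each get an independent,
#' reproducible RNG stream.  Results stay inside the 32-bit integer range.
#'
#' @param seed integer base seed.
#' @param k nonnegative integer stream index.
#' @return an integer seed.
#' @export
mix_seed <- function(seed, k) {
  v <- (as.numeric(seed) %% 2147483647) + 1
  # two rounds of a multiplicative congruential mix keep distinct (seed, k)
  # pairs well separated without leaving double precision
  v <- (v * 48271 + as.numeric(k) * 2654435761 + 11) %% 2147483629
  v <- (v * 69621 + 7) %% 2147483629
  as.integer(v)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

# md5 of an R object via its canonical JSON serialization (used for
# provenance hashes in dataset sidecars and pipeline manifests)
hash_object <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                          force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}

# 17 significant digits round-trip IEEE doubles exactly
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
}
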