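#' @useDynLib mfcnsr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd cor var
#' @importFrom utils write.csv head tail
NULL

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Polynomial rolling hash (mod 2^31-1) over the serialized object; cheap
# content hash for manifests and paired-run audits, not cryptographic.
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 3L))
  h <- 0
  m <- 2147483647
  # chunked Horner scheme keeps every intermediate below 2^53
  for (i in seq(1, length(bytes), by = 4096)) {
    chunk <- bytes[i:min(i + 4095, length(bytes))]
    for (b in chunk) h <- (h * 257 + b) %% m
  }
  sprintf("%08x", h)
}

stopifnot_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %s", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
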