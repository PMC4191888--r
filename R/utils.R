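# Internal plumbing: content hashing and seed derivation.

# 32-bit FNV-1a over a character string; returns a double in [0, 2^32).
# XOR touches only the low byte; the 32-bit modular multiply is split into
# 16-bit halves so everything stays exactly representable in doubles.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    hlo <- h %% 65536
    hhi <- (h - hlo) / 65536
    h <- (hlo * m + ((hhi * m) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Content fingerprint of an R object
#'
#' A short hexadecimal fingerprint used in run manifests and for snapshot
#' comparison. Stable across sessions for identical content.
#'
#' @param x any R object (deparsed to a canonical string before hashing).
#' @return a character scalar, eight hex digits.
#' @export
dl_fingerprint <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  hex8(fnv1a(s))
}

# format a double in [0, 2^32) as 8 hex digits (sprintf %x needs integers)
hex8 <- function(h) {
  hi <- floor(h / 65536)
  sprintf("%04x%04x", as.integer(hi), as.integer(h - hi * 65536))
}

#' Derive a reproducible sub-seed
#'
#' Hashes a base seed together with arbitrary labels (for example the
#' `p_short`/`p_long` coordinates of a heat-map cell) into an integer seed
#' below 2^31, so that parameter scans are reproducible and order-independent.
#'
#' @param base integer base seed.
#' @param ... further scalars mixed into the hash.
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(base, ...) {
  parts <- vapply(list(base, ...), function(v) format(v, digits = 15), "")
  as.integer(fnv1a(paste(parts, collapse = "|")) %% (2^31 - 2) + 1)
}

# Run `expr` with a locally seeded R RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# A seed for C++ streams when the user did not give one: drawn from R's RNG
# so that set.seed() upstream still controls everything.
auto_seed <- function(seed) {
  if (!is.null(seed)) return(as.numeric(seed))
  as.numeric(sample.int(.Machine$integer.max, 1L))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
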