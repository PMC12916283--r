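# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage draws its own seed from the run's master seed and a
#' stage label, so that stages can be re-run in isolation (or in parallel)
#' without perturbing each other's random streams.
#'
#' @param seed master seed (integer).
#' @param ... labels (strings or integers) identifying the substream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime used by the Lehmer generator
  key <- as.numeric(seed) %% m
  for (part in list(...)) {
    if (is.character(part)) {
      for (ch in utf8ToInt(part)) key <- (key * 69621 + ch) %% m
    } else {
      key <- (key * 69621 + as.numeric(part) + 1) %% m
    }
  }
  as.integer(key %% (m - 2) + 1)
}

# Evaluate `expr` with a local RNG state seeded at `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
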