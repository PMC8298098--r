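# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a child RNG seed from a root seed and a stream key
#'
#' Every stochastic operation in the package derives its own stream from the
#' root seed keyed by the operation name, so that adding or reordering
#' operations does not perturb the draws of the others. The derivation is a
#' simple 31-bit polynomial string hash, which keeps seeds within R's
#' integer range.
#'
#' @param root integer root seed.
#' @param key character stream name (usually the operation name).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, key) {
  h <- as.numeric(root) %% 2147483647
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Evaluate `code` under `seed` (when non-NULL), restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# proportion check used by several validators
check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stopf("invalid configuration: '%s' must be a proportion in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != floor(x))
    stopf("invalid configuration: '%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}
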