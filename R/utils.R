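# Seed plumbing and small shared helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded internals never disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Deterministic sub-stream seeds: fold integers into [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 1000003 + (as.numeric(k) %% 2147483647)) %% 2147483647
  as.integer(h)
}

# Order-sensitive fingerprint of a (possibly nested) list of numeric arrays,
# used for the frozen-network contract. Any elementwise change alters at
# least one of the per-array moments, so a training update cannot go
# unnoticed; tests back it up with identical() on the raw parameters.
param_checksum <- function(x) {
  sig <- c()
  walk <- function(v) {
    if (is.list(v)) {
      for (el in v) walk(el)
    } else if (is.numeric(v)) {
      z <- as.numeric(v)
      n <- length(z)
      sig <<- c(sig, n, sum(z), sum(z * z), sum(z * seq_len(n)))
    }
  }
  walk(x)
  txt <- paste(formatC(sig, digits = 17, format = "g"), collapse = ",")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647L), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x-%d", as.integer(h), length(bytes))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}
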