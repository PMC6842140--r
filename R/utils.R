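#' @importFrom stats median rgamma runif setNames
#' @importFrom utils head tail
NULL

# Deterministically fold integer components into a seed in [0, 2^31 - 2].
# Used to give each (archive, run, spot-range) request its own RNG stream.
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  m <- 2147483647 # 2^31 - 1, prime
  s <- 104729
  for (x in parts) {
    s <- (s * 48271 + (abs(x) %% m) + 1) %% m
  }
  as.integer(s)
}

# Evaluate `expr` under a private RNG stream, restoring the caller's RNG
# state afterwards so simulator calls never perturb selection randomness.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_contract <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("srasampler_contract_error", "error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
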