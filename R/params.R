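#' Selection parameters
#'
#' Collects the tunable parameters of the online sampling algorithm.
#'
#' @param batch_size Number of spots (reads or read pairs) per downloaded
#'   batch, the constant `b` in the expected-score objective. Default 50000.
#' @param lambda Pseudocount weight pulling a run's profile estimate towards
#'   the archive-wide tile frequency; default 10.
#' @param pseudocount General additive pseudocount `a`; default 1. With
#'   `pseudocount > 0` every tile has positive estimated probability.
#' @param max_batches Total batch budget for one sampling execution;
#'   default 1000.
#' @param q_weights Length-2 nonnegative weights, summing to 1, of the
#'   uniquely-aligned and spliced read fractions in the run quality estimate
#'   \eqn{\hat q_r}. Default `c(unique = 0.9, spliced = 0.1)`.
#' @param q_init Quality assumed for runs never sampled; default 1 so that
#'   unexplored runs are treated optimistically and exploration is encouraged.
#' @param blacklist_threshold Minimum fraction of uniquely aligning spots in a
#'   run's first batch; runs below it are permanently blacklisted.
#'   Default 0.05; a run at exactly the threshold is kept.
#' @param tie_rel_tol Relative tolerance under which two expected scores are
#'   considered tied; default 1e-12.
#' @param mapq_unique Mapping-quality cutoff used to call an alignment unique
#'   when the aligner emits no NH tag; default 30.
#' @param max_failures Number of consecutive fetch/align failures after which
#'   a run is blacklisted; default 3.
#' @param seed Integer seed governing all randomness of a sampling execution
#'   (tie-breaks and, in simulator mode, read generation).
#' @return An object of class `selection_params`.
#' @export
selection_params <- function(batch_size = 50000,
                             lambda = 10,
                             pseudocount = 1,
                             max_batches = 1000,
                             q_weights = c(unique = 0.9, spliced = 0.1),
                             q_init = 1,
                             blacklist_threshold = 0.05,
                             tie_rel_tol = 1e-12,
                             mapq_unique = 30,
                             max_failures = 3,
                             seed = 1L) {
  if (!is_count(batch_size) || batch_size < 1) stop_contract("batch_size must be >= 1")
  if (!is.numeric(lambda) || lambda < 0) stop_contract("lambda must be >= 0")
  if (!is.numeric(pseudocount) || pseudocount < 0) stop_contract("pseudocount must be >= 0")
  if (!is_count(max_batches)) stop_contract("max_batches must be a nonnegative integer")
  if (length(q_weights) != 2L || any(q_weights < 0) ||
      abs(sum(q_weights) - 1) > 1e-9)
    stop_contract("q_weights must be two nonnegative values summing to 1")
  if (blacklist_threshold < 0 || blacklist_threshold > 1)
    stop_contract("blacklist_threshold must lie in [0, 1]")
  if (q_init < 0 || q_init > 1) stop_contract("q_init must lie in [0, 1]")
  names(q_weights) <- c("unique", "spliced")
  structure(list(
    batch_size = as.integer(batch_size),
    lambda = lambda,
    pseudocount = pseudocount,
    max_batches = as.integer(max_batches),
    q_weights = q_weights,
    q_init = q_init,
    blacklist_threshold = blacklist_threshold,
    tie_rel_tol = tie_rel_tol,
    mapq_unique = mapq_unique,
    max_failures = as.integer(max_failures),
    seed = as.integer(seed)
  ), class = "selection_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat("selection_params:\n")
  cat(sprintf("  batch_size=%d  lambda=%g  pseudocount=%g  max_batches=%d\n",
              x$batch_size, x$lambda, x$pseudocount, x$max_batches))
  cat(sprintf("  q_weights=(unique=%g, spliced=%g)  q_init=%g\n",
              x$q_weights[1], x$q_weights[2], x$q_init))
  cat(sprintf("  blacklist_threshold=%g  seed=%d\n",
              x$blacklist_threshold, x$seed))
  invisible(x)
}
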