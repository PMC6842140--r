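#' Log-coverage objective score
#'
#' The objective the sampler maximizes: \eqn{S(c) = \sum_{j=1}^{T}
#' \ln(1 + c_j)} over per-tile aligned spot counts. The logarithm encodes
#' diminishing returns: new coverage on an empty tile is worth more than on a
#' well-covered one, which is what drives the algorithm towards complementary
#' runs. The argument may be real-valued (expected counts), not only integer.
#'
#' @param counts Nonnegative numeric vector of per-tile counts.
#' @return A single nonnegative number.
#' @examples
#' coverage_score(c(0, 0, 0)) # 0
#' coverage_score(c(3, 1, 0)) # log(4) + log(2)
#' @export
coverage_score <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0))
    stop_contract("coverage_score: counts must be nonnegative")
  sum(log1p(counts))
}

#' Coverage state
#'
#' Tracks the global and per-run aligned spot counts over genome tiles, plus
#' cumulative per-run alignment-quality statistics. The invariant
#' \eqn{c_j = \sum_r c_j^r} is maintained by [update_state()].
#'
#' @param tiles A [tile_index()].
#' @param run_ids Character vector of run identifiers known to the sampler.
#' @return An object of class `coverage_state` with elements `c` (global
#'   per-tile counts, length T), `counts` (T x R matrix of per-run counts)
#'   and `quality` (per-run cumulative sampled/unique/spliced spot counts).
#' @export
coverage_state <- function(tiles, run_ids) {
  stopifnot(inherits(tiles, "tile_index"))
  run_ids <- as.character(run_ids)
  if (anyDuplicated(run_ids)) stop_contract("run ids must be unique")
  structure(list(
    tiles = tiles,
    c = numeric(tiles$T),
    counts = matrix(0, nrow = tiles$T, ncol = length(run_ids),
                    dimnames = list(NULL, run_ids)),
    quality = data.frame(run_id = run_ids,
                         n_sampled = 0, n_unique = 0, n_spliced = 0,
                         row.names = run_ids, stringsAsFactors = FALSE)
  ), class = "coverage_state")
}

#' @export
print.coverage_state <- function(x, ...) {
  cat(sprintf("coverage_state: T=%d tiles, %d run(s), %g aligned spots, S(c)=%.4f\n",
              x$tiles$T, ncol(x$counts), sum(x$c), coverage_score(x$c)))
  invisible(x)
}

#' Cumulative run quality estimate
#'
#' \eqn{\hat q_r}: a weighted sum of the fractions of uniquely aligned and
#' spliced spots, pooled over all batches downloaded from the run so far.
#' Runs never sampled get the optimistic prior `params$q_init`.
#'
#' @param state A [coverage_state()].
#' @param run_id Run identifier(s).
#' @param params A [selection_params()].
#' @return Numeric vector of quality estimates in `[0, 1]`.
#' @export
run_quality <- function(state, run_id, params) {
  q <- state$quality[run_id, , drop = FALSE]
  out <- rep(params$q_init, length(run_id))
  sampled <- q$n_sampled > 0
  out[sampled] <- (params$q_weights[["unique"]] * q$n_unique[sampled] +
                   params$q_weights[["spliced"]] * q$n_spliced[sampled]) /
    q$n_sampled[sampled]
  pmin(pmax(out, 0), 1)
}

# Archive-wide relative tile frequency over all sampled batches; uniform
# when nothing has been aligned anywhere yet (the only symmetric choice).
mean_profile <- function(state) {
  tot <- sum(state$c)
  if (tot == 0) rep(1 / state$tiles$T, state$tiles$T) else state$c / tot
}

#' Estimate a run's expression profile over tiles
#'
#' Multinomial estimate of where a randomly drawn read from the run aligns,
#' smoothed with pseudocounts:
#' \deqn{\hat p_r[j] \propto c_j^r + \lambda T \bar p[j] + a,}
#' where \eqn{c_j^r} is the run's aligned spot count on tile j, \eqn{\bar p}
#' is the relative tile frequency over all sampled batches of all runs, and
#' `a` is a general pseudocount. For runs with few or no sampled reads the
#' estimate is dominated by the archive-wide profile when \eqn{\lambda \gg a}.
#'
#' @inheritParams run_quality
#' @param run_id A single run identifier.
#' @return Probability vector of length T (sums to 1; strictly positive when
#'   `pseudocount > 0`).
#' @export
estimate_profile <- function(state, run_id, params) {
  stopifnot(length(run_id) == 1L)
  cr <- state$counts[, run_id]
  w <- cr + params$lambda * state$tiles$T * mean_profile(state) + params$pseudocount
  tot <- sum(w)
  if (tot == 0) return(rep(1 / state$tiles$T, state$tiles$T))
  w / tot
}

#' Expected objective score after one more batch from a run
#'
#' Evaluates \eqn{S(c + b\,\hat q_r\,\hat p_r)}: the score of the expected
#' count vector if the next batch of `batch_size` spots were drawn from
#' `run_id`. The expected counts are real-valued; no rounding is applied.
#'
#' @inheritParams estimate_profile
#' @return A single number.
#' @export
expected_batch_score <- function(state, run_id, params) {
  q <- run_quality(state, run_id, params)
  p <- estimate_profile(state, run_id, params)
  coverage_score(state$c + params$batch_size * q * p)
}

#' Greedily choose the run to sample next
#'
#' Evaluates the expected post-batch score for every candidate run and
#' returns an argmax. Scores equal within `params$tie_rel_tol` (relative) are
#' treated as tied — in particular all never-sampled runs tie exactly — and
#' the tie is broken randomly with probability proportional to the runs'
#' average read lengths, biasing towards longer reads. Runs sharing identical
#' profile and quality estimates (all never-sampled runs) are evaluated once
#' as a class rather than per run.
#'
#' @param state A [coverage_state()].
#' @param candidates Data frame with columns `run_id` and `avg_read_length`
#'   for the runs still eligible (not blacklisted, not exhausted). Missing
#'   read lengths are imputed as the median of the known ones.
#' @param params A [selection_params()].
#' @return The chosen run id (character scalar). Draws depend on the current
#'   RNG state; seed it for reproducibility.
#' @export
choose_next_run <- function(state, candidates, params) {
  if (NROW(candidates) == 0L)
    stop(errorCondition("archive exhausted: no eligible runs remain",
                        class = c("archive_exhausted", "error")))
  ids <- as.character(candidates$run_id)
  fresh <- state$quality[ids, "n_sampled"] == 0

  scores <- numeric(length(ids))
  if (any(fresh)) {
    # all never-sampled runs share p-hat and q-hat: evaluate the class once
    scores[fresh] <- expected_batch_score(state, ids[which(fresh)[1L]], params)
  }
  for (i in which(!fresh)) scores[i] <- expected_batch_score(state, ids[i], params)

  best <- max(scores)
  tied <- (best - scores) <= params$tie_rel_tol * max(abs(best), 1)
  tied_ids <- ids[tied]
  if (length(tied_ids) == 1L) return(tied_ids)

  len <- suppressWarnings(as.numeric(candidates$avg_read_length))[tied]
  all_len <- suppressWarnings(as.numeric(candidates$avg_read_length))
  fill <- if (all(is.na(all_len))) 1 else median(all_len, na.rm = TRUE)
  len[is.na(len) | len <= 0] <- fill
  tied_ids[sample.int(length(tied_ids), 1L, prob = len)]
}

#' Fold a classified batch into the coverage state
#'
#' Adds the batch's per-tile aligned spot increments to the global and
#' per-run counts and updates the run's cumulative quality statistics. The
#' quality fractions are pooled over all of the run's batches (counts are
#' summed first), not averaged per batch.
#'
#' @param state A [coverage_state()].
#' @param batch A `batch_result` from [classify_batch()].
#' @return The updated `coverage_state`.
#' @export
update_state <- function(state, batch) {
  stopifnot(inherits(batch, "batch_result"))
  run_id <- batch$run_id
  if (!run_id %in% colnames(state$counts))
    stop_contract("unknown run id: %s", run_id)
  inc <- batch$tile_counts
  if (length(inc)) {
    idx <- as.integer(names(inc))
    if (any(idx < 1L | idx > state$tiles$T))
      stop_contract("tile increment outside 1..T")
    state$counts[idx, run_id] <- state$counts[idx, run_id] + inc
    state$c[idx] <- state$c[idx] + inc
  }
  state$quality[run_id, c("n_sampled", "n_unique", "n_spliced")] <-
    state$quality[run_id, c("n_sampled", "n_unique", "n_spliced")] +
    c(batch$spots_downloaded, batch$spots_unique, batch$spots_spliced)
  state
}
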