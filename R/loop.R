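#' @title Sampling loop
#' @description Internal engine shared by [run_loop()] and [load_all_once()]:
#'   per-run range bookkeeping, fetch/align via an adapter, batch
#'   classification, first-batch quality filtering and coverage updates.
#' @name sampling-loop
NULL

new_run_states <- function(run_list) {
  setNames(lapply(seq_len(nrow(run_list)), function(i) {
    list(ranges = matrix(numeric(), ncol = 2,
                         dimnames = list(NULL, c("start", "end"))),
         blacklisted = FALSE, exhausted = FALSE,
         failures = 0L, n_batches = 0L)
  }), run_list$run_id)
}

eligible_runs <- function(runs) {
  names(runs)[!vapply(runs, function(x) x$blacklisted || x$exhausted, logical(1))]
}

# Execute one batch attempt for run `rid`, mutating the loop environment.
sample_one_batch <- function(env, rid) {
  run_meta <- env$run_list[env$run_list$run_id == rid, ]
  rs <- env$runs[[rid]]
  rng <- next_range(rs$ranges, run_meta$total_spots, env$params$batch_size)
  requested <- rng[["end"]] - rng[["start"]]
  env$batch_i <- env$batch_i + 1L

  res <- tryCatch(env$source(rid, rng), error = function(e) e)
  if (inherits(res, "error")) {
    rs$failures <- rs$failures + 1L
    if (rs$failures >= env$params$max_failures) rs$blacklisted <- TRUE
    env$runs[[rid]] <- rs
    env$log[[env$batch_i]] <- data.frame(
      batch = env$batch_i, run_id = rid,
      start = rng[["start"]], end = rng[["start"]],
      spots = 0L, unique = 0L, multi = 0L, unmapped = 0L, spliced = 0L,
      kept = FALSE, failed = TRUE, score = coverage_score(env$state$c),
      cum_spots = env$cum_spots, stringsAsFactors = FALSE)
    env$batch_introns[[env$batch_i]] <-
      data.frame(seqname = character(), start = integer(), end = integer(),
                 count = integer(), stringsAsFactors = FALSE)
    return(invisible(FALSE))
  }
  rs$failures <- 0L

  actual <- res$n_spots
  if (actual < requested) rs$exhausted <- TRUE # archive end reached
  rng[["end"]] <- rng[["start"]] + actual
  if (actual > 0) rs$ranges <- rbind(rs$ranges, rng)
  if (ranges_cover_all(rs$ranges, run_meta$total_spots)) rs$exhausted <- TRUE

  batch <- classify_batch(res$records, env$tiles, run_id = rid,
                          paired = isTRUE(run_meta$paired), n_spots = actual,
                          mapq_unique = env$params$mapq_unique)
  first <- rs$n_batches == 0L
  rs$n_batches <- rs$n_batches + 1L
  keep <- TRUE
  if (first && !quality_filter(batch, env$params$blacklist_threshold)) {
    keep <- FALSE
    rs$blacklisted <- TRUE
  }
  if (keep) env$state <- update_state(env$state, batch)
  env$runs[[rid]] <- rs
  env$cum_spots <- env$cum_spots + actual

  if (!is.null(env$sam_path)) {
    write_sam(res$records, env$tiles, env$sam_path, append = env$sam_started)
    env$sam_started <- TRUE
  }

  env$log[[env$batch_i]] <- data.frame(
    batch = env$batch_i, run_id = rid,
    start = rng[["start"]], end = rng[["end"]],
    spots = actual, unique = batch$spots_unique, multi = batch$spots_multi,
    unmapped = batch$spots_unmapped, spliced = batch$spots_spliced,
    kept = keep, failed = FALSE, score = coverage_score(env$state$c),
    cum_spots = env$cum_spots, stringsAsFactors = FALSE)
  env$batch_introns[[env$batch_i]] <- batch$introns
  invisible(TRUE)
}

init_loop_env <- function(run_list, tiles, source, params, resume, sam_path) {
  stopifnot(inherits(tiles, "tile_index"), inherits(params, "selection_params"))
  if (nrow(run_list) == 0L) stop_contract("run list is empty")
  env <- new.env(parent = emptyenv())
  env$run_list <- run_list
  env$tiles <- tiles
  env$source <- source
  env$params <- params
  env$sam_path <- sam_path
  env$sam_started <- FALSE
  if (is.null(resume)) {
    env$state <- coverage_state(tiles, run_list$run_id)
    env$runs <- new_run_states(run_list)
    env$log <- list()
    env$batch_introns <- list()
    env$batch_i <- 0L
    env$cum_spots <- 0
  } else {
    stopifnot(inherits(resume, "sampling_run"))
    env$state <- resume$state
    env$runs <- resume$runs
    env$log <- if (nrow(resume$log)) split(resume$log, seq_len(nrow(resume$log))) else list()
    env$batch_introns <- resume$batch_introns
    env$batch_i <- length(env$batch_introns)
    env$cum_spots <- resume$total_spots_downloaded
  }
  env
}

finish_loop <- function(env, policy) {
  log <- if (length(env$log)) do.call(rbind, env$log) else
    data.frame(batch = integer(), run_id = character(), start = numeric(),
               end = numeric(), spots = integer(), unique = integer(),
               multi = integer(), unmapped = integer(), spliced = integer(),
               kept = logical(), failed = logical(), score = numeric(),
               cum_spots = numeric(), stringsAsFactors = FALSE)
  rownames(log) <- NULL
  structure(list(
    state = env$state,
    runs = env$runs,
    log = log,
    batch_introns = env$batch_introns,
    params = env$params,
    run_list = env$run_list,
    policy = policy,
    total_spots_downloaded = env$cum_spots
  ), class = "sampling_run")
}

#' Online sampling loop over an archive of sequencing runs
#'
#' Repeats, for at most `params$max_batches` batches: choose the next run
#' (greedily by expected objective gain, or uniformly at random for the
#' baseline policy), determine the next not-yet-downloaded spot range,
#' fetch and align it through the `source` adapter, classify the alignments,
#' apply the first-batch quality filter, and fold the result into the
#' coverage state. Terminates early when every run is blacklisted or
#' exhausted. A run whose fetches fail `params$max_failures` times in a row
#' is blacklisted so the loop cannot stall on dead accessions.
#'
#' @param run_list Run catalogue as returned by [read_run_list()] (columns
#'   `run_id`, `paired`, `avg_read_length`, `total_spots`).
#' @param tiles A [tile_index()] over the target genome.
#' @param source Fetch-and-align adapter: a `function(run_id, range)`
#'   returning `list(records = <alignment record data frame>, n_spots =
#'   <spots actually retrieved>)`, e.g. [simulator_source()] or an external
#'   wrapper around fastq-dump plus an aligner. Any error it signals is
#'   treated as a batch failure.
#' @param params A [selection_params()]; `params$seed` governs all
#'   randomness of the execution.
#' @param policy `"greedy"` for expected-score maximization, `"random"` for
#'   uniform run choice at equal budget (baseline).
#' @param resume A previous `sampling_run` on the same archive to continue
#'   from; downloaded-range bookkeeping carries over so no spot is fetched
#'   twice across phases.
#' @param sam_path Optional path; when given, all batch alignment records
#'   are appended to this SAM file.
#' @return An object of class `sampling_run`: final coverage state, per-run
#'   bookkeeping, a per-batch log (run, spot range, classification counts,
#'   objective score) and per-batch observed introns.
#' @seealso [load_all_once()], [observed_introns()], [accuracy_curve()]
#' @export
run_loop <- function(run_list, tiles, source, params = selection_params(),
                     policy = c("greedy", "random"), resume = NULL,
                     sam_path = NULL) {
  policy <- match.arg(policy)
  env <- init_loop_env(run_list, tiles, source, params, resume, sam_path)
  set.seed(params$seed)
  for (i in seq_len(params$max_batches)) {
    elig <- eligible_runs(env$runs)
    if (!length(elig)) break
    rid <- if (policy == "greedy") {
      cand <- run_list[run_list$run_id %in% elig,
                       c("run_id", "avg_read_length")]
      choose_next_run(env$state, cand, params)
    } else {
      elig[sample.int(length(elig), 1L)]
    }
    sample_one_batch(env, rid)
  }
  finish_loop(env, policy)
}

#' Download one batch from every run
#'
#' The trivial sampling mode: a single batch is fetched from each run of the
#' catalogue exactly once, bypassing greedy selection, with accounting
#' (classification, quality filter, coverage updates, range bookkeeping)
#' identical to [run_loop()]. Useful to survey library quality across an
#' archive, or as a seeding phase before a greedy phase continued with
#' `resume =` the returned object.
#'
#' @inheritParams run_loop
#' @param order `"list"` to visit runs in catalogue order, `"random"` for a
#'   seeded random order.
#' @return A `sampling_run`, as for [run_loop()].
#' @export
load_all_once <- function(run_list, tiles, source, params = selection_params(),
                          order = c("list", "random"), resume = NULL,
                          sam_path = NULL) {
  order <- match.arg(order)
  env <- init_loop_env(run_list, tiles, source, params, resume, sam_path)
  set.seed(params$seed)
  ids <- run_list$run_id
  if (order == "random") ids <- ids[sample.int(length(ids))]
  for (rid in ids) {
    rs <- env$runs[[rid]]
    if (rs$blacklisted || rs$exhausted) next
    sample_one_batch(env, rid)
  }
  finish_loop(env, policy = "load_all_once")
}

#' @export
print.sampling_run <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("sampling_run (%s): %d batch(es), %g spots from %d run(s); %d blacklisted; S(c) = %.4f\n",
              x$policy, s$batches, s$total_spots_downloaded, s$runs_sampled,
              s$runs_blacklisted, s$final_score))
  invisible(x)
}

#' Summarize a sampling execution
#'
#' @param object A `sampling_run`.
#' @param ... Unused.
#' @return A list with batch/spot totals, per-run outcomes, the final
#'   objective score and the full resolved parameters (audit trail).
#' @export
summary.sampling_run <- function(object, ...) {
  runs <- object$runs
  list(
    policy = object$policy,
    seed = object$params$seed,
    batches = nrow(object$log),
    total_spots_downloaded = object$total_spots_downloaded,
    runs_sampled = sum(vapply(runs, function(x) x$n_batches > 0L, logical(1))),
    runs_blacklisted = sum(vapply(runs, function(x) x$blacklisted, logical(1))),
    runs_exhausted = sum(vapply(runs, function(x) x$exhausted, logical(1))),
    final_score = coverage_score(object$state$c),
    tiles_covered = sum(object$state$c > 0),
    params = unclass(object$params)
  )
}

#' Write the summary of a sampling execution as JSON
#'
#' @param result A `sampling_run`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(result, path) {
  jsonlite::write_json(summary(result), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Introns observed across a sampling execution
#'
#' Pools the introns induced by spliced unique alignments over all batches,
#' with per-intron supporting-alignment counts.
#'
#' @param result A `sampling_run`.
#' @param min_support Minimum number of supporting alignments for an intron
#'   to be reported (default 1, i.e. all observed introns).
#' @return An [intron_set()] with a `count` column.
#' @export
observed_introns <- function(result, min_support = 1) {
  all <- data.table::rbindlist(result$batch_introns)
  if (!nrow(all))
    return(intron_set(character(), integer(), integer()))
  seqname <- start <- end <- NULL # data.table NSE
  agg <- all[, list(count = sum(count)), by = list(seqname, start, end)]
  agg <- agg[agg$count >= min_support, ]
  intron_set(agg$seqname, agg$start, agg$end, count = agg$count)
}
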