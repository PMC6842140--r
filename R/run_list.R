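#' Read a run list
#'
#' A run list is the tabular catalogue of candidate sequencing runs for one
#' species, typically produced from an SRA metadata query: a headered TSV
#' with columns `run_id`, `paired` (0/1), `avg_read_length` (bp) and
#' `total_spots` (may be empty when unknown).
#'
#' @param path Path to the TSV file.
#' @return Data frame with one row per run; `run_id` values are unique.
#' @export
read_run_list <- function(path) {
  if (!file.exists(path)) stop_contract("run list not found: %s", path)
  rl <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("run_id", "paired", "avg_read_length", "total_spots")
  if (!all(needed %in% names(rl)))
    stop_contract("run list must have columns %s", paste(needed, collapse = ", "))
  rl$run_id <- as.character(rl$run_id)
  if (anyDuplicated(rl$run_id)) stop_contract("run ids must be unique")
  rl$paired <- as.integer(rl$paired) == 1L
  rl$avg_read_length <- suppressWarnings(as.numeric(rl$avg_read_length))
  rl$total_spots <- suppressWarnings(as.numeric(rl$total_spots))
  rl[needed]
}

#' Write a run list
#'
#' @param run_list Data frame with columns `run_id`, `paired`,
#'   `avg_read_length`, `total_spots`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_run_list <- function(run_list, path) {
  out <- run_list[c("run_id", "paired", "avg_read_length", "total_spots")]
  out$paired <- as.integer(out$paired)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Empty run-list template
#'
#' Writes a header-only run-list TSV to fill in by hand or from an archive
#' metadata query.
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
make_runlist_template <- function(path) {
  write_run_list(data.frame(run_id = character(), paired = integer(),
                            avg_read_length = numeric(), total_spots = numeric()),
                 path)
}

#' Next spot range to download from a run
#'
#' Spot ranges already downloaded from a run are tracked so that no spot is
#' ever downloaded twice and, with unlimited budget, every spot is requested
#' exactly once. The next range is the lowest-starting interval of length at
#' most `batch_size` disjoint from all downloaded ranges; a final partial
#' interval shorter than `batch_size` is allowed.
#'
#' @param ranges Two-column matrix of half-open, pairwise disjoint
#'   `[start, end)` spot intervals already downloaded (0-based spots),
#'   or `NULL`/empty for a fresh run.
#' @param total_spots Total spots in the run, or `NA` when unknown.
#' @param batch_size Maximum spots per batch.
#' @return Numeric `c(start, end)`, a half-open interval.
#' @export
next_range <- function(ranges, total_spots, batch_size) {
  if (is.null(ranges) || nrow(ranges) == 0L) {
    start <- 0
    cap <- Inf
  } else {
    o <- order(ranges[, 1])
    ranges <- ranges[o, , drop = FALSE]
    start <- 0
    cap <- Inf
    for (i in seq_len(nrow(ranges))) {
      if (ranges[i, 1] > start) { cap <- ranges[i, 1]; break }
      start <- max(start, ranges[i, 2])
    }
  }
  if (!is.na(total_spots) && start >= total_spots)
    stop_contract("run is exhausted: no spots left to download")
  end <- min(start + batch_size, cap,
             if (is.na(total_spots)) Inf else total_spots)
  c(start = start, end = end)
}

# TRUE when the downloaded ranges cover [0, total_spots)
ranges_cover_all <- function(ranges, total_spots) {
  if (is.na(total_spots)) return(FALSE)
  if (is.null(ranges) || nrow(ranges) == 0L) return(total_spots == 0)
  sum(ranges[, 2] - ranges[, 1]) >= total_spots
}
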