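#' Set of genomic introns
#'
#' An intron is a pair of genome coordinates — the first and last intronic
#' base, 1-based inclusive, on a named sequence — and each intron is counted
#' only once: the container has set semantics over `(seqname, start, end)`.
#' Strand is deliberately not part of intron identity (inferring the strand
#' of a spliced alignment is a downstream concern); see `strand` to carry it
#' along where available.
#'
#' @param seqname,start,end Parallel vectors of coordinates; `start <= end`.
#' @param count Optional supporting-alignment counts (summed over duplicate
#'   coordinates).
#' @param strand Optional strand annotation (kept, not part of identity).
#' @return Object of class `intron_set` (a data frame, one row per distinct
#'   intron, ordered by coordinate).
#' @export
intron_set <- function(seqname, start, end, count = NULL, strand = NULL) {
  n <- length(start)
  stopifnot(length(end) == n)
  seqname <- rep_len(as.character(seqname), n)
  if (n && any(end < start)) stop_contract("intron end before start")
  df <- data.frame(seqname = as.character(seqname), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  df$count <- if (is.null(count)) rep(1L, n) else as.integer(count)
  if (!is.null(strand)) df$strand <- as.character(strand)
  if (n) {
    dt <- data.table::as.data.table(df)
    seqname <- start <- end <- NULL # data.table NSE
    agg <- if (is.null(strand)) {
      dt[, list(count = sum(count)), by = list(seqname, start, end)]
    } else {
      dt[, list(count = sum(count), strand = strand[1L]),
         by = list(seqname, start, end)]
    }
    df <- as.data.frame(agg[order(agg$seqname, agg$start, agg$end), ])
  }
  rownames(df) <- NULL
  class(df) <- c("intron_set", "data.frame")
  df
}

intron_keys <- function(x) {
  if (!nrow(x)) return(character())
  paste(x$seqname, x$start, x$end, sep = ":")
}

#' @export
print.intron_set <- function(x, ...) {
  cat(sprintf("intron_set: %d intron(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Reference coding introns from a GFF3 annotation
#'
#' Extracts the introns of protein-coding regions: for each transcript the
#' CDS features (grouped by their `Parent` attribute, with a
#' `transcript_id`/`gene_id` fallback for GTF-flavoured input) are sorted by
#' coordinate, and every gap between consecutive CDS parts becomes an intron
#' `(end_i + 1, start_{i+1} - 1)`. Introns shared between transcripts or
#' genes are counted once. Coding introns are used as the reference because
#' their annotation is more reliable than that of UTR or non-coding introns.
#'
#' Transcripts with overlapping CDS parts are skipped with a warning;
#' abutting CDS parts (zero-length gap) yield no intron.
#'
#' @param annotation Path to a GFF3 (or GTF) file with CDS features.
#' @return An [intron_set()].
#' @export
reference_coding_introns <- function(annotation) {
  gr <- rtracklayer::import(annotation)
  cds <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (!length(cds)) stop_contract("annotation contains no CDS features")

  parent <- if (!is.null(cds$Parent)) {
    p <- as(cds$Parent, "CharacterList")
    pl <- lengths(p)
    if (any(pl == 0) || any(pl > 1)) {
      # expand multi-parent CDS; group orphans by transcript/gene id fallback
      fallback <- cds$transcript_id %||% cds$gene_id %||%
        rep(NA_character_, length(cds))
      idx <- rep(seq_along(cds), pmax(pl, 1L))
      par <- unlist(ifelse(pl == 0, as.list(fallback), as.list(p)))
      cds <- cds[idx]
      par
    } else unlist(p)
  } else {
    cds$transcript_id %||% cds$gene_id %||%
      stop_contract("CDS features carry neither Parent nor transcript_id")
  }
  keep <- !is.na(parent)
  cds <- cds[keep]; parent <- parent[keep]

  dt <- data.table(parent = parent,
                   seqname = as.character(GenomicRanges::seqnames(cds)),
                   start = GenomicRanges::start(cds),
                   end = GenomicRanges::end(cds),
                   strand = as.character(GenomicRanges::strand(cds)))
  data.table::setorder(dt, parent, start)
  seqname <- start <- end <- NULL # data.table NSE
  res <- dt[, {
    if (.N < 2L) {
      list(seqname = character(), istart = integer(), iend = integer(),
           strand = character())
    } else if (any(start[-1L] <= end[-.N])) {
      warning(sprintf("transcript %s has overlapping CDS parts; skipped",
                      .BY[[1L]]), call. = FALSE)
      list(seqname = character(), istart = integer(), iend = integer(),
           strand = character())
    } else {
      gap <- start[-1L] - end[-.N] > 1L # abutting parts yield no intron
      list(seqname = seqname[-1L][gap], istart = end[-.N][gap] + 1L,
           iend = start[-1L][gap] - 1L, strand = strand[-1L][gap])
    }
  }, by = parent]
  intron_set(res$seqname, res$istart, res$iend, strand = res$strand)
}

#' Intron-level sensitivity and specificity
#'
#' Compares a predicted intron set (typically introns induced by spliced
#' alignments) with a reference set (typically annotated coding introns):
#' sensitivity is the fraction of reference introns also predicted,
#' specificity the fraction of predicted introns present in the reference.
#' Identity is by coordinate pair `(seqname, start, end)` unless
#' `strand_aware = TRUE` and both sets carry strand.
#'
#' @param predicted,reference [intron_set()] objects in the same coordinate
#'   convention.
#' @param strand_aware Include strand in intron identity (both sets must
#'   carry a `strand` column).
#' @return Named numeric `c(sensitivity, specificity)`. An empty reference
#'   makes sensitivity `NA` (with a warning); an empty prediction makes
#'   specificity `NA` and sensitivity 0.
#' @examples
#' ref <- intron_set(rep("s", 4), c(1, 10, 20, 30), c(5, 15, 25, 35))
#' prd <- intron_set(rep("s", 3), c(1, 10, 40), c(5, 15, 45))
#' intron_accuracy(prd, ref) # 0.5, 2/3
#' @export
intron_accuracy <- function(predicted, reference, strand_aware = FALSE) {
  key <- function(x) {
    if (strand_aware) {
      if (is.null(x$strand)) stop_contract("strand_aware requires strand columns")
      paste(intron_keys(x), x$strand, sep = ":")
    } else intron_keys(x)
  }
  pk <- key(predicted); rk <- key(reference)
  tp <- sum(pk %in% rk)
  sn <- if (length(rk) == 0) {
    warning("empty reference intron set: sensitivity undefined", call. = FALSE)
    NA_real_
  } else tp / length(rk)
  sp <- if (length(pk) == 0) NA_real_ else tp / length(pk)
  if (length(pk) == 0 && length(rk) > 0) sn <- 0
  c(sensitivity = sn, specificity = sp)
}

#' Accuracy as a function of downloaded spots
#'
#' Recomputes intron sensitivity and specificity after each batch of a
#' sampling execution, in download order: the prediction after batch k is
#' the union of introns observed in batches 1..k, and the x-coordinate is
#' the cumulative number of downloaded spots (not aligned reads). Since the
#' predicted set only grows, sensitivity is non-decreasing along the curve,
#' while specificity typically decays once false introns accumulate faster
#' than new true ones.
#'
#' @param result A `sampling_run` from [run_loop()] or [load_all_once()].
#' @param reference Reference [intron_set()].
#' @return Data frame with one row per batch: `batch`, `run_id`, `spots`
#'   (cumulative), `n_predicted`, `sensitivity`, `specificity`.
#' @export
accuracy_curve <- function(result, reference) {
  stopifnot(inherits(result, "sampling_run"))
  rk <- intron_keys(reference)
  n_batches <- nrow(result$log)
  seen <- new.env(parent = emptyenv())
  n_pred <- 0L; tp <- 0L
  out <- data.frame(batch = result$log$batch, run_id = result$log$run_id,
                    spots = result$log$cum_spots, n_predicted = 0L,
                    sensitivity = NA_real_, specificity = NA_real_)
  ref_env <- new.env(parent = emptyenv())
  for (k in rk) assign(k, TRUE, envir = ref_env)
  for (i in seq_len(n_batches)) {
    b <- result$batch_introns[[i]]
    if (nrow(b)) {
      keys <- paste(b$seqname, b$start, b$end, sep = ":")
      for (k in keys) {
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          n_pred <- n_pred + 1L
          if (exists(k, envir = ref_env, inherits = FALSE)) tp <- tp + 1L
        }
      }
    }
    out$n_predicted[i] <- n_pred
    out$sensitivity[i] <- if (length(rk)) tp / length(rk) else NA_real_
    out$specificity[i] <- if (n_pred) tp / n_pred else NA_real_
  }
  out
}

#' Write observed introns as GFF-style hints
#'
#' Serializes an intron set (with supporting-alignment counts) as a
#' GFF3-style intron hints file of the kind annotation pipelines consume.
#'
#' @param introns An [intron_set()].
#' @param path Output path.
#' @param source Value of the GFF source column.
#' @return `path`, invisibly.
#' @export
write_intron_hints <- function(introns, path, source = "srasampler") {
  lines <- sprintf("%s\t%s\tintron\t%d\t%d\t%d\t%s\t.\tmult=%d;",
                   introns$seqname, source, introns$start, introns$end,
                   introns$count, introns$strand %||% rep(".", nrow(introns)),
                   introns$count)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
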