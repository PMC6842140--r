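#' @import data.table
NULL

cigar_valid <- function(cigar) grepl("^([0-9]+[MIDNSHP=X])+$", cigar)

# reference-consuming CIGAR operations
REF_OPS <- c("M", "D", "N", "=", "X")

#' Extract introns induced by spliced alignments from CIGAR strings
#'
#' Every `N` (skipped-reference) operation of an alignment spans an intron.
#' For an alignment starting at 1-based position `p`, an `N` of length `n`
#' preceded by `o` reference-consuming bases yields the intron
#' `(p + o, p + o + n - 1)` — the first and last intronic base, 1-based
#' inclusive. Multiple `N` operations yield multiple introns in order.
#'
#' @param pos Integer vector of 1-based leftmost alignment positions.
#' @param cigar Character vector of CIGAR strings (same length as `pos`).
#' @param seqname Character vector of reference sequence names.
#' @return A data frame with columns `seqname`, `start`, `end`, one row per
#'   intron, in input order.
#' @examples
#' cigar_introns(1, "10M100N10M", "chr1")      # intron (11, 110)
#' cigar_introns(100, "5M10N5M20N5M", "chr1")  # (105,114) and (125,144)
#' @export
cigar_introns <- function(pos, cigar, seqname) {
  n <- length(cigar)
  stopifnot(length(pos) == n, length(seqname) == n)
  hits <- which(grepl("N", cigar, fixed = TRUE))
  if (!length(hits))
    return(data.frame(seqname = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  o_sq <- o_st <- o_en <- vector("list", length(hits))
  lens_all <- strsplit(cigar[hits], "[MIDNSHP=X]")
  ops_all <- strsplit(gsub("[0-9]+", "", cigar[hits]), "")
  for (k in seq_along(hits)) {
    i <- hits[k]
    if (!cigar_valid(cigar[i])) stop_contract("malformed CIGAR: %s", cigar[i])
    lens <- as.numeric(lens_all[[k]])
    ops <- ops_all[[k]]
    ref_len <- lens
    ref_len[!(ops %in% REF_OPS)] <- 0
    before <- cumsum(c(0, ref_len[-length(ref_len)]))
    is_n <- ops == "N"
    if (any(lens[is_n] == 0)) stop_contract("zero-length N operation in CIGAR: %s", cigar[i])
    st <- pos[i] + before[is_n]
    o_sq[[k]] <- rep(seqname[i], sum(is_n))
    o_st[[k]] <- st
    o_en[[k]] <- st + lens[is_n] - 1
  }
  data.frame(seqname = unlist(o_sq), start = as.integer(unlist(o_st)),
             end = as.integer(unlist(o_en)), stringsAsFactors = FALSE)
}

#' Classify one batch of alignment records
#'
#' Turns the alignment records of a downloaded batch into per-spot
#' classification counts, per-tile coverage increments and the set of introns
#' induced by spliced alignments. Every spot (read, or read pair for paired
#' libraries) is classified exactly once as uniquely aligned, multi-mapped,
#' or unmapped:
#' * an alignment is *unique* when its `NH` tag equals 1, or — where the
#'   aligner emits no `NH` — when its mapping quality is at least
#'   `mapq_unique`;
#' * a paired spot is unique when at least one mate aligns uniquely; the
#'   leftmost-mapping uniquely aligned mate is the spot's representative;
#' * only uniquely aligned spots increment coverage, `+1` to the tile holding
#'   the leftmost aligned base of the representative alignment;
#' * a unique spot is *spliced* when any of its alignments contains an `N`
#'   CIGAR operation; introns are recorded from the `N` operations of its
#'   unique alignments.
#'
#' Secondary and supplementary records are ignored. Records with malformed
#' CIGAR strings or positions outside the reference are counted as unmapped
#' with a warning.
#'
#' @param records Data frame of alignment records with columns `qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar` and optionally `nh` (the NH
#'   tag; `NA` where absent). Unmapped records carry flag bit 0x4.
#' @param tiles A [tile_index()].
#' @param run_id Run identifier the batch belongs to.
#' @param paired Logical; whether the library is paired-end (spot = pair).
#' @param n_spots Number of spots actually downloaded for the batch. Spots
#'   without any record are counted as unmapped. Defaults to the number of
#'   distinct query names.
#' @param mapq_unique Mapping-quality cutoff for the NH-less uniqueness call.
#' @return An object of class `batch_result`: classification counts
#'   (`spots_downloaded`, `spots_unique`, `spots_multi`, `spots_unmapped`,
#'   `spots_spliced`), `tile_counts` (named by tile index) and `introns`
#'   (data frame with per-intron supporting-alignment counts).
#' @export
classify_batch <- function(records, tiles, run_id = "run", paired = FALSE,
                           n_spots = NULL, mapq_unique = 30) {
  stopifnot(inherits(tiles, "tile_index"))
  r <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("qname", "flag", "rname", "pos", "mapq", "cigar")
  if (!all(needed %in% names(r)))
    stop_contract("records must have columns %s", paste(needed, collapse = ", "))
  if (is.null(r$nh)) r$nh <- NA_integer_

  r <- r[bitwAnd(r$flag, 0x900L) == 0L, , drop = FALSE] # primary records only
  mapped <- bitwAnd(r$flag, 0x4L) == 0L & !is.na(r$rname) & !is.na(r$pos)

  bad_cigar <- mapped & !cigar_valid(r$cigar)
  if (any(bad_cigar)) {
    warning(sprintf("%d record(s) with malformed CIGAR counted as unmapped",
                    sum(bad_cigar)))
    mapped[bad_cigar] <- FALSE
  }
  seqlen <- tiles$seqlengths[match(r$rname, tiles$seqnames)]
  oob <- mapped & (is.na(seqlen) | r$pos < 1 | r$pos > seqlen)
  if (any(oob)) {
    warning(sprintf("%d record(s) outside the reference counted as unmapped",
                    sum(oob)))
    mapped[oob] <- FALSE
  }

  uniq <- mapped & ifelse(!is.na(r$nh), r$nh == 1L, r$mapq >= mapq_unique)
  spliced <- mapped & grepl("N", r$cigar, fixed = TRUE)

  if (!paired && !anyDuplicated(r$qname)) {
    # fast path: one primary record per spot
    spot_unique <- uniq
    spot_mapped <- mapped
    spot_spliced <- uniq & spliced
    rep_rname <- r$rname[spot_unique]
    rep_pos <- r$pos[spot_unique]
  } else {
    dt <- data.table(qname = r$qname, mapped = mapped, uniq = uniq,
                     spliced = spliced, rname = r$rname, pos = r$pos)
    # representative = leftmost-mapping uniquely aligned record of the spot
    ag <- dt[, {
      u <- which(uniq)
      rep_i <- if (length(u)) u[which.min(pos[u])] else NA_integer_
      list(spot_unique = length(u) > 0L,
           spot_mapped = any(mapped),
           spot_spliced = length(u) > 0L && any(spliced),
           rep_rname = if (is.na(rep_i)) NA_character_ else rname[rep_i],
           rep_pos = if (is.na(rep_i)) NA_integer_ else pos[rep_i])
    }, by = qname]
    spot_unique <- ag$spot_unique
    spot_mapped <- ag$spot_mapped
    spot_spliced <- ag$spot_spliced
    rep_rname <- ag$rep_rname[spot_unique]
    rep_pos <- ag$rep_pos[spot_unique]
  }

  n_obs <- if (!paired && !anyDuplicated(r$qname)) nrow(r) else length(spot_unique)
  spots_downloaded <- as.integer(n_spots %||% n_obs)
  if (spots_downloaded < n_obs)
    stop_contract("n_spots (%d) smaller than the number of observed spots (%d)",
                  spots_downloaded, n_obs)

  n_unique <- sum(spot_unique)
  n_multi <- sum(spot_mapped & !spot_unique)
  n_unmapped <- spots_downloaded - n_unique - n_multi

  tile_idx <- tile_of(tiles, rep_rname, rep_pos)
  tile_counts <- if (length(tile_idx)) table(tile_idx) else integer()
  tile_counts <- setNames(as.numeric(tile_counts), names(tile_counts))

  intr_src <- which(uniq & spliced)
  introns <- cigar_introns(r$pos[intr_src], r$cigar[intr_src], r$rname[intr_src])
  if (nrow(introns)) {
    dti <- data.table(introns)
    introns <- as.data.frame(
      dti[, list(count = .N), by = list(seqname, start, end)])
  } else {
    introns$count <- integer()
  }

  structure(list(
    run_id = run_id,
    spots_downloaded = spots_downloaded,
    spots_unique = as.integer(n_unique),
    spots_multi = as.integer(n_multi),
    spots_unmapped = as.integer(n_unmapped),
    spots_spliced = as.integer(sum(spot_spliced)),
    tile_counts = tile_counts,
    introns = introns
  ), class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf(
    "batch_result [%s]: %d spots (%d unique, %d multi, %d unmapped, %d spliced), %d tile(s), %d intron(s)\n",
    x$run_id, x$spots_downloaded, x$spots_unique, x$spots_multi,
    x$spots_unmapped, x$spots_spliced, length(x$tile_counts), nrow(x$introns)))
  invisible(x)
}

#' Run-quality filter on a first batch
#'
#' A run whose first downloaded batch has fewer than
#' `threshold` (default 5%) uniquely aligning spots is permanently
#' blacklisted: such runs are typically mislabeled genomic libraries, very
#' short reads or otherwise unalignable data. A run at exactly the threshold
#' is kept. A batch with zero downloaded spots blacklists the run.
#'
#' @param batch A `batch_result` for the run's first batch.
#' @param threshold Minimum unique-alignment fraction in `[0, 1]`.
#' @return `TRUE` to keep the run, `FALSE` to blacklist it.
#' @export
quality_filter <- function(batch, threshold = 0.05) {
  stopifnot(inherits(batch, "batch_result"), threshold >= 0, threshold <= 1)
  if (batch$spots_downloaded == 0) return(FALSE)
  batch$spots_unique / batch$spots_downloaded >= threshold
}

#' Read alignment records from SAM/BAM
#'
#' Loads the fields the classifier needs (query name, flag, reference,
#' position, mapping quality, CIGAR and the NH tag) from a BAM file, or from
#' SAM text which is converted on the fly.
#'
#' @param path Path to a `.bam` or `.sam` file.
#' @return Data frame of records suitable for [classify_batch()].
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM/BAM requires the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "NH")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  data.frame(qname = b$qname, flag = b$flag,
             rname = as.character(b$rname), pos = b$pos,
             mapq = b$mapq, cigar = b$cigar,
             nh = if (is.null(b$tag$NH)) NA_integer_ else b$tag$NH,
             stringsAsFactors = FALSE)
}

#' Write alignment records as SAM text
#'
#' Serializes a record data frame (e.g. simulator output) to a SAM file with
#' a header derived from the tile index's sequence lengths, so external tools
#' (samtools sort/merge) and BAM conversion can be applied downstream.
#'
#' @param records Record data frame as consumed by [classify_batch()].
#' @param tiles A [tile_index()] providing sequence names and lengths.
#' @param path Output path; records are appended when `append = TRUE`.
#' @param append Logical; append without repeating the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, tiles, path, append = FALSE) {
  r <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(r$nh)) r$nh <- NA_integer_
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  if (!append) {
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", tiles$seqnames,
                         as.integer(tiles$seqlengths))), con)
  }
  unmapped <- bitwAnd(r$flag, 0x4L) != 0L | is.na(r$rname)
  lines <- paste(r$qname, r$flag,
                 ifelse(unmapped, "*", r$rname),
                 ifelse(unmapped, 0L, r$pos),
                 ifelse(unmapped, 0L, r$mapq),
                 ifelse(unmapped, "*", r$cigar),
                 "*", 0L, 0L, "*", "*",
                 sep = "\t")
  lines <- ifelse(is.na(r$nh), lines, paste0(lines, "\tNH:i:", r$nh))
  writeLines(lines, con)
  invisible(path)
}
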