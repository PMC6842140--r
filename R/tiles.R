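#' Genome tile index
#'
#' Partitions a genome into fixed-size non-overlapping windows ("tiles") that
#' serve as a proxy for transcribed units when counting read coverage. Each
#' sequence is cut into half-open windows of `tile_size` bp; the last tile of
#' a sequence may be shorter. Tiles are numbered 1..T across sequences in the
#' order given.
#'
#' @param seqlengths Named integer vector of sequence lengths in bp (names are
#'   sequence names, e.g. chromosome identifiers).
#' @param tile_size Tile width in bp (default 5000).
#' @return An object of class `tile_index`: a list with `seqnames`,
#'   `seqlengths`, `tile_size`, per-sequence tile offsets and the total tile
#'   count `T`.
#' @examples
#' ti <- tile_index(c(chr1 = 12000, chr2 = 4000))
#' ti$T  # ceiling(12000/5000) + ceiling(4000/5000) = 3 + 1
#' tile_of(ti, c("chr1", "chr2"), c(5001, 1))
#' @export
tile_index <- function(seqlengths, tile_size = 5000) {
  if (length(seqlengths) < 1L) stop_contract("at least one sequence is required")
  if (is.null(names(seqlengths)) || anyDuplicated(names(seqlengths)))
    stop_contract("seqlengths must have unique names")
  if (!is_count(tile_size) || tile_size < 1) stop_contract("tile_size must be a positive integer")
  nms <- names(seqlengths)
  seqlengths <- setNames(as.numeric(seqlengths), nms)
  if (any(is.na(seqlengths)) || any(seqlengths < 1))
    stop_contract("all sequence lengths must be positive")
  n_tiles <- ceiling(seqlengths / tile_size)
  structure(list(
    seqnames = nms,
    seqlengths = seqlengths,
    tile_size = as.integer(tile_size),
    n_tiles = as.integer(n_tiles),
    offsets = setNames(cumsum(c(0, head(n_tiles, -1L))), names(seqlengths)),
    T = as.integer(sum(n_tiles))
  ), class = "tile_index")
}

#' @export
print.tile_index <- function(x, ...) {
  cat(sprintf("tile_index: %d sequence(s), tile size %d bp, T = %d tiles\n",
              length(x$seqnames), x$tile_size, x$T))
  invisible(x)
}

#' Build a tile index from a genome FASTA
#'
#' Only sequence names and lengths are used; sequence content is ignored.
#'
#' @param path Path to a FASTA file.
#' @inheritParams tile_index
#' @return A [tile_index()].
#' @export
tile_index_from_fasta <- function(path, tile_size = 5000) {
  if (!file.exists(path)) stop_contract("FASTA file not found: %s", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    fa <- Biostrings::fasta.seqlengths(path)
    lens <- setNames(as.numeric(fa), sub("\\s.*$", "", names(fa)))
  } else {
    # header/line accounting without loading sequences into memory at once
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    grp <- cumsum(hdr)
    nm <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
    lens <- setNames(as.numeric(tapply(nchar(lines[!hdr]), grp[!hdr], sum)), nm)
  }
  tile_index(lens, tile_size = tile_size)
}

#' Map genome positions to tile indices
#'
#' @param tiles A [tile_index()].
#' @param seqname Character vector of sequence names.
#' @param pos Integer vector of 1-based positions.
#' @return Integer vector of tile indices in 1..T; `NA` where the sequence is
#'   unknown or the position lies outside the sequence.
#' @export
tile_of <- function(tiles, seqname, pos) {
  stopifnot(inherits(tiles, "tile_index"))
  off <- tiles$offsets[seqname]
  len <- tiles$seqlengths[match(seqname, tiles$seqnames)]
  idx <- as.integer(off + (pos - 1) %/% tiles$tile_size + 1)
  idx[is.na(off) | pos < 1 | pos > len] <- NA_integer_
  idx
}
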