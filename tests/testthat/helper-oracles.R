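# Independent oracles and fixture builders used across the suite.
# The oracles deliberately re-derive quantities with naive scalar loops or
# per-base expansion, independent of the package's vectorized code paths.

# scalar-loop evaluation of the pseudocount profile estimate
oracle_profile <- function(cr, pbar, lambda, a) {
  T <- length(cr)
  w <- numeric(T)
  for (j in seq_len(T)) w[j] <- cr[j] + lambda * T * pbar[j] + a
  s <- 0
  for (j in seq_len(T)) s <- s + w[j]
  w / s
}

# naive per-run evaluation of the greedy objective S(c + b * q * p)
oracle_expected_scores <- function(cvec, counts, quality, params) {
  T <- length(cvec)
  run_ids <- colnames(counts)
  tot <- sum(counts)
  pbar <- if (tot == 0) rep(1 / T, T) else rowSums(counts) / tot
  out <- setNames(numeric(length(run_ids)), run_ids)
  for (r in run_ids) {
    q <- if (quality[r, "n_sampled"] == 0) params$q_init else
      params$q_weights[["unique"]] * quality[r, "n_unique"] / quality[r, "n_sampled"] +
      params$q_weights[["spliced"]] * quality[r, "n_spliced"] / quality[r, "n_sampled"]
    p <- oracle_profile(counts[, r], pbar, params$lambda, params$pseudocount)
    s <- 0
    for (j in seq_len(T)) s <- s + log(1 + cvec[j] + params$batch_size * q * p[j])
    out[r] <- s
  }
  out
}

oracle_argmax_set <- function(scores, rel_tol = 1e-12) {
  best <- max(scores)
  names(scores)[(best - scores) <= rel_tol * max(abs(best), 1)]
}

# per-base CIGAR expansion: label every reference base with its operation,
# then read introns off as maximal runs of N-labelled bases
oracle_cigar_introns <- function(pos, cigar) {
  lens <- as.numeric(strsplit(cigar, "[MIDNSHP=X]")[[1]])
  ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1]]
  consumes <- ops %in% c("M", "D", "N", "=", "X")
  labels <- rep(ops[consumes], lens[consumes])
  coords <- pos + seq_along(labels) - 1
  r <- rle(labels == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = coords[starts[keep]], end = coords[ends[keep]])
}

# build an alignment record data frame row-wise with sensible defaults
make_records <- function(qname, rname = "seq1", pos = 1L, cigar = "100M",
                         nh = 1L, mapq = 60L, flag = 0L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = as.integer(pos),
             mapq = as.integer(mapq), cigar = cigar, nh = as.integer(nh),
             stringsAsFactors = FALSE)
}

# coverage state with prescribed per-run counts and quality statistics
make_state <- function(tiles, counts, quality = NULL) {
  st <- coverage_state(tiles, colnames(counts))
  st$counts <- counts
  st$c <- rowSums(counts)
  if (!is.null(quality)) {
    st$quality[rownames(quality), c("n_sampled", "n_unique", "n_spliced")] <-
      quality[, c("n_sampled", "n_unique", "n_spliced")]
  }
  st
}

# random small selection instance: some runs sampled with random counts
rand_instance <- function(T = NULL, R = NULL) {
  T <- T %||% sample(2:50, 1)
  R <- R %||% sample(2:10, 1)
  tiles <- tile_index(c(s = T * 5000), tile_size = 5000)
  ids <- sprintf("R%02d", seq_len(R))
  counts <- matrix(0, T, R, dimnames = list(NULL, ids))
  n_sampled <- sample(0:3, R, replace = TRUE) * sample(c(0, 100, 500), R, replace = TRUE)
  qual <- data.frame(n_sampled = n_sampled, n_unique = 0, n_spliced = 0,
                     row.names = ids)
  for (r in seq_len(R)) {
    if (n_sampled[r] > 0) {
      qual$n_unique[r] <- rbinom(1, n_sampled[r], runif(1, 0.1, 1))
      qual$n_spliced[r] <- rbinom(1, qual$n_unique[r], 0.3)
      hot <- sample(T, min(T, sample(1:8, 1)))
      counts[hot, r] <- rmultinom(1, qual$n_unique[r], runif(length(hot)))[, 1]
    }
  }
  run_list <- data.frame(run_id = ids, paired = FALSE,
                         avg_read_length = sample(c(50, 75, 100, 150), R, TRUE),
                         total_spots = 1e6, stringsAsFactors = FALSE)
  list(tiles = tiles, state = make_state(tiles, counts, qual),
       run_list = run_list,
       counts = counts, quality = qual)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiles overlapped by any exonic base of any gene of a simulated archive
expressed_gene_tiles <- function(archive, tiles) {
  idx <- unlist(lapply(archive$genes, function(g) {
    n <- length(g$exon_starts)
    c(tile_of(tiles, rep(g$seqname, n), g$exon_starts),
      tile_of(tiles, rep(g$seqname, n), g$exon_ends))
  }))
  sort(unique(idx))
}
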