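#' Configuration of a synthetic sequencing-run archive
#'
#' Describes a simulated SRA-like archive: a genome, single-transcript gene
#' models with known introns, and a catalogue of sequencing runs that each
#' express the genes under their own multinomial profile. A configurable
#' fraction of runs is of a "bad" quality class emulating the heterogeneity
#' of real archives (mislabeled genomic libraries, barely alignable reads).
#'
#' Gene structures are drawn uniformly within the given ranges and laid out
#' left to right along the sequences with random intergenic gaps. Run
#' profiles over genes are drawn from a symmetric Dirichlet; small
#' concentrations (default 0.1) give the strongly tissue-skewed expression
#' that makes complementary sampling worthwhile.
#'
#' @param seed Integer seed; the archive is fully reproducible from it.
#' @param n_seqs,seq_length Number and length (bp) of genome sequences.
#' @param n_genes Number of genes (one transcript each).
#' @param exon_count,exon_length,intron_length,intergenic Inclusive
#'   `c(min, max)` ranges for exons per gene, exon length, intron length and
#'   intergenic gap, in bp.
#' @param genes Optional explicit gene models overriding random generation: a
#'   list of `list(seqname=, strand=, exon_starts=, exon_ends=)`.
#' @param n_runs Number of runs in the archive.
#' @param frac_bad Fraction of runs of the bad quality class; the bad-run
#'   count is `round(frac_bad * n_runs)`, assigned to a seeded random subset.
#' @param bad_class `"low_alignability"` (reads mostly unmapped or
#'   multi-mapped) or `"mislabeled_genomic"` (a genomic library mislabeled as
#'   transcriptomic: reads placed uniformly on the genome, no splicing).
#' @param unalignable_frac For low-alignability runs, the fraction of spots
#'   emitted as unmapped or multi-mapped (default 0.97, i.e. 3% unique —
#'   below the 5% quality threshold).
#' @param dirichlet_alpha Symmetric Dirichlet concentration of run profiles.
#' @param profiles Optional explicit genes x runs profile matrix (columns
#'   sum to 1) overriding the Dirichlet draw.
#' @param read_length Read length in bp, scalar or one value per run.
#' @param total_spots Spots per run, scalar or one value per run.
#' @return An object of class `archive_config` (a validated list).
#' @export
archive_config <- function(seed = 1,
                           n_seqs = 1, seq_length = 1e6,
                           n_genes = 200,
                           exon_count = c(2, 5),
                           exon_length = c(150, 400),
                           intron_length = c(60, 200),
                           intergenic = c(500, 4500),
                           genes = NULL,
                           n_runs = 30,
                           frac_bad = 0,
                           bad_class = c("low_alignability", "mislabeled_genomic"),
                           unalignable_frac = 0.97,
                           dirichlet_alpha = 0.1,
                           profiles = NULL,
                           read_length = 100,
                           total_spots = 1e5) {
  bad_class <- match.arg(bad_class)
  if (frac_bad < 0 || frac_bad > 1) stop_contract("frac_bad must lie in [0, 1]")
  if (unalignable_frac < 0 || unalignable_frac > 1)
    stop_contract("unalignable_frac must lie in [0, 1]")
  if (is.null(genes) && n_genes < 1) stop_contract("need at least one gene")
  if (n_runs < 1) stop_contract("need at least one run")
  read_length <- rep_len(read_length, n_runs)
  total_spots <- rep_len(total_spots, n_runs)
  structure(list(
    seed = as.integer(seed), n_seqs = as.integer(n_seqs),
    seq_length = seq_length, n_genes = as.integer(n_genes),
    exon_count = exon_count, exon_length = exon_length,
    intron_length = intron_length, intergenic = intergenic,
    genes = genes, n_runs = as.integer(n_runs), frac_bad = frac_bad,
    bad_class = bad_class, unalignable_frac = unalignable_frac,
    dirichlet_alpha = dirichlet_alpha, profiles = profiles,
    read_length = read_length, total_spots = total_spots
  ), class = "archive_config")
}

#' Read an archive configuration from a YAML file
#'
#' Keys mirror the arguments of [archive_config()].
#'
#' @param path Path to a YAML file.
#' @return An `archive_config`.
#' @export
read_archive_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(archive_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_contract("unknown archive config key(s): %s", paste(unknown, collapse = ", "))
  do.call(archive_config, cfg)
}

finalize_gene <- function(seqname, strand, exon_starts, exon_ends) {
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
  if (any(exon_ends < exon_starts)) stop_contract("exon end before start")
  if (length(exon_starts) > 1 &&
      any(exon_starts[-1] <= exon_ends[-length(exon_ends)]))
    stop_contract("overlapping exons within a gene")
  widths <- exon_ends - exon_starts + 1
  list(seqname = seqname, strand = strand,
       exon_starts = as.numeric(exon_starts), exon_ends = as.numeric(exon_ends),
       widths = widths, cumtx = cumsum(widths), tx_len = sum(widths))
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Build a synthetic archive
#'
#' Materializes the genome layout, gene models (hence the ground-truth
#' intron set), run catalogue, quality classes and expression profiles
#' described by an [archive_config()]. Deterministic given the config seed.
#'
#' @param config An [archive_config()].
#' @return An object of class `sim_archive` with elements `seqlengths`,
#'   `genes`, `introns` (truth), `runs` (catalogue with quality `class`
#'   column) and `profiles` (genes x runs).
#' @export
build_archive <- function(config) {
  stopifnot(inherits(config, "archive_config"))
  with_private_seed(derive_seed(config$seed, 1), {
    seqlengths <- setNames(rep(config$seq_length, config$n_seqs),
                           sprintf("seq%d", seq_len(config$n_seqs)))
    if (!is.null(config$genes)) {
      genes <- lapply(config$genes, function(g)
        finalize_gene(g$seqname, g$strand %||% "+", g$exon_starts, g$exon_ends))
      for (g in genes) {
        if (!g$seqname %in% names(seqlengths))
          stop_contract("gene on unknown sequence %s", g$seqname)
        if (max(g$exon_ends) > seqlengths[[g$seqname]])
          stop_contract("gene exceeds sequence bounds")
      }
    } else {
      genes <- vector("list", config$n_genes)
      seq_i <- 1L
      cursor <- 1
      for (gi in seq_len(config$n_genes)) {
        n_ex <- runif_int(1, config$exon_count)
        ex_len <- runif_int(n_ex, config$exon_length)
        in_len <- if (n_ex > 1) runif_int(n_ex - 1, config$intron_length) else numeric()
        gap <- runif_int(1, config$intergenic)
        span <- sum(ex_len) + sum(in_len)
        start <- cursor + gap
        while (start + span - 1 > seqlengths[[seq_i]]) {
          seq_i <- seq_i + 1L
          if (seq_i > length(seqlengths))
            stop_contract("infeasible config: genome too small for %d genes", config$n_genes)
          cursor <- 1
          start <- cursor + gap
        }
        starts <- start + cumsum(c(0, head(ex_len, -1) + in_len))
        genes[[gi]] <- finalize_gene(names(seqlengths)[seq_i], sample(c("+", "-"), 1),
                                     starts, starts + ex_len - 1)
        cursor <- start + span
      }
    }
    introns <- do.call(rbind, lapply(seq_along(genes), function(gi) {
      g <- genes[[gi]]
      k <- length(g$exon_starts)
      if (k < 2) return(NULL)
      data.frame(seqname = g$seqname,
                 start = as.integer(g$exon_ends[-k] + 1),
                 end = as.integer(g$exon_starts[-1] - 1),
                 gene = gi, stringsAsFactors = FALSE)
    }))
    if (is.null(introns))
      introns <- data.frame(seqname = character(), start = integer(),
                            end = integer(), gene = integer())

    n_runs <- config$n_runs
    n_bad <- round(config$frac_bad * n_runs)
    class <- rep("good", n_runs)
    if (n_bad > 0) class[sample.int(n_runs, n_bad)] <- config$bad_class
    runs <- data.frame(
      run_id = sprintf("SIM%04d", seq_len(n_runs)),
      paired = FALSE,
      avg_read_length = config$read_length,
      total_spots = config$total_spots,
      class = class, stringsAsFactors = FALSE)

    n_genes <- length(genes)
    if (!is.null(config$profiles)) {
      profiles <- as.matrix(config$profiles)
      if (nrow(profiles) != n_genes || ncol(profiles) != n_runs)
        stop_contract("profiles must be a %d x %d matrix", n_genes, n_runs)
      profiles <- sweep(profiles, 2, colSums(profiles), "/")
    } else {
      profiles <- matrix(rgamma(n_genes * n_runs, shape = config$dirichlet_alpha),
                         nrow = n_genes)
      profiles[profiles < 1e-300] <- 1e-300
      profiles <- sweep(profiles, 2, colSums(profiles), "/")
    }
    colnames(profiles) <- runs$run_id

    structure(list(seed = config$seed, seqlengths = seqlengths, genes = genes,
                   introns = introns, runs = runs, profiles = profiles,
                   config = config),
              class = "sim_archive")
  })
}

#' @export
print.sim_archive <- function(x, ...) {
  cat(sprintf("sim_archive: %d seq(s) (%g bp), %d gene(s), %d true intron(s), %d run(s) (%d bad)\n",
              length(x$seqlengths), sum(x$seqlengths), length(x$genes),
              nrow(x$introns), nrow(x$runs), sum(x$runs$class != "good")))
  invisible(x)
}

#' Run catalogue of a synthetic archive
#'
#' The run-list view of the archive, as [run_loop()] expects. The quality
#' class is deliberately omitted: the sampler must discover bad runs from
#' the data, as with a real archive.
#'
#' @param archive A `sim_archive`.
#' @return Run-list data frame.
#' @export
archive_run_list <- function(archive) {
  archive$runs[c("run_id", "paired", "avg_read_length", "total_spots")]
}

#' Tile index over a synthetic archive's genome
#'
#' @param archive A `sim_archive`.
#' @param tile_size Tile width in bp.
#' @return A [tile_index()].
#' @export
archive_tiles <- function(archive, tile_size = 5000) {
  tile_index(archive$seqlengths, tile_size = tile_size)
}

#' Ground-truth introns of a synthetic archive
#'
#' @param archive A `sim_archive`.
#' @return An [intron_set()].
#' @export
true_introns <- function(archive) {
  intron_set(archive$introns$seqname, archive$introns$start, archive$introns$end)
}

# simulate reads for one good-run batch: spots pick a gene from the run's
# profile and a start uniform along the spliced transcript; the CIGAR gets
# an N operation wherever the read spans a true intron
sim_good_reads <- function(archive, run_idx, n) {
  prof <- archive$profiles[, run_idx]
  rl <- archive$runs$avg_read_length[run_idx]
  gidx <- sample.int(length(prof), n, replace = TRUE, prob = prof)
  pos <- integer(n); cig <- character(n); rn <- character(n)
  for (g in unique(gidx)) {
    sel <- which(gidx == g)
    gene <- archive$genes[[g]]
    rl_g <- min(rl, gene$tx_len)
    s <- sample.int(gene$tx_len - rl_g + 1, length(sel), replace = TRUE)
    e <- s + rl_g - 1
    cum0 <- c(0, gene$cumtx)
    i1 <- findInterval(s - 1, gene$cumtx) + 1L
    i2 <- findInterval(e - 1, gene$cumtx) + 1L
    pos[sel] <- gene$exon_starts[i1] + (s - (cum0[i1] + 1))
    same <- i1 == i2
    cig[sel[same]] <- paste0(rl_g, "M")
    for (k in which(!same)) {
      a <- i1[k]; b <- i2[k]
      mlens <- c(gene$cumtx[a] - s[k] + 1,
                 if (b - a > 1) gene$widths[(a + 1):(b - 1)],
                 e[k] - gene$cumtx[b - 1])
      nlens <- gene$exon_starts[(a + 1):b] - gene$exon_ends[a:(b - 1)] - 1
      cig[sel[k]] <- paste0(paste0(mlens, "M", c(paste0(nlens, "N"), "")),
                            collapse = "")
    }
    rn[sel] <- gene$seqname
  }
  data.frame(rname = rn, pos = pos, cigar = cig, mapq = 60L, nh = 1L,
             flag = 0L, stringsAsFactors = FALSE)
}

sim_genomic_reads <- function(archive, run_idx, n, nh, mapq) {
  rl <- archive$runs$avg_read_length[run_idx]
  sq <- sample.int(length(archive$seqlengths), n, replace = TRUE,
                   prob = archive$seqlengths)
  maxpos <- pmax(1, archive$seqlengths[sq] - rl + 1)
  pos <- floor(runif(n, min = 1, max = maxpos + 1))
  data.frame(rname = names(archive$seqlengths)[sq], pos = as.integer(pos),
             cigar = paste0(rl, "M"), mapq = mapq, nh = nh, flag = 0L,
             stringsAsFactors = FALSE)
}

#' Simulate the aligned batch for a spot range of a run
#'
#' Emits already-aligned records (no FASTQ, no aligner needed) for the
#' requested half-open spot interval, deterministically: the same
#' `(run, interval)` request always yields identical records, and requests
#' never perturb the caller's RNG state. Behaviour by quality class:
#' * `good` — every spot is a uniquely aligned read drawn from the run's
#'   expression profile, spliced (`N` operations) exactly where it spans
#'   true introns;
#' * `low_alignability` — a configured fraction (default 97%) of spots is
#'   unmapped or multi-mapped (`NH=2`), the remainder as for a good run;
#' * `mislabeled_genomic` — reads placed uniformly on the genome, uniquely
#'   aligned but never spliced.
#'
#' @param archive A `sim_archive`.
#' @param run_id Run identifier.
#' @param range Half-open spot interval `c(start, end)`, 0-based; truncated
#'   at the run's total spot count, with the actual count reported.
#' @return `list(records = <data frame>, n_spots = <spots retrieved>)`.
#' @export
sample_batch <- function(archive, run_id, range) {
  stopifnot(inherits(archive, "sim_archive"))
  run_idx <- match(run_id, archive$runs$run_id)
  if (is.na(run_idx)) stop_contract("unknown run id: %s", run_id)
  total <- archive$runs$total_spots[run_idx]
  if (range[1] < 0 || range[2] < range[1] || range[1] > total)
    stop_contract("spot interval [%g, %g) out of bounds for run %s",
                  range[1], range[2], run_id)
  end <- min(range[2], total)
  n <- unname(end - range[1])
  if (n == 0)
    return(list(records = data.frame(qname = character(), flag = integer(),
                                     rname = character(), pos = integer(),
                                     mapq = integer(), cigar = character(),
                                     nh = integer(), stringsAsFactors = FALSE),
                n_spots = 0))
  cls <- archive$runs$class[run_idx]
  rec <- with_private_seed(derive_seed(archive$seed, 7, run_idx, range[1]), {
    if (cls == "good") {
      sim_good_reads(archive, run_idx, n)
    } else if (cls == "mislabeled_genomic") {
      sim_genomic_reads(archive, run_idx, n, nh = 1L, mapq = 60L)
    } else { # low_alignability
      u <- runif(n)
      bad_unmapped <- u < archive$config$unalignable_frac / 2
      bad_multi <- !bad_unmapped & u < archive$config$unalignable_frac
      good <- !bad_unmapped & !bad_multi
      rec <- data.frame(rname = NA_character_, pos = NA_integer_,
                        cigar = NA_character_, mapq = 0L, nh = NA_integer_,
                        flag = 4L, stringsAsFactors = FALSE)[rep(1L, n), ]
      if (any(bad_multi))
        rec[bad_multi, ] <- sim_genomic_reads(archive, run_idx, sum(bad_multi),
                                              nh = 2L, mapq = 0L)
      if (any(good))
        rec[good, ] <- sim_good_reads(archive, run_idx, sum(good))
      rec
    }
  })
  rec$qname <- paste0(run_id, ".", seq(range[1], length.out = n))
  rownames(rec) <- NULL
  list(records = rec[c("qname", "flag", "rname", "pos", "mapq", "cigar", "nh")],
       n_spots = n)
}

#' Fetch-and-align adapter backed by a synthetic archive
#'
#' Wraps [sample_batch()] into the adapter contract [run_loop()] consumes,
#' so the whole sampling pipeline runs offline against simulated data.
#'
#' @param archive A `sim_archive`.
#' @return A `function(run_id, range)` returning `list(records, n_spots)`.
#' @export
simulator_source <- function(archive) {
  force(archive)
  function(run_id, range) sample_batch(archive, run_id, range)
}

#' Export the ground truth of a synthetic archive
#'
#' Writes the archive's truth as plain-text files: gene models as GFF3
#' (gene/mRNA/exon/CDS with Parent linkage, so [reference_coding_introns()]
#' applies directly), true introns and per-run expression profiles as TSV,
#' and the run catalogue as a run-list TSV.
#'
#' @param archive A `sim_archive`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_archive_truth <- function(archive, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  export_genes_gff3(archive, file.path(dir, "genes.gff3"))
  utils::write.table(archive$introns, file.path(dir, "true_introns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- data.frame(gene = seq_len(nrow(archive$profiles)), archive$profiles,
                     check.names = FALSE)
  utils::write.table(prof, file.path(dir, "true_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_list(archive_run_list(archive), file.path(dir, "run_list.tsv"))
  invisible(dir)
}

export_genes_gff3 <- function(archive, path) {
  rows <- lapply(seq_along(archive$genes), function(gi) {
    g <- archive$genes[[gi]]
    gene_id <- sprintf("gene%d", gi)
    tx_id <- sprintf("tx%d", gi)
    k <- length(g$exon_starts)
    data.frame(
      seqname = g$seqname,
      type = c("gene", "mRNA", rep(c("exon", "CDS"), each = k)),
      start = c(min(g$exon_starts), min(g$exon_starts),
                rep(g$exon_starts, 2)),
      end = c(max(g$exon_ends), max(g$exon_ends), rep(g$exon_ends, 2)),
      strand = g$strand,
      id = c(gene_id, tx_id, rep(NA_character_, 2 * k)),
      parent = c(NA_character_, gene_id, rep(tx_id, 2 * k)),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqname,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  gr$type <- tab$type
  gr$phase <- ifelse(tab$type == "CDS", 0L, NA_integer_)
  gr$ID <- tab$id
  gr$Parent <- S4Vectors::unname(
    IRanges::CharacterList(ifelse(is.na(tab$parent), list(character()),
                                  as.list(tab$parent))))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a random genome FASTA matching a synthetic archive
#'
#' Sequence content is random DNA (deterministic from the archive seed);
#' only names and lengths matter to the sampler, but a concrete FASTA lets
#' the external-aligner adapter be exercised end to end.
#'
#' @param archive A `sim_archive`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(archive, path) {
  seqs <- with_private_seed(derive_seed(archive$seed, 11), {
    vapply(archive$seqlengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  })
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names(archive$seqlengths)
    Biostrings::writeXStringSet(x, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(seqs)) {
      writeLines(paste0(">", nm), con)
      writeLines(substring(seqs[[nm]], seq(1, nchar(seqs[[nm]]), 70),
                           pmin(seq(1, nchar(seqs[[nm]]), 70) + 69,
                                nchar(seqs[[nm]]))), con)
    }
  }
  invisible(path)
}
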