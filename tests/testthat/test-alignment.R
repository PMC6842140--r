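tiles10k <- tile_index(c(seq1 = 10000), tile_size = 5000)

test_that("intron extraction matches manual CIGAR walks", {
  expect_equal(cigar_introns(1, "10M100N10M", "seq1"),
               data.frame(seqname = "seq1", start = 11L, end = 110L))
  expect_equal(nrow(cigar_introns(1, "20M", "seq1")), 0L)
  two <- cigar_introns(100, "5M10N5M20N5M", "seq1")
  expect_equal(two$start, c(105L, 120L))
  expect_equal(two$end, c(114L, 139L))
  # insertions and soft clips consume no reference
  expect_equal(cigar_introns(10, "5S5M2I50N5M", "seq1")$start, 15L)
  expect_error(cigar_introns(1, "5M0N5M", "seq1"),
               class = "srasampler_contract_error")
})

test_that("intron extraction agrees with a per-base expansion oracle", {
  set.seed(19)
  for (i in 1:500) {
    k <- sample(1:7, 1)
    # structurally plausible CIGARs: M segments separated by I/D/N events,
    # optional soft clips at the ends
    ops <- c(rbind(sample(c("I", "D", "N"), k, replace = TRUE), "M"))
    ops <- c(if (runif(1) < 0.3) "S", "M", ops, if (runif(1) < 0.3) "S")
    lens <- sample(1:200, length(ops), replace = TRUE)
    cigar <- paste0(lens, ops, collapse = "")
    pos <- sample(1:5000, 1)
    got <- cigar_introns(pos, cigar, "s")
    exp <- oracle_cigar_introns(pos, cigar)
    expect_equal(got$start, exp$start, info = cigar)
    expect_equal(got$end, exp$end, info = cigar)
  }
})

test_that("intron extraction agrees with GenomicAlignments junctions", {
  skip_if_not_installed("GenomicAlignments")
  set.seed(29)
  cigars <- replicate(60, {
    k <- sample(1:3, 1)
    m <- sample(5:80, k + 1, replace = TRUE)
    n <- sample(30:5000, k, replace = TRUE)
    paste0(paste0(m[-(k + 1)], "M", n, "N", collapse = ""), m[k + 1], "M")
  })
  pos <- sample(1:10000, 60, replace = TRUE)
  ours <- cigar_introns(pos, cigars, rep("s", 60))
  theirs <- do.call(rbind, lapply(seq_along(cigars), function(i) {
    j <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigars[i], pos = pos[i], ops = "N")[[1]]
    data.frame(start = BiocGenerics::start(j), end = BiocGenerics::end(j))
  }))
  expect_equal(ours$start, theirs$start)
  expect_equal(ours$end, theirs$end)
})

test_that("single-end spots are classified by uniqueness and tiled by leftmost base", {
  b <- classify_batch(make_records("r1", pos = 1, cigar = "100M"), tiles10k)
  expect_equal(b$spots_unique, 1L)
  expect_equal(b$tile_counts, c(`1` = 1))
  expect_equal(b$spots_spliced, 0L)

  # NH=3 multimapper contributes no coverage
  b <- classify_batch(make_records("r1", nh = 3), tiles10k)
  expect_equal(b$spots_multi, 1L)
  expect_equal(length(b$tile_counts), 0L)

  # spliced read at a tile boundary: leftmost base 4951 is still in tile 1
  b <- classify_batch(make_records("r1", pos = 4951, cigar = "50M200N50M"),
                      tiles10k)
  expect_equal(b$spots_unique, 1L)
  expect_equal(b$tile_counts, c(`1` = 1))
  expect_equal(b$spots_spliced, 1L)
  expect_equal(b$introns,
               data.frame(seqname = "seq1", start = 5001L, end = 5200L,
                          count = 1L))

  # without an NH tag, mapping quality decides uniqueness
  b <- classify_batch(make_records(c("a", "b"), nh = NA, mapq = c(60, 3)),
                      tiles10k)
  expect_equal(b$spots_unique, 1L)
  expect_equal(b$spots_multi, 1L)
})

test_that("paired spots count once via the leftmost uniquely aligned mate", {
  rec <- rbind(
    make_records("p1", pos = 6000, cigar = "50M", flag = 0x63),  # mate 1
    make_records("p1", pos = 200, cigar = "50M", flag = 0x93),   # mate 2, leftmost
    make_records("p2", pos = 300, cigar = "50M", flag = 0x63, nh = 4),
    make_records("p2", pos = 9000, cigar = "50M", flag = 0x93, nh = 1))
  b <- classify_batch(rec, tiles10k, paired = TRUE)
  expect_equal(b$spots_downloaded, 2L)
  expect_equal(b$spots_unique, 2L)
  # p1: both unique, representative is mate at 200 (tile 1)
  # p2: only the mate at 9000 is unique -> tile 2
  expect_equal(b$tile_counts, c(`1` = 1, `2` = 1))

  # a pair with only multimapped mates is multi, not unique
  rec2 <- rbind(make_records("p3", pos = 10, flag = 0x63, nh = 2),
                make_records("p3", pos = 500, flag = 0x93, nh = 2))
  b2 <- classify_batch(rec2, tiles10k, paired = TRUE)
  expect_equal(b2$spots_multi, 1L)
  expect_equal(b2$spots_unique, 0L)
})

test_that("classification is a partition and tile increments sum to unique spots", {
  set.seed(31)
  for (i in 1:10) {
    n <- 200
    status <- sample(c("u", "m", "x"), n, replace = TRUE)
    rec <- make_records(paste0("q", 1:n),
                        pos = sample(1:9000, n, replace = TRUE),
                        cigar = "50M",
                        nh = ifelse(status == "m", 2L, 1L),
                        flag = ifelse(status == "x", 4L, 0L))
    rec$rname[status == "x"] <- NA
    extra <- sample(0:20, 1) # spots downloaded but never reported by the aligner
    b <- classify_batch(rec, tiles10k, n_spots = n + extra)
    expect_identical(b$spots_unique + b$spots_multi + b$spots_unmapped,
                     b$spots_downloaded)
    expect_equal(sum(b$tile_counts), b$spots_unique)
    # determinism: same records give an identical result
    expect_identical(b, classify_batch(rec, tiles10k, n_spots = n + extra))
  }
})

test_that("malformed or out-of-bounds records degrade to unmapped with a warning", {
  rec <- rbind(make_records("ok", pos = 10),
               make_records("bad", cigar = "10M5Q"),
               make_records("oob", pos = 99999))
  expect_warning(expect_warning(b <- classify_batch(rec, tiles10k),
                                "malformed CIGAR"), "outside the reference")
  expect_equal(b$spots_unique, 1L)
  expect_equal(b$spots_unmapped, 2L)
})

test_that("the first-batch quality filter blacklists below 5% unique, keeps at 5%", {
  fake <- function(downloaded, unique) {
    structure(list(run_id = "r", spots_downloaded = downloaded,
                   spots_unique = unique, spots_multi = 0L,
                   spots_unmapped = downloaded - unique, spots_spliced = 0L,
                   tile_counts = numeric(), introns = data.frame()),
              class = "batch_result")
  }
  expect_false(quality_filter(fake(50000L, 2000L)))  # 4% < 5%
  expect_true(quality_filter(fake(50000L, 2500L)))   # exactly 5% is kept
  expect_true(quality_filter(fake(100L, 100L)))      # fully unique
  expect_false(quality_filter(fake(0L, 0L)))         # nothing retrievable
})

test_that("SAM round trip preserves the fields the classifier uses", {
  skip_if_not_installed("Rsamtools")
  rec <- rbind(make_records("a", pos = 101, cigar = "40M60N40M"),
               make_records("b", pos = 7000, nh = 2, mapq = 0),
               make_records("c", flag = 4L, rname = NA, pos = NA,
                            cigar = NA, nh = NA, mapq = 0))
  path <- tempfile(fileext = ".sam")
  write_sam(rec, tiles10k, path)
  back <- read_alignments(path)
  expect_equal(nrow(back), 3L)
  mapped <- !is.na(back$rname)
  expect_equal(sort(back$pos[mapped]), c(101L, 7000L))
  expect_equal(back$nh[match(c("a", "b"), back$qname)], c(1L, 2L))
  b1 <- classify_batch(rec, tiles10k)
  b2 <- classify_batch(back, tiles10k)
  expect_equal(b1$tile_counts, b2$tile_counts)
  expect_equal(b1$introns, b2$introns)
})
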