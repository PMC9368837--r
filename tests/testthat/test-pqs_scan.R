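test_that("subtype classification follows the loop-length rule", {
  expect_identical(classify_pqs(3L, c(1, 1, 1)), "G3L1-7")
  expect_identical(classify_pqs(3L, c(1, 7, 7)), "G3L1-7")
  expect_identical(classify_pqs(3L, c(1, 1, 8)), "G3L8-12")
  expect_identical(classify_pqs(2L, c(12, 12, 12)), "G2L8-12")
  expect_identical(classify_pqs(2L, c(7, 3, 2)), "G2L1-7")
  expect_error(classify_pqs(3L, c(1, 1, 13)), "loop length")
  expect_error(classify_pqs(3L, c(0, 1, 2)), "loop length")
  expect_error(classify_pqs(4L, c(1, 1, 1)), "tract_len")
})

test_that("canonical G3 motif is found with its loops and strand", {
  rec <- scan_pqs(c(chr1 = "ATGGGTGGGTGGGTGGGAT"))
  expect_length(rec, 1L)
  expect_identical(rec$subtype, "G3L1-7")
  expect_identical(rec$loops, "1,1,1")
  expect_identical(as.character(GenomicRanges::strand(rec)), "+")
  expect_identical(rec$sequence, "GGGTGGGTGGGTGGG")

  # the C-pattern on the forward strand is the same PQS on the minus
  # strand at the same coordinates
  minus <- scan_pqs(c(chr1 = "ATCCCACCCACCCACCCAT"))
  expect_length(minus, 1L)
  expect_identical(as.character(GenomicRanges::strand(minus)), "-")
  expect_identical(GenomicRanges::start(minus), GenomicRanges::start(rec))
  expect_identical(minus$subtype, "G3L1-7")
  expect_identical(minus$sequence, "GGGTGGGTGGGTGGG")
})

test_that("G-run absorption, N rejection and G2/G3 exclusivity hold", {
  # surplus guanines absorb into the tract, not the loop
  rec <- scan_pqs(c(chr1 = "AGGGGGTGGGTGGGTGGGA"))
  expect_length(rec, 1L)
  expect_identical(rec$n_tracts, 4L)
  expect_identical(rec$loops, "1,1,1")

  # an N inside a prospective loop rejects the link silently
  rec <- scan_pqs(c(chr1 = "GGGAGGGAGGGAGGGNGGG"))
  expect_length(rec, 1L)
  expect_identical(GenomicRanges::end(rec), 15L)

  # a G3 match is not re-reported at the G2 level
  rec <- scan_pqs(c(chr1 = "ATGGGTGGGTGGGTGGGAT"))
  expect_length(rec, 1L)
  # but a pure two-tetrad pattern is
  rec2 <- scan_pqs(c(chr1 = "ATGGTGGTGGTGGAT"))
  expect_identical(rec2$subtype, "G2L1-7")

  expect_error(scan_pqs(c(chr1 = "ACGTX")), "non-IUPAC")
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(7)
  for (i in 1:40) {
    s <- random_seq(400)
    got <- as.data.frame(scan_pqs(c(chr = s)))
    exp <- oracle_scan(s)
    expect_identical(pqs_keys(got), pqs_keys(exp),
                     info = paste("sequence", i))
  }
})

test_that("scanning the reverse complement mirrors the record set", {
  set.seed(11)
  s <- random_seq(600)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  fwd <- as.data.frame(scan_pqs(c(chr = s)))
  rev <- as.data.frame(scan_pqs(c(chr = rc)))
  n <- nchar(s)
  mirrored <- data.frame(
    start = n - rev$end + 1L, end = n - rev$start + 1L,
    strand = ifelse(rev$strand == "+", "-", "+"),
    subtype = rev$subtype)
  expect_identical(pqs_keys(fwd), pqs_keys(mirrored))
})

test_that("every reported record re-matches its generating pattern", {
  set.seed(13)
  s <- random_seq(2000)
  rec <- scan_pqs(c(chr = s))
  for (i in seq_along(rec)) {
    tl <- rec$tract_len[i]
    pat <- sprintf("^G{%d,}([ACGT]{1,12}G{%d,}){3,}$", tl, tl)
    expect_true(grepl(pat, rec$sequence[i], perl = TRUE))
  }
})

test_that("pqs_content reports counts, peak percentages and densities", {
  # 10 peaks of 1 kb; PQSs overlap 4 of them
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(1, by = 2000,
                                                       length.out = 10),
                                                   width = 1000))
  pqs <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 2100, 4100, 6100), width = 20),
    strand = "+", subtype = rep("G3L1-7", 4))
  tab <- pqs_content(peaks, pqs)
  row <- tab[tab$subtype == "G3L1-7", ]
  expect_equal(row$count, 4L)
  expect_equal(row$percent_peaks, 40)
  expect_equal(row$density_per_kb, 4 / 10)
  # aggregate row pools both G3 classes
  expect_equal(tab$count[tab$subtype == "G3L1-12"], 4L)
  # all-zero when nothing overlaps
  far <- GenomicRanges::shift(peaks, 50000)
  expect_true(all(pqs_content(far, pqs)$count == 0))
  # empty peak set -> empty table
  expect_identical(nrow(pqs_content(GenomicRanges::GRanges(), pqs)), 0L)
})

test_that("meme windows are centered, fixed-width and clip-flagged", {
  genome <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))
  # 0-based peak [1000, 1300) -> center 1150 -> window [1050, 1250)
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1300))
  w <- export_meme_windows(peak, genome)
  expect_identical(unname(Biostrings::width(w)), 200L)
  expect_identical(names(w), "chr1:1050-1250|src=chr1:1000-1300")
  expect_identical(as.character(w[[1]]),
                   substr(genome[["chr1"]], 1051, 1250))
  # window past the chromosome start is clipped and flagged
  edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 30))
  we <- export_meme_windows(edge, genome)
  expect_true(grepl("clipped", names(we)))
  expect_lt(Biostrings::width(we)[1], 200L)
})
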