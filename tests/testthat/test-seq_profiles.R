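test_that("composition formulas hit their analytic limits", {
  genome <- c(chr1 = paste0(strrep("A", 1200), strrep("G", 500),
                            strrep("A", 1200)))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1201, 1700))
  gs <- composition_profile(region, genome, "gc_skew")
  gc <- composition_profile(region, genome, "gc_content")
  at <- composition_profile(region, genome, "at_skew")
  body <- 51:100
  expect_true(all(gs$values[body] == 1))
  expect_true(all(gc$values[body] == 1))
  # AT skew undefined (zero denominator) in the all-G body
  expect_true(all(is.na(at$values[body])))
  # flanks are all A: gc_skew undefined, at_skew = +1, gc_content = 0
  expect_true(all(is.na(gs$values[c(1:50, 101:150)])))
  expect_true(all(at$values[c(1:50, 101:150)] == 1))
  expect_true(all(gc$values[c(1:50, 101:150)] == 0))
})

test_that("reverse-complement mirroring flips skews bin-wise", {
  set.seed(17)
  s <- random_seq(6000)
  genome <- c(chr1 = s)
  rc <- c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2501, 3300))
  mirror <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(6000 - 3300 + 1, 6000 - 2501 + 1))
  for (st in c("gc_skew", "at_skew")) {
    a <- composition_profile(region, genome, st)$values
    b <- composition_profile(mirror, rc, st)$values
    expect_equal(a, -rev(b), tolerance = 1e-12)
  }
  a <- composition_profile(region, genome, "gc_content")$values
  b <- composition_profile(mirror, rc, "gc_content")$values
  expect_equal(a, rev(b), tolerance = 1e-12)
  # the reverse-strand profile of the same regions flips skews in place
  fwd <- composition_profile(region, genome, "gc_skew")$values
  rev_strand <- composition_profile(region, genome, "gc_skew",
                                    strand = "reverse")$values
  expect_equal(fwd, -rev_strand, tolerance = 1e-12)
})

test_that("every region yields the same 150-bin shape", {
  set.seed(23)
  genome <- c(chr1 = random_seq(50000))
  for (w in c(20, 49, 50, 137, 1000, 2500)) {
    region <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(10000,
                                                      width = w))
    pr <- composition_profile(region, genome, "gc_content")
    expect_length(pr$values, 150L)
    # short regions still populate body bins via midpoint assignment
    expect_true(all(pr$n_contrib[51:100] >= as.integer(w >= 50)))
  }
  expect_error(composition_profile(GenomicRanges::GRanges(), genome,
                                   "gc_content"), "empty")
})

test_that("profiles aggregate linearly over disjoint region sets", {
  set.seed(29)
  genome <- c(chr1 = random_seq(60000))
  r1 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(2000, 20000, by = 3000), width = 400))
  r2 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(30000, 50000, by = 4000), width = 400))
  p1 <- composition_profile(r1, genome, "gc_content")
  p2 <- composition_profile(r2, genome, "gc_content")
  p12 <- composition_profile(c(r1, r2), genome, "gc_content")
  pooled <- (p1$values * p1$n_contrib + p2$values * p2$n_contrib) /
    (p1$n_contrib + p2$n_contrib)
  expect_equal(p12$values, pooled, tolerance = 1e-12)
})

test_that("planted G-rich start boxes appear in the first body bins", {
  sim <- tiny_sim()
  genome <- as.character(sim$objects$genome)
  starts <- seq(5000, 150000, by = 5000)
  for (s in starts) {
    substr(genome[["chr1"]], s, s + 29) <- strrep("G", 30)
  }
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(starts,
                                                     width = 400))
  pr <- composition_profile(regions, genome, "gc_skew")
  # 30 bp box covers body bins 1-3 (8 bp body bins on 400 bp regions)
  expect_gt(mean(pr$values[51:53]), 0.8)
  # background just outside the region start is near zero within one
  # 20-bp flank bin
  expect_lt(abs(pr$values[49]), 0.25)
  expect_lt(mean(abs(pr$values[56:100])), 0.25)
})

test_that("region C content matches direct counting", {
  genome <- c(chr1 = "CCCCACGTACGTACGT")
  expect_equal(region_c_content(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4)), genome), 1)
  expect_equal(region_c_content(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 8)), genome),
    0.25)
  expect_equal(region_c_content(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 8)), genome,
    base = "G"), 0.25)
  set.seed(41)
  big <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 1000,
                               replace = TRUE), collapse = ""))
  cc <- region_c_content(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 1000)), big)
  expect_lt(abs(cc - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
})
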