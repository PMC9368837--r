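flat_track <- function(cs, value, bin = 50) {
  out <- lapply(names(cs), function(chrom) {
    starts <- seq(1, cs[[chrom]], by = bin)
    GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts,
                              pmin(starts + bin - 1, cs[[chrom]])),
      score = value)
  })
  suppressWarnings(do.call(c, out))
}

test_that("a constant track profiles to its value in every bin", {
  cs <- c(chr1 = 5e4)
  tr <- flat_track(cs, 2.75)
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(5000, 40000, by = 5000), width = 300))
  pr <- center_profile(tr, regions, cs)
  expect_length(pr$values, 100L)
  expect_true(all(abs(pr$values - 2.75) < 1e-12))
  expect_identical(dim(pr$matrix), c(length(regions), 100L))
})

test_that("a step track localizes the transition within one bin", {
  cs <- c(chr1 = 5e4)
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(24901, 25100))
  tr <- suppressWarnings(c(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 24900),
                           score = 0),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(24901, 25100),
                           score = 1),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(25101, 5e4),
                           score = 0)))
  pr <- center_profile(tr, peak, cs)
  v <- pr$values
  expect_true(all(v[47:54] == 1))   # inside the 200 bp peak
  expect_true(all(v[1:44] == 0))    # deep flank
  expect_true(all(v[57:100] == 0))
  # transition happens at +/-100 bp, i.e. between bins 45/46 and 55/56
  expect_true(all(v[c(45, 56)] %in% c(0, 1)) ||
                all(v[c(45, 56)] >= 0 & v[c(45, 56)] <= 1))
})

test_that("methylation profiles hit the degenerate limits", {
  cs <- c(chr1 = 2e4)
  pos <- seq(100, 19900, by = 37)
  full <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pos, pos), strand = "+",
    meth_count = 10L, total_count = 10L, context = "CG")
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(5000, 9000, 14000), width = 200))
  pr <- methylation_profile(full, regions, "CG", cs)
  expect_true(all(pr$values[!is.na(pr$values)] == 1))
  none <- full
  none$meth_count <- 0L
  pr0 <- methylation_profile(none, regions, "CG", cs)
  expect_true(all(pr0$values[!is.na(pr0$values)] == 0))
  # no cytosines of the requested context -> all-missing with warning
  expect_warning(methylation_profile(full, regions, "CHH", cs),
                 "no covered cytosines")
})

test_that("methylation pooling is additive over split records", {
  cs <- c(chr1 = 1e4)
  base <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(4951, 5050), width = 1), strand = "+",
    meth_count = c(6L, 2L), total_count = c(10L, 8L), context = "CG")
  split <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(4951, 4951, 5050), width = 1),
    strand = "+", meth_count = c(4L, 2L, 2L),
    total_count = c(7L, 3L, 8L), context = "CG")
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4901, 5100))
  p1 <- methylation_profile(base, region, "CG", cs)
  p2 <- methylation_profile(split, region, "CG", cs)
  expect_equal(p1$values, p2$values)
})

test_that("generator methylation levels are recovered at peak centers", {
  sim <- tiny_sim()
  meth <- read_cytosine_report(sim$paths$cytosine_report)
  peaks <- sim$objects$peak_sets$a_rep1
  pr <- methylation_profile(meth, peaks, "CG",
                            sim$objects$chrom_sizes)
  lv <- sim$manifest$methylation$levels$CG
  expect_lt(abs(mean(pr$values[49:52]) - lv[["peak"]]), 0.05)
})

test_that("matched random controls respect the C-content tolerance", {
  sim <- tiny_sim()
  genome <- sim$objects$genome
  obs <- sim$objects$peak_sets$a_rep1[1:40]
  ctrl <- suppressWarnings(
    matched_random_regions(obs, genome, c_tolerance = 0.02, seed = 12))
  expect_length(ctrl, 40L)
  expect_identical(GenomicRanges::width(ctrl),
                   GenomicRanges::width(obs))
  expect_false(any(IRanges::overlapsAny(ctrl, obs)))
  dC <- abs(region_c_content(ctrl, genome) -
              region_c_content(obs, genome))
  expect_lt(mean(dC), 0.03)
  expect_lt(abs(mean(region_c_content(ctrl, genome)) -
                  mean(region_c_content(obs, genome))), 0.02)
})

test_that("region fold is 1 for a uniform track", {
  cs <- c(chr1 = 3e4)
  tr <- flat_track(cs, 4)
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 9000, 20000), width = 500))
  rf <- region_fold(tr, regions)
  expect_equal(rf$score, rep(1, 3))
})

test_that("metagene profiles are strand-oriented TSS to TES", {
  cs <- c(chr1 = 4e4)
  # minus-strand gene: TSS at its right edge
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, 24000),
                              strand = "-")
  g$gene_id <- "g1"; g$is_TE_gene <- FALSE
  models <- gene_models(
    genes = g, exons = GenomicRanges::GRangesList(
      g1 = GenomicRanges::granges(g)))
  # signal only near the TSS (right end, 23800-24200)
  tr <- suppressWarnings(c(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 23799),
                           score = 0),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(23800, 24200),
                           score = 5),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(24201, 4e4),
                           score = 0)))
  classes <- data.frame(gene_id = "g1",
                        class = factor("high",
                                       levels = c("non", "low",
                                                  "medium", "high")))
  prof <- suppressWarnings(
    metagene_profile(tr, models, classes, cs))
  v <- prof$high$values
  # profile runs TSS (bin 51) -> TES (bin 100): signal sits at the
  # start of the body, not the end
  expect_gt(mean(v[51:53]), 4)
  expect_lt(mean(v[95:100]), 0.5)
  # and in the promoter-side flank just upstream of the TSS
  expect_gt(mean(v[46:50]), 4)
  expect_lt(mean(v[1:10]), 0.5)
})

test_that("a uniform track gives flat, equal class metagene profiles", {
  sim <- tiny_sim()
  cs <- sim$objects$chrom_sizes
  tr <- flat_track(cs, 3)
  expr <- sim$objects$expression
  classes <- classify_expression(expr)
  prof <- suppressWarnings(metagene_profile(
    tr, sim$objects$models, classes, cs))
  for (p in prof) {
    expect_true(all(abs(p$values[is.finite(p$values)] - 3) < 1e-9))
  }
})
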