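test_that("BED fields map onto the internal convention and back", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t350\tpk1\t50\t.", path)
  gr <- read_intervals(path, "BED6")
  expect_identical(GenomicRanges::start(gr), 101L)
  expect_identical(GenomicRanges::end(gr), 350L)
  expect_identical(gr$name, "pk1")
  out <- withr::local_tempfile(fileext = ".bed")
  write_intervals(gr, out, "BED6")
  expect_identical(readLines(out), readLines(path))
})

test_that("empty interval files give empty sets without error", {
  path <- withr::local_tempfile(fileext = ".bed")
  file.create(path)
  expect_length(read_intervals(path, "BED3"), 0L)
})

test_that("narrowPeak files round-trip byte-identically", {
  sim <- tiny_sim()
  lines1 <- readLines(sim$paths$a_rep1)
  gr <- read_intervals(sim$paths$a_rep1, "narrowPeak")
  expect_true(all(c("signalValue", "pValue", "qValue", "peak") %in%
                    names(S4Vectors::mcols(gr))))
  out <- withr::local_tempfile(fileext = ".narrowPeak")
  write_intervals(gr, out, "narrowPeak")
  expect_identical(readLines(out), lines1)
})

test_that("malformed interval files fail with the offending line", {
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t30"), bad)
  expect_error(read_intervals(bad, "BED3"), "line 2")
  writeLines(c("chr1\t10\t20", "chr1\t50\t40"), bad)
  expect_error(read_intervals(bad, "BED3"), "line 2.*start.*end")
  writeLines("chr9\t10\t20", bad)
  expect_error(read_intervals(bad, "BED3", chrom_sizes = c(chr1 = 100)),
               "unknown chromosome")
})

test_that("bedGraph reader enforces the run invariants", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t100\t2.5", path)
  tr <- read_bedgraph(path)
  expect_identical(GenomicRanges::start(tr), 1L)
  expect_identical(GenomicRanges::end(tr), 100L)
  expect_identical(tr$score, 2.5)
  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t2"), path)
  expect_error(read_bedgraph(path), "overlapping")
})

test_that("FASTA io rejects duplicate headers and round-trips", {
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(chr1 = "ACGTACGT", chr2 = "GGTTAACC"), path)
  seqs <- read_fasta(path)
  expect_identical(as.character(seqs[["chr2"]]), "GGTTAACC")
  writeLines(c(">a", "ACGT", ">a", "GGGT"), path)
  expect_error(read_fasta(path), "duplicate")
})

test_that("cytosine report records carry C/(C+T) levels and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t10\t+\t3\t7\tCG", "chr1\t25\t-\t0\t4\tCHH"), path)
  meth <- read_cytosine_report(path)
  expect_identical(meth$total_count, c(10L, 4L))
  expect_equal(meth$meth_count[1] / meth$total_count[1], 0.3)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(meth, out)
  expect_identical(readLines(out), readLines(path))
  writeLines("chr1\t10\t+\t3\t7\tXX", path)
  expect_error(read_cytosine_report(path), "context.*line 1")
})

test_that("GFF3 gene models keep 1-based coordinates and longest mRNA", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t1001\t2400\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t1001\t1900\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\t.\texon\t1001\t1900\t.\t+\t.\tParent=g1.1",
    "chr1\t.\tmRNA\t1001\t2200\t.\t+\t.\tID=g1.2;Parent=g1",
    "chr1\t.\texon\t1001\t1500\t.\t+\t.\tParent=g1.2",
    "chr1\t.\texon\t1801\t2200\t.\t+\t.\tParent=g1.2"
  ), path)
  models <- read_gff3_genes(path)
  # the 1200 bp mRNA wins over the 900 bp one
  expect_identical(GenomicRanges::start(models$genes), 1001L)
  expect_identical(GenomicRanges::end(models$genes), 2200L)
  expect_length(models$exons[["g1"]], 2L)
})

test_that("generator GFF3 round-trips through the reader", {
  sim <- tiny_sim()
  models <- read_gff3_genes(sim$paths$gff3)
  truth <- sim$objects$models
  expect_identical(length(models$genes), length(truth$genes))
  ord <- match(truth$genes$gene_id, models$genes$gene_id)
  expect_false(anyNA(ord))
  expect_identical(GenomicRanges::start(models$genes)[ord],
                   GenomicRanges::start(truth$genes))
  expect_identical(GenomicRanges::end(models$genes)[ord],
                   GenomicRanges::end(truth$genes))
  expect_identical(models$genes$is_TE_gene[ord],
                   truth$genes$is_TE_gene)
  expect_identical(unname(lengths(models$exons)[ord]),
                   unname(lengths(truth$exons)))
})

test_that("BED 0-based to internal and back recovers the original pair", {
  set.seed(3)
  for (i in 1:20) {
    s0 <- sample.int(1e5, 1)
    e0 <- s0 + sample.int(1e3, 1)
    path <- withr::local_tempfile(fileext = ".bed")
    writeLines(sprintf("chr1\t%d\t%d", s0, e0), path)
    gr <- read_intervals(path, "BED3")
    out <- withr::local_tempfile(fileext = ".bed")
    write_intervals(gr, out, "BED3")
    expect_identical(readLines(out), sprintf("chr1\t%d\t%d", s0, e0))
  }
})
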