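single_gene_models <- function(start = 5001, end = 8000,
                               strand = "+", chrom_len = 20000) {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                              strand = strand)
  g$gene_id <- "g1"
  g$is_TE_gene <- FALSE
  gene_models(
    genes = g,
    exons = GenomicRanges::GRangesList(g1 = GenomicRanges::granges(g)))
}

test_that("a single plus-strand gene partitions a chromosome exactly", {
  cs <- c(chr1 = 20000)
  part <- build_partition(single_gene_models(), cs)
  cats <- part$categories
  expect_identical(GenomicRanges::start(cats$promoter), 4001L)
  expect_identical(GenomicRanges::end(cats$promoter), 5000L)
  expect_identical(GenomicRanges::start(cats$downstream), 8001L)
  expect_identical(GenomicRanges::end(cats$downstream), 9000L)
  bp <- vapply(cats, function(g) sum(GenomicRanges::width(g)),
               numeric(1))
  expect_equal(sum(bp), 20000)
  expect_equal(unname(bp[["exon"]]), 3000)
  expect_equal(unname(bp[["intergenic"]]), 20000 - 3000 - 2000)
})

test_that("an empty gene set makes everything intergenic", {
  g <- GenomicRanges::GRanges()
  g$gene_id <- character(0); g$is_TE_gene <- logical(0)
  models <- gene_models(genes = g,
                        exons = GenomicRanges::GRangesList())
  part <- build_partition(models, c(chr1 = 5000, chr2 = 3000))
  expect_equal(sum(GenomicRanges::width(part$categories$intergenic)),
               8000)
  expect_true(all(vapply(part$categories[1:6], length, integer(1)) ==
                    0L))
})

test_that("category priority resolves promoter/downstream collisions", {
  # g2 downstream territory overlaps g1 promoter: promoter wins
  g <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(c(5001, 1001),
                                               c(8000, 3600)),
                              strand = "+")
  g$gene_id <- c("g1", "g2")
  g$is_TE_gene <- c(FALSE, FALSE)
  models <- gene_models(
    genes = g,
    exons = GenomicRanges::GRangesList(
      g1 = GenomicRanges::granges(g[1]),
      g2 = GenomicRanges::granges(g[2])))
  part <- build_partition(models, c(chr1 = 20000))
  ds <- part$categories$downstream
  # g2 downstream is [3601, 4600] raw but [4001, 4600] belongs to the
  # g1 promoter
  expect_identical(GenomicRanges::end(ds[GenomicRanges::start(ds) ==
                                           3601]), 4000L)
  pr <- part$categories$promoter
  expect_true(any(GenomicRanges::start(pr) == 4001 &
                    GenomicRanges::end(pr) == 5000))
  bp <- vapply(part$categories,
               function(x) sum(GenomicRanges::width(x)), numeric(1))
  expect_equal(sum(bp), 20000)
})

test_that("partition tiles the genome for random gene layouts", {
  for (seed in 1:4) {
    cfg <- sim_config(n_chroms = 2, chrom_len = 1e5, n_genes = 15,
                      peaks = list(n_per_condition = 20),
                      pqs = list(n_per_subtype = 2),
                      components = character(0))
    sim <- generate_dataset(cfg, seed = seed, write_files = FALSE)
    part <- sim$objects$partition
    bp <- vapply(part$categories,
                 function(x) sum(GenomicRanges::width(x)), numeric(1))
    expect_equal(sum(bp), 2e5)
    # pairwise disjoint
    all_cats <- unlist(GenomicRanges::GRangesList(part$categories))
    expect_identical(
      sum(GenomicRanges::width(GenomicRanges::reduce(all_cats))),
      as.integer(sum(bp)))
  }
})

test_that("peaks are assigned by midpoint category, order-invariantly", {
  cs <- c(chr1 = 20000)
  part <- build_partition(single_gene_models(), cs)
  # midpoint 5000 (0-based) = promoter's last base vs first exon base
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4901, 5100))
  res <- assign_peaks(pk, part)
  expect_identical(as.character(res$per_peak), "exon")
  # an all-intergenic set is 100% intergenic
  pk2 <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(15001, 17001),
                                                 width = 200))
  res2 <- assign_peaks(pk2, part)
  expect_equal(res2$table$percent[res2$table$category == "intergenic"],
               100)
  # permutation invariance and percentages summing to 100
  set.seed(2)
  pk3 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(sample.int(19000, 50), width = 100))
  r1 <- assign_peaks(pk3, part)
  r2 <- assign_peaks(rev(pk3), part)
  expect_identical(sort(table(r1$per_peak)), sort(table(r2$per_peak)))
  expect_equal(sum(r1$table$percent), 100, tolerance = 1e-9)
})

test_that("gene associations follow the 1 bp overlap rule", {
  cs <- c(chr1 = 20000)
  models <- single_gene_models()
  # a peak spanning the TSS associates in both regions
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4951, 5050))
  names(pk) <- "pk1"
  prom <- overlap_genes(pk, models, "promoter", chrom_sizes = cs)
  body <- overlap_genes(pk, models, "gene_body", chrom_sizes = cs)
  expect_identical(prom$gene_id, "g1")
  expect_identical(body$gene_id, "g1")
  # intergenic desert peak associates with nothing
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(15001, 15100))
  expect_identical(nrow(overlap_genes(far, models, "promoter",
                                      chrom_sizes = cs)), 0L)
})

test_that("promoter-linked peaks recover exactly the manifest genes", {
  cfg <- sim_config(n_chroms = 2, chrom_len = 3e5, n_genes = 50,
                    pqs = list(n_per_subtype = 2),
                    peaks = list(n_per_condition = 125,
                                 replicate_overlap = 0.8,
                                 cross_condition_overlap = 0.5,
                                 promoter_link_fraction = 50 / 50 * 0.5),
                    components = character(0))
  # 125 peaks -> 100 reproducible -> 50 common + 50 a-specific; the 25
  # promoter-linked genes occupy 25 of the a-specific slots
  cfg$peaks$promoter_link_fraction <- 25 / 50
  sim <- generate_dataset(cfg, seed = 9, write_files = FALSE)
  linked <- sim$manifest$promoter_linked_genes
  expect_length(linked, 25L)
  a_spec <- sim$objects$anchors[sim$objects$anchors$role ==
                                  "a_specific"]
  linked_peaks <- a_spec[!is.na(a_spec$linked_gene)]
  assoc <- overlap_genes(linked_peaks, sim$objects$models, "promoter",
                         chrom_sizes = sim$objects$chrom_sizes)
  expect_setequal(assoc$gene_id, linked)
})
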