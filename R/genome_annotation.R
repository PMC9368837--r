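.partition_categories <- c("promoter", "utr5", "utr3", "exon", "intron",
                           "downstream", "intergenic")

# Strand-adjusted promoter windows [TSS - len, TSS) clipped to bounds.
.promoter_regions <- function(genes, promoter_len, chrom_sizes) {
  pr <- GenomicRanges::promoters(genes, upstream = promoter_len,
                                 downstream = 0)
  len <- chrom_sizes[as.character(GenomicRanges::seqnames(pr))]
  GenomicRanges::start(pr) <- pmax(GenomicRanges::start(pr), 1)
  GenomicRanges::end(pr) <- pmin(GenomicRanges::end(pr), len)
  pr[GenomicRanges::width(pr) > 0]
}

# Strand-adjusted downstream windows [TES, TES + len) clipped to bounds.
.downstream_regions <- function(genes, downstream_len, chrom_sizes) {
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  start <- ifelse(minus,
                  GenomicRanges::start(genes) - downstream_len,
                  GenomicRanges::end(genes) + 1)
  end <- ifelse(minus,
                GenomicRanges::start(genes) - 1,
                GenomicRanges::end(genes) + downstream_len)
  ds <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                               IRanges::IRanges(pmax(start, 1),
                                                pmin(end, chrom_sizes[
                                                  as.character(
                                                    GenomicRanges::seqnames(
                                                      genes))])))
  ds[GenomicRanges::width(ds) > 0]
}

#' Partition the genome into seven functional categories
#'
#' Builds the disjoint subgenomic partition (promoter, 5'UTR, 3'UTR,
#' exon, intron, downstream of the TES, intergenic) that tiles every
#' chromosome exactly. Promoters are the strand-adjusted
#' \code{promoter_len} bp upstream of the TSS, downstream regions the
#' \code{downstream_len} bp past the TES; introns are the gene body
#' minus exons. Where raw territories overlap, assignment follows the
#' fixed priority promoter > 5'UTR > 3'UTR > exon > intron >
#' downstream; everything unassigned is intergenic.
#'
#' @param models A \code{gene_models} object (empty gene set allowed:
#'   everything becomes intergenic).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param promoter_len,downstream_len Window widths in bp.
#' @return A list of class \code{genome_partition} with a \code{GRanges}
#'   per category plus the parameters.
#' @export
build_partition <- function(models, chrom_sizes, promoter_len = 1000L,
                            downstream_len = 1000L) {
  stopifnot(promoter_len > 0, downstream_len > 0)
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  genome <- GenomicRanges::GRanges(
    names(chrom_sizes), IRanges::IRanges(1, unname(chrom_sizes)))
  genes <- models$genes
  if (length(genes) > 0) {
    check_on_genome(genes, chrom_sizes, what = "gene")
  }
  strip <- function(gr) {
    gr <- GenomicRanges::granges(gr)
    GenomicRanges::strand(gr) <- "*"
    gr
  }
  if (length(genes) == 0L) {
    raw <- rep(list(GenomicRanges::GRanges()), 6)
    names(raw) <- .partition_categories[1:6]
  } else {
    exons <- strip(unlist(models$exons))
    body <- strip(genes)
    raw <- list(
      promoter = strip(.promoter_regions(genes, promoter_len,
                                         chrom_sizes)),
      utr5 = strip(unlist(models$utr5)),
      utr3 = strip(unlist(models$utr3)),
      exon = exons,
      intron = GenomicRanges::setdiff(body, exons),
      downstream = strip(.downstream_regions(genes, downstream_len,
                                             chrom_sizes))
    )
  }
  assigned <- GenomicRanges::GRanges()
  out <- list()
  for (cat in names(raw)) {
    terr <- GenomicRanges::reduce(raw[[cat]])
    out[[cat]] <- GenomicRanges::setdiff(terr, assigned)
    assigned <- GenomicRanges::reduce(c(assigned, out[[cat]]))
  }
  out$intergenic <- GenomicRanges::setdiff(genome, assigned)
  structure(
    list(categories = out, chrom_sizes = chrom_sizes,
         promoter_len = promoter_len, downstream_len = downstream_len),
    class = "genome_partition"
  )
}

#' @export
print.genome_partition <- function(x, ...) {
  bp <- vapply(x$categories, function(g) sum(GenomicRanges::width(g)),
               numeric(1))
  cat("genome_partition (", sum(x$chrom_sizes), " bp):\n", sep = "")
  for (cat in names(bp)) {
    cat(sprintf("  %-11s %12s bp (%.2f%%)\n", cat,
                format(bp[[cat]], big.mark = ","),
                100 * bp[[cat]] / sum(x$chrom_sizes)))
  }
  invisible(x)
}

#' Per-category base-pair shares of a partition
#'
#' @param partition A \code{genome_partition}.
#' @return Named numeric vector of fractions summing to 1.
#' @export
partition_shares <- function(partition) {
  bp <- vapply(partition$categories,
               function(g) sum(GenomicRanges::width(g)), numeric(1))
  bp / sum(partition$chrom_sizes)
}

#' Assign peaks to subgenomic categories
#'
#' Each peak is assigned to exactly one category: the category of its
#' midpoint base (floor((start + end) / 2) in 0-based coordinates).
#' Percentages therefore sum to 100.
#'
#' @param peaks A \code{GRanges}.
#' @param partition A \code{genome_partition}.
#' @return A list with \code{per_peak} (factor of categories, one per
#'   peak) and \code{table} (data.frame category/count/percent in fixed
#'   category order).
#' @export
assign_peaks <- function(peaks, partition) {
  check_on_genome(peaks, partition$chrom_sizes, what = "peak")
  mids <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(interval_midpoint(peaks), width = 1))
  per_peak <- factor(rep(NA_character_, length(peaks)),
                     levels = .partition_categories)
  for (cat in .partition_categories) {
    hit <- IRanges::overlapsAny(mids, partition$categories[[cat]],
                                ignore.strand = TRUE)
    per_peak[is.na(per_peak) & hit] <- cat
  }
  stopifnot(!anyNA(per_peak))  # guaranteed by the tiling invariant
  counts <- as.integer(table(per_peak))
  list(per_peak = per_peak,
       table = data.frame(category = .partition_categories,
                          count = counts,
                          percent = if (length(peaks)) {
                            100 * counts / length(peaks)
                          } else {
                            rep(0, length(counts))
                          }))
}

#' Associate peaks with genes at promoters or gene bodies
#'
#' A gene is associated with every peak overlapping (>= 1 bp) the
#' requested region: its promoter (strand-adjusted
#' \code{promoter_len} bp upstream of the TSS) or its gene body (the
#' transcript span). Each gene is reported once per region with the set
#' of overlapping peaks; a peak spanning a TSS associates the gene in
#' both regions.
#'
#' @param peaks A \code{GRanges}; unnamed peaks are labelled
#'   \code{peak_<i>} by input order.
#' @param models A \code{gene_models} object.
#' @param region "promoter" or "gene_body".
#' @param promoter_len Promoter width in bp.
#' @param chrom_sizes Optional named vector; defaults to unbounded
#'   clipping at position 1 only.
#' @return A data.frame with gene_id, region, is_TE_gene, n_peaks and
#'   peak_ids (comma-separated), one row per associated gene.
#' @export
overlap_genes <- function(peaks, models, region = c("promoter",
                                                    "gene_body"),
                          promoter_len = 1000L, chrom_sizes = NULL) {
  region <- match.arg(region)
  genes <- models$genes
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(
      c(GenomicRanges::end(genes), GenomicRanges::end(peaks)),
      c(as.character(GenomicRanges::seqnames(genes)),
        as.character(GenomicRanges::seqnames(peaks))), max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes) + promoter_len,
                                   names(chrom_sizes))
  }
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  if (region == "promoter") {
    pr <- GenomicRanges::promoters(genes, upstream = promoter_len,
                                   downstream = 0)
    len <- chrom_sizes[as.character(GenomicRanges::seqnames(pr))]
    cl_s <- pmax(GenomicRanges::start(pr), 1)
    cl_e <- pmin(GenomicRanges::end(pr), len)
    keep <- cl_e >= cl_s  # promoters clipped away entirely drop the gene
    target <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(pr)[keep],
      IRanges::IRanges(cl_s[keep], cl_e[keep]))
    gene_idx <- which(keep)
  } else {
    target <- genes
    gene_idx <- seq_along(genes)
  }
  peak_ids <- if (!is.null(names(peaks)) && all(nzchar(names(peaks)))) {
    names(peaks)
  } else if ("name" %in% names(S4Vectors::mcols(peaks))) {
    as.character(peaks$name)
  } else {
    sprintf("peak_%d", seq_along(peaks))
  }
  hits <- GenomicRanges::findOverlaps(target, peaks, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(data.frame(gene_id = character(0), region = character(0),
                      is_TE_gene = logical(0), n_peaks = integer(0),
                      peak_ids = character(0)))
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  per_gene <- split(peak_ids[sh], qh)
  gi <- gene_idx[as.integer(names(per_gene))]
  data.frame(
    gene_id = genes$gene_id[gi],
    region = region,
    is_TE_gene = genes$is_TE_gene[gi],
    n_peaks = lengths(per_gene),
    peak_ids = vapply(per_gene, paste, character(1), collapse = ","),
    row.names = NULL
  )
}
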