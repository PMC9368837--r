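# base codes used by the composition binner
.base_code <- local({
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v[utf8ToInt("a")] <- 1L; v[utf8ToInt("c")] <- 2L
  v[utf8ToInt("g")] <- 3L; v[utf8ToInt("t")] <- 4L
  v
})

# Per-region base counts in the scaled-region bin scheme: flank bins of
# fixed width tiled outward from the region edges, body split into
# body_bins equal sub-intervals with bases assigned to the bin holding
# their midpoint. Returns a 4 x nbins count matrix (A, C, G, T rows).
.region_bin_counts <- function(chrom_seq, start, end, body_bins,
                               flank_bp, flank_bin_bp) {
  L <- nchar(chrom_seq)
  nf <- flank_bp %/% flank_bin_bp
  nb <- 2L * nf + body_bins
  len <- end - start + 1
  ws <- max(1, start - flank_bp)
  we <- min(L, end + flank_bp)
  pos <- ws:we
  code <- .base_code[utf8ToInt(substr(chrom_seq, ws, we))]
  binid <- integer(length(pos))
  left <- pos < start
  right <- pos > end
  body <- !left & !right
  binid[left] <- (pos[left] - (start - flank_bp)) %/% flank_bin_bp + 1L
  binid[body] <- nf + 1L +
    floor((pos[body] - start + 0.5) * body_bins / len)
  binid[right] <- nf + body_bins +
    (pos[right] - end - 1L) %/% flank_bin_bp + 1L
  ok <- !is.na(code)
  counts <- tabulate((binid[ok] - 1L) * 4L + code[ok], nbins = nb * 4L)
  matrix(counts, nrow = 4L, dimnames = list(c("A", "C", "G", "T"), NULL))
}

.composition_stat <- function(counts, statistic) {
  a <- counts["A", ]; c <- counts["C", ]
  g <- counts["G", ]; t <- counts["T", ]
  switch(statistic,
    gc_content = {
      tot <- a + c + g + t
      ifelse(tot == 0, NA_real_, (g + c) / tot)
    },
    gc_skew = ifelse(g + c == 0, NA_real_, (g - c) / (g + c)),
    at_skew = ifelse(a + t == 0, NA_real_, (a - t) / (a + t)),
    stop("unknown statistic: ", statistic)
  )
}

#' Scaled-region sequence-composition profile
#'
#' Computes GC content, GC skew or AT skew in a fixed bin scheme over a
#' set of regions: each region body is split into \code{body_bins}
#' equal sub-intervals (bases assigned by midpoint, so short regions
#' still fill all bins) and each flank is tiled outward in
#' \code{flank_bin_bp} windows. Per-bin statistics use forward-strand
#' base counts (GC skew = (G - C)/(G + C), AT skew = (A - T)/(A + T),
#' GC content = (G + C)/(A + C + G + T)); the reverse-strand profile
#' complements the counts, which flips the skew signs and leaves GC
#' content unchanged. Bins with a zero denominator contribute a missing
#' value excluded from the cross-region mean.
#'
#' @param intervals A non-empty \code{GRanges}.
#' @param genome Named \code{DNAStringSet} or character vector.
#' @param statistic "gc_content", "gc_skew" or "at_skew".
#' @param body_bins,flank_bp,flank_bin_bp The bin scheme (defaults: 50
#'   body bins, 1 kb flanks in 20 bp windows, i.e. 150 bins).
#' @param strand "forward" or "reverse".
#' @return A \code{binned_profile}.
#' @export
composition_profile <- function(intervals, genome,
                                statistic = c("gc_content", "gc_skew",
                                              "at_skew"),
                                body_bins = 50L, flank_bp = 1000L,
                                flank_bin_bp = 20L,
                                strand = c("forward", "reverse")) {
  statistic <- match.arg(statistic)
  strand <- match.arg(strand)
  if (length(intervals) == 0L) stop("empty interval set")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  check_on_genome(intervals, lens, what = "region")
  seqs <- lapply(as.list(as.character(genome)), identity)
  nb <- 2L * (flank_bp %/% flank_bin_bp) + body_bins
  sums <- numeric(nb)
  nn <- integer(nb)
  chroms <- as.character(GenomicRanges::seqnames(intervals))
  starts <- GenomicRanges::start(intervals)
  ends <- GenomicRanges::end(intervals)
  for (i in seq_along(intervals)) {
    counts <- .region_bin_counts(seqs[[chroms[i]]], starts[i], ends[i],
                                 body_bins, flank_bp, flank_bin_bp)
    if (strand == "reverse") {
      counts <- counts[c("T", "G", "C", "A"), , drop = FALSE]
      rownames(counts) <- c("A", "C", "G", "T")
    }
    vals <- .composition_stat(counts, statistic)
    ok <- !is.na(vals)
    sums[ok] <- sums[ok] + vals[ok]
    nn <- nn + ok
  }
  new_binned_profile(
    values = ifelse(nn > 0, sums / pmax(nn, 1L), NA_real_),
    n_contrib = nn,
    statistic = paste0(statistic, if (strand == "reverse") " (reverse)"),
    scheme = list(body_bins = body_bins, flank_bp = flank_bp,
                  flank_bin_bp = flank_bin_bp),
    n_regions = length(intervals)
  )
}

#' Cytosine (or other base) content of regions
#'
#' Forward-strand base fraction per region, used to build
#' C-content-matched random controls.
#'
#' @param intervals A \code{GRanges} of non-zero width.
#' @param genome Named \code{DNAStringSet} or character vector.
#' @param base Single base to count (default "C"; use "G" for the
#'   complementary, strand-agnostic companion count).
#' @return Numeric vector of fractions, one per interval.
#' @export
region_c_content <- function(intervals, genome, base = "C") {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (any(GenomicRanges::width(intervals) == 0L)) {
    stop("zero-length interval")
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  check_on_genome(intervals, lens, what = "region")
  chroms <- as.character(GenomicRanges::seqnames(intervals))
  out <- numeric(length(intervals))
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    sub <- Biostrings::extractAt(
      genome[[chrom]],
      IRanges::IRanges(GenomicRanges::start(intervals)[idx],
                       GenomicRanges::end(intervals)[idx]))
    out[idx] <- Biostrings::letterFrequency(sub, base)[, 1] /
      GenomicRanges::width(intervals)[idx]
  }
  out
}
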