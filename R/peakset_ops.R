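#' Biologically reproducible peaks between two replicates
#'
#' Returns the replicate-1 peaks that overlap (>= 1 bp, bedtools
#' intersect semantics) any replicate-2 peak, together with the overlap
#' ratio |reproducible| / |rep1|. Replicate-1 coordinates are retained.
#'
#' @param rep1,rep2 \code{GRanges} peak sets on the same genome.
#' @return A list with \code{peaks} (\code{GRanges}) and
#'   \code{overlap_ratio} (numeric).
#' @export
reproducible_peaks <- function(rep1, rep2) {
  if (length(rep1) == 0L) {
    stop("rep1 is empty: overlap ratio is undefined")
  }
  keep <- IRanges::overlapsAny(rep1, rep2, ignore.strand = TRUE)
  list(peaks = rep1[keep], overlap_ratio = mean(keep))
}

#' Classify two condition peak sets into common and condition-specific
#'
#' Every peak of one condition overlapping (>= 1 bp) any peak of the
#' other contributes to the "common" class; common intervals are the
#' merged union of each cross-condition overlapping cluster, so a
#' single common interval may absorb several peaks from either side.
#' Peaks with no cross-condition overlap keep their original
#' coordinates as condition-specific.
#'
#' @param set_a,set_b Reproducible peak sets of the two conditions.
#' @param labels Length-2 character vector naming the conditions.
#' @return A list of class \code{peak_classification} with elements
#'   \code{common}, \code{a_specific}, \code{b_specific} (all
#'   \code{GRanges}) and \code{labels}.
#' @export
classify_conditions <- function(set_a, set_b, labels = c("A", "B")) {
  stopifnot(length(labels) == 2L)
  a_hit <- IRanges::overlapsAny(set_a, set_b, ignore.strand = TRUE)
  b_hit <- IRanges::overlapsAny(set_b, set_a, ignore.strand = TRUE)
  common <- GenomicRanges::reduce(
    c(GenomicRanges::granges(set_a[a_hit]),
      GenomicRanges::granges(set_b[b_hit])),
    ignore.strand = TRUE
  )
  structure(
    list(common = common,
         a_specific = set_a[!a_hit],
         b_specific = set_b[!b_hit],
         labels = labels,
         n_a_absorbed = sum(a_hit),
         n_b_absorbed = sum(b_hit)),
    class = "peak_classification"
  )
}

#' @export
print.peak_classification <- function(x, ...) {
  cat(sprintf(
    "peak_classification: %d common, %d %s-specific, %d %s-specific\n",
    length(x$common), length(x$a_specific), x$labels[1],
    length(x$b_specific), x$labels[2]))
  invisible(x)
}

#' Length statistics of a peak set
#'
#' @param gr A non-empty \code{GRanges}.
#' @param bin_width Histogram bin width in bp.
#' @return A list with \code{mean}, \code{median}, \code{n} and
#'   \code{histogram} (data.frame of bin_start, bin_end, count).
#' @export
length_stats <- function(gr, bin_width = 50L) {
  if (length(gr) == 0L) stop("empty interval set")
  len <- GenomicRanges::width(gr)
  breaks <- seq(0, (max(len) %/% bin_width + 1) * bin_width,
                by = bin_width)
  counts <- as.integer(table(cut(len, breaks, right = FALSE)))
  list(mean = mean(len), median = stats::median(len), n = length(len),
       histogram = data.frame(bin_start = breaks[-length(breaks)],
                              bin_end = breaks[-1], count = counts))
}
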