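#' Randomly re-place intervals on the genome (shuffle null)
#'
#' Re-places every interval uniformly at random on the genome
#' (chromosome chosen with probability proportional to its length,
#' start uniform among positions where the interval fits), preserving
#' the multiset of interval lengths, in the manner of
#' \code{bedtools shuffle -noOverlapping}. With
#' \code{no_overlap = TRUE}, placed intervals are mutually
#' non-overlapping (batched rejection sampling with a bounded retry
#' count). Intervals overlapping \code{exclude} are never emitted.
#'
#' @param gr A \code{GRanges} (only lengths are used).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @param no_overlap Forbid overlaps among placed intervals.
#' @param exclude Optional \code{GRanges} of forbidden territory.
#' @param max_rounds Maximum resampling rounds before erroring.
#' @return A \code{GRanges} of re-placed, unstranded intervals, in a
#'   deterministic order given the seed.
#' @export
shuffle_intervals <- function(gr, chrom_sizes, seed = NULL,
                              no_overlap = TRUE, exclude = NULL,
                              max_rounds = 200L) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  n <- length(gr)
  if (n == 0L) return(GenomicRanges::GRanges())
  lens <- GenomicRanges::width(gr)
  if (no_overlap && sum(lens) >= sum(chrom_sizes)) {
    stop("total interval length exceeds genome length")
  }
  # all arithmetic on a pooled number line (chromosomes laid end to
  # end with 1 bp spacers), so the rejection rounds stay vectorized
  offsets <- c(0, cumsum(unname(chrom_sizes) + 1))[seq_along(chrom_sizes)]
  names(offsets) <- names(chrom_sizes)
  excl <- if (!is.null(exclude) && length(exclude)) {
    red <- GenomicRanges::reduce(GenomicRanges::granges(exclude),
                                 ignore.strand = TRUE)
    check_on_genome(red, chrom_sizes, within = FALSE, what = "exclude")
    o <- offsets[as.character(GenomicRanges::seqnames(red))]
    L <- chrom_sizes[as.character(GenomicRanges::seqnames(red))]
    cbind(start = pmax(GenomicRanges::start(red), 1) + o,
          end = pmin(GenomicRanges::end(red), L) + o)
  }
  with_seed(seed, {
    placed <- rep(FALSE, n)
    out_pos <- numeric(n)
    acc_s <- numeric(0)
    acc_e <- numeric(0)
    hits_sorted <- function(s, e, ref_s, ref_e) {
      if (length(ref_s) == 0L) return(rep(FALSE, length(s)))
      i <- findInterval(e, ref_s)
      i >= 1L & ref_e[pmax(i, 1L)] >= s
    }
    for (round in seq_len(max_rounds)) {
      todo <- which(!placed)
      if (length(todo) == 0L) break
      ci <- sample.int(length(chrom_sizes), length(todo),
                       replace = TRUE, prob = chrom_sizes)
      fit <- unname(chrom_sizes)[ci] - lens[todo] + 1
      ok <- fit >= 1
      start <- floor(stats::runif(length(todo)) * pmax(fit, 1)) + 1
      pos <- unname(offsets)[ci] + start
      pend <- pos + lens[todo] - 1
      keep <- ok
      if (!is.null(excl)) {
        ord <- order(excl[, "start"])
        keep <- keep & !hits_sorted(pos, pend, excl[ord, "start"],
                                    excl[ord, "end"])
      }
      if (no_overlap) {
        keep <- keep & !hits_sorted(pos, pend, acc_s, acc_e)
        # in-batch conflicts: sweep left to right, keep greedily
        sel <- which(keep)
        if (length(sel) > 1L) {
          o <- sel[order(pos[sel])]
          last_end <- -Inf
          for (j in o) {
            if (pos[j] > last_end) last_end <- pend[j] else
              keep[j] <- FALSE
          }
        }
      }
      idx <- todo[keep]
      placed[idx] <- TRUE
      out_pos[idx] <- pos[keep]
      if (no_overlap && length(idx)) {
        acc_s <- c(acc_s, pos[keep])
        acc_e <- c(acc_e, pend[keep])
        o <- order(acc_s)
        acc_s <- acc_s[o]; acc_e <- acc_e[o]
      }
    }
    if (!all(placed)) {
      stop("could not place all intervals without overlap after ",
           max_rounds, " rounds")
    }
    ci <- findInterval(out_pos, unname(offsets))
    GenomicRanges::GRanges(
      names(chrom_sizes)[ci],
      IRanges::IRanges(out_pos - unname(offsets)[ci], width = lens))
  })
}

# Shared core: observed statistic vs the mean over n randomizations.
.fold_results <- function(strata, observed, random_mat, n) {
  random_mean <- rowMeans(random_mat)
  random_sd <- apply(random_mat, 1, stats::sd)
  fold <- ifelse(random_mean == 0,
                 ifelse(observed == 0, NaN, Inf),
                 observed / random_mean)
  data.frame(
    stratum = strata,
    observed = observed,
    random_mean = random_mean,
    random_sd = random_sd,
    fold = fold,
    degenerate = random_mean == 0,
    n_randomizations = n,
    random_values = I(lapply(seq_along(strata),
                             function(i) unname(random_mat[i, ])))
  )
}

#' Observed/expected subgenomic fold enrichment of a peak set
#'
#' The observed statistic is the per-category percentage from
#' \code{\link{assign_peaks}}; the expectation is the mean of the same
#' statistic over \code{n} independent genome-wide shuffles of the
#' peaks. Fold = observed / mean(random); a category never hit by the
#' randomizations reports Inf (degenerate flag) unless the observed
#' count is also zero.
#'
#' @param peaks A \code{GRanges}.
#' @param partition A \code{genome_partition}.
#' @param n Number of randomizations.
#' @param seed Optional master seed; per-randomization streams are
#'   derived deterministically from it.
#' @param no_overlap Passed to \code{\link{shuffle_intervals}}.
#' @return A data.frame of per-category enrichment results with the
#'   randomization values retained in a list column.
#' @export
subgenomic_fold <- function(peaks, partition, n = 3L, seed = NULL,
                            no_overlap = TRUE) {
  if (n < 1L) stop("n must be >= 1")
  observed <- assign_peaks(peaks, partition)$table
  random_mat <- matrix(0, nrow = nrow(observed), ncol = n)
  seeds <- derive_seeds(seed, n)
  for (k in seq_len(n)) {
    shuf <- shuffle_intervals(peaks, partition$chrom_sizes,
                              seed = seeds[[k]], no_overlap = no_overlap)
    random_mat[, k] <- assign_peaks(shuf, partition)$table$percent
  }
  .fold_results(observed$category, observed$percent, random_mat, n)
}

#' Per-subtype PQS fold enrichment of a peak set
#'
#' The observed statistic is the number of PQS records of each subtype
#' (plus the aggregate G3L1-12) overlapping the peak set; the
#' expectation is the mean count within \code{n} genome-wide shuffles
#' of the peaks. The genome is scanned once; randomizations only move
#' the intervals.
#'
#' @param peaks A \code{GRanges}.
#' @param genome A named \code{DNAStringSet}/character vector, scanned
#'   with \code{\link{scan_pqs}} when \code{pqs} is not supplied.
#' @param chrom_sizes Named lengths; defaults to the genome's widths.
#' @param pqs Optional precomputed \code{scan_pqs} result.
#' @param n Number of randomizations.
#' @param seed Optional master seed.
#' @param no_overlap Passed to \code{\link{shuffle_intervals}}.
#' @return A data.frame of per-subtype enrichment results.
#' @export
pqs_fold <- function(peaks, genome = NULL, chrom_sizes = NULL,
                     pqs = NULL, n = 100L, seed = NULL,
                     no_overlap = TRUE) {
  if (n < 1L) stop("n must be >= 1")
  if (is.null(pqs)) {
    if (is.null(genome)) stop("supply either genome or pqs")
    pqs <- scan_pqs(genome)
  }
  if (is.null(chrom_sizes)) {
    if (is.null(genome)) stop("supply chrom_sizes when genome is absent")
    if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
    chrom_sizes <- stats::setNames(Biostrings::width(genome),
                                   names(genome))
  }
  # one overlap pass per interval set, tallied into the five strata
  strata <- c(pqs_subtypes(), "G3L1-12")
  count_in <- function(set) {
    inpeak <- IRanges::overlapsAny(pqs, set, ignore.strand = TRUE)
    per <- table(factor(pqs$subtype[inpeak], levels = pqs_subtypes()))
    c(as.integer(per), sum(per[c("G3L1-7", "G3L8-12")]))
  }
  observed <- count_in(peaks)
  random_mat <- matrix(0, nrow = length(strata), ncol = n)
  seeds <- derive_seeds(seed, n)
  for (k in seq_len(n)) {
    shuf <- shuffle_intervals(peaks, chrom_sizes, seed = seeds[[k]],
                              no_overlap = no_overlap)
    random_mat[, k] <- count_in(shuf)
  }
  .fold_results(strata, observed, random_mat, n)
}

# Deterministic per-randomization seed streams from one master seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% .Machine$integer.max)
}

#' Wilcoxon rank-sum (Mann-Whitney) test p-value
#'
#' Exact p-value for small untied samples (both n <= 20), normal
#' approximation with tie correction and continuity correction
#' otherwise. Two samples with all values identical return p = 1 by
#' convention.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return The p-value.
#' @export
rank_sum <- function(values_a, values_b, alternative = "two.sided") {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both samples must be non-empty")
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) return(1)
  exact <- length(values_a) <= 20L && length(values_b) <= 20L &&
    !anyDuplicated(pooled)
  stats::wilcox.test(values_a, values_b, alternative = alternative,
                     exact = exact, correct = TRUE)$p.value
}
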