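# Build the center-anchored bin scaffold for a set of regions: nb bins
# of `bin` bp tiling [mid - flank, mid + flank). Returns a list with a
# clipped GRanges of in-bounds bins plus index bookkeeping.
.center_bins <- function(intervals, chrom_sizes, flank, bin) {
  nb <- as.integer(2 * flank / bin)
  mid0 <- interval_midpoint(intervals) - 1  # 0-based midpoint base
  chroms <- as.character(GenomicRanges::seqnames(intervals))
  L <- chrom_sizes[chroms]
  keep_region <- (mid0 - flank + 1) <= L & (mid0 + flank) >= 1
  if (!all(keep_region)) {
    message(sum(!keep_region), " region(s) fully off-chromosome skipped")
  }
  ridx <- which(keep_region)
  n <- length(ridx)
  bs0 <- rep(mid0[ridx], each = nb) +
    rep(seq_len(nb) - 1L, times = n) * bin - flank
  be0 <- bs0 + bin
  chrom_b <- rep(chroms[ridx], each = nb)
  Lb <- chrom_sizes[chrom_b]
  inb <- bs0 < Lb & be0 > 0
  gr <- GenomicRanges::GRanges(
    chrom_b[inb],
    IRanges::IRanges(pmax(bs0[inb] + 1, 1), pmin(be0[inb], Lb[inb])))
  list(bins = gr, nb = nb, region_of = rep(seq_len(n), each = nb)[inb],
       bin_of = rep(seq_len(nb), times = n)[inb],
       region_idx = ridx, n_regions = n)
}

#' Peak-centered profile of a quantitative signal track
#'
#' Tiles the +/- \code{flank} bp window around each interval midpoint
#' into fixed \code{bin} bp bins and computes, per bin, the
#' length-weighted mean of the track runs overlapping it, then averages
#' bins across regions. Bins without track coverage (or off-chromosome)
#' are missing; regions whose window lies fully off-chromosome are
#' skipped with a message. The per-region bin matrix is retained for
#' rank-sum comparisons between peak classes.
#'
#' @param track A \code{GRanges} with a \code{score} column (bedGraph
#'   runs).
#' @param intervals A \code{GRanges} of regions.
#' @param chrom_sizes Named chromosome lengths.
#' @param flank Half-window in bp.
#' @param bin Bin width in bp.
#' @return A \code{binned_profile}; \code{$matrix} holds the
#'   region-by-bin values.
#' @export
center_profile <- function(track, intervals, chrom_sizes,
                           flank = 1000L, bin = 20L) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  sc <- .center_bins(intervals, chrom_sizes, flank, bin)
  mat <- matrix(NA_real_, nrow = sc$n_regions, ncol = sc$nb)
  if (length(sc$bins)) {
    hits <- GenomicRanges::findOverlaps(sc$bins, track,
                                        ignore.strand = TRUE)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(sc$bins)[qh],
        GenomicRanges::ranges(track)[sh]))
      dt <- data.table::data.table(
        r = sc$region_of[qh], b = sc$bin_of[qh],
        wv = w * track$score[sh], w = w)
      agg <- dt[, list(v = sum(wv) / sum(w)), by = c("r", "b")]
      mat[cbind(agg$r, agg$b)] <- agg$v
    }
  }
  new_binned_profile(
    values = colMeans(mat, na.rm = TRUE),
    n_contrib = colSums(!is.na(mat)),
    statistic = "signal",
    scheme = list(body_bins = 0L, flank_bp = flank, flank_bin_bp = bin),
    n_regions = sc$n_regions,
    matrix = mat
  )
}

#' Center-anchored cytosine methylation metaprofile
#'
#' For one cytosine context, pools all cytosines of that context
#' falling in each +/- \code{flank} bp bin around the interval
#' midpoints (both strands) and reports the coverage-weighted level
#' sum(meth) / sum(total) per bin, summed over regions. Bins with no
#' covered cytosine are missing.
#'
#' @param meth A \code{GRanges} from \code{\link{read_cytosine_report}}.
#' @param intervals A \code{GRanges} of regions.
#' @param context "CG", "CHG" or "CHH".
#' @param chrom_sizes Named chromosome lengths.
#' @param flank Half-window in bp.
#' @param bin Bin width in bp.
#' @return A \code{binned_profile} with values in [0, 1].
#' @export
methylation_profile <- function(meth, intervals,
                                context = c("CG", "CHG", "CHH"),
                                chrom_sizes, flank = 1000L, bin = 20L) {
  context <- match.arg(context)
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  meth <- meth[meth$context == context & meth$total_count > 0]
  nb <- as.integer(2 * flank / bin)
  mid0 <- interval_midpoint(intervals) - 1
  windows <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(intervals),
    IRanges::IRanges(pmax(mid0 - flank + 1, 1),
                     pmin(mid0 + flank,
                          chrom_sizes[as.character(
                            GenomicRanges::seqnames(intervals))])))
  hits <- GenomicRanges::findOverlaps(meth, windows,
                                      ignore.strand = TRUE)
  msum <- numeric(nb)
  tsum <- numeric(nb)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    off <- GenomicRanges::start(meth)[qh] - 1 - (mid0[sh] - flank)
    b <- off %/% bin + 1L
    ok <- b >= 1L & b <= nb
    msum <- as.numeric(tapply(meth$meth_count[qh][ok],
                              factor(b[ok], levels = seq_len(nb)), sum,
                              default = 0))
    tsum <- as.numeric(tapply(meth$total_count[qh][ok],
                              factor(b[ok], levels = seq_len(nb)), sum,
                              default = 0))
  }
  vals <- ifelse(tsum > 0, msum / tsum, NA_real_)
  if (all(is.na(vals))) {
    warning("no covered cytosines of context ", context,
            " in any window")
  }
  new_binned_profile(
    values = vals,
    n_contrib = as.integer(tsum > 0),
    statistic = paste0("methylation_", context),
    scheme = list(body_bins = 0L, flank_bp = flank, flank_bin_bp = bin),
    n_regions = length(intervals)
  )
}

#' Random control regions matched for C content
#'
#' For each observed interval, rejection-samples a same-length position
#' elsewhere on the genome (never overlapping the observed set) until
#' its C content is within \code{c_tolerance} of the observed
#' interval's. After every \code{relax_after} failed rounds the
#' tolerance is widened by one \code{c_tolerance} step (with a
#' warning), so the procedure always terminates on feasible genomes.
#'
#' @param intervals Observed regions (\code{GRanges}).
#' @param genome Named \code{DNAStringSet} or character vector.
#' @param c_tolerance Allowed absolute C-content difference (and the
#'   relaxation step).
#' @param seed Optional seed.
#' @param relax_after Rounds between tolerance relaxations.
#' @param max_rounds Hard cap on sampling rounds.
#' @return A \code{GRanges} of matched random regions, one per input.
#' @export
matched_random_regions <- function(intervals, genome,
                                   c_tolerance = 0.01, seed = NULL,
                                   relax_after = 50L,
                                   max_rounds = 500L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chrom_sizes <- stats::setNames(Biostrings::width(genome),
                                 names(genome))
  target <- region_c_content(intervals, genome)
  lens <- GenomicRanges::width(intervals)
  n <- length(intervals)
  with_seed(seed, {
    out_chrom <- character(n)
    out_start <- numeric(n)
    placed <- rep(FALSE, n)
    tol <- rep(c_tolerance, n)
    relaxed <- FALSE
    for (round in seq_len(max_rounds)) {
      todo <- which(!placed)
      if (!length(todo)) break
      if (round %% relax_after == 0L) {
        tol[todo] <- tol[todo] + c_tolerance
        relaxed <- TRUE
      }
      chrom <- sample(names(chrom_sizes), length(todo), replace = TRUE,
                      prob = chrom_sizes)
      fit <- chrom_sizes[chrom] - lens[todo] + 1
      ok <- fit >= 1
      start <- floor(stats::runif(length(todo)) * pmax(fit, 1)) + 1
      cand <- GenomicRanges::GRanges(chrom[ok],
                                     IRanges::IRanges(start[ok],
                                                      width = lens[todo][ok]))
      cidx <- todo[ok]
      keep <- !IRanges::overlapsAny(cand, intervals,
                                    ignore.strand = TRUE)
      if (any(keep)) {
        cc <- region_c_content(cand[keep], genome)
        sel <- which(keep)[abs(cc - target[cidx[keep]]) <=
                             tol[cidx[keep]]]
        idx <- cidx[sel]
        placed[idx] <- TRUE
        out_chrom[idx] <- as.character(
          GenomicRanges::seqnames(cand))[sel]
        out_start[idx] <- GenomicRanges::start(cand)[sel]
      }
    }
    if (!all(placed)) {
      stop("could not find C-content-matched controls for ",
           sum(!placed), " region(s)")
    }
    if (relaxed) {
      warning("C-content tolerance was relaxed for some regions")
    }
    GenomicRanges::GRanges(out_chrom,
                           IRanges::IRanges(out_start, width = lens))
  })
}

#' Per-region signal enrichment over the genome-wide mean
#'
#' @param track A \code{GRanges} with a \code{score} column.
#' @param regions A \code{GRanges}.
#' @param label Track label carried into the output.
#' @return A data.frame with region id, track label and score =
#'   mean(track over region) / mean(track genome-wide), both
#'   length-weighted.
#' @export
region_fold <- function(track, regions, label = "track") {
  gw <- sum(GenomicRanges::width(track) * track$score) /
    sum(GenomicRanges::width(track))
  hits <- GenomicRanges::findOverlaps(regions, track,
                                      ignore.strand = TRUE)
  score <- rep(NA_real_, length(regions))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(regions)[qh],
      GenomicRanges::ranges(track)[sh]))
    dt <- data.table::data.table(r = qh, wv = w * track$score[sh],
                                 w = w)
    agg <- dt[, list(v = sum(wv) / sum(w)), by = "r"]
    score[agg$r] <- agg$v / gw
  }
  data.frame(region = seq_along(regions), track = label, score = score)
}

#' Metagene profile of a signal track by expression class
#'
#' Scales every gene body to \code{body_bins} bins and adds
#' \code{flank} bp flanks in \code{bin} bp windows, oriented in the
#' direction of transcription (profiles run TSS to TES; minus-strand
#' genes are reversed). Genes are grouped by expression class and each
#' class profile is the per-bin mean over its genes.
#'
#' @param track A \code{GRanges} with a \code{score} column.
#' @param models A \code{gene_models} object.
#' @param classes A data.frame with columns \code{gene_id} and
#'   \code{class} (as from \code{\link{classify_expression}}).
#' @param chrom_sizes Named chromosome lengths.
#' @param flank,body_bins,bin Bin scheme parameters.
#' @return A named list of \code{binned_profile} objects, one per
#'   non-empty class (empty classes are dropped with a warning).
#' @export
metagene_profile <- function(track, models, classes, chrom_sizes,
                             flank = 1000L, body_bins = 50L,
                             bin = 20L) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  genes <- models$genes
  sel <- match(classes$gene_id, genes$gene_id)
  if (anyNA(sel)) stop("expression classes name unknown genes")
  nf <- as.integer(flank / bin)
  nb <- 2L * nf + body_bins
  n <- nrow(classes)
  chroms <- as.character(GenomicRanges::seqnames(genes))[sel]
  s1 <- GenomicRanges::start(genes)[sel]
  e1 <- GenomicRanges::end(genes)[sel]
  minus <- as.character(GenomicRanges::strand(genes))[sel] == "-"
  len <- e1 - s1 + 1
  # genomic bin boundaries, left to right: upstream-left flank, body,
  # right flank; orientation applied when filling the matrix
  bs0 <- be0 <- matrix(0, nrow = n, ncol = nb)
  for (j in seq_len(nf)) {
    bs0[, j] <- s1 - 1 - flank + (j - 1L) * bin
    bs0[, nf + body_bins + j] <- e1 + (j - 1L) * bin
  }
  for (k in seq_len(body_bins)) {
    bs0[, nf + k] <- s1 - 1 + floor((k - 1) * len / body_bins)
    be0[, nf + k] <- s1 - 1 + floor(k * len / body_bins)
  }
  be0[, seq_len(nf)] <- bs0[, seq_len(nf)] + bin
  be0[, nf + body_bins + seq_len(nf)] <-
    bs0[, nf + body_bins + seq_len(nf)] + bin
  L <- chrom_sizes[chroms]
  flat_s <- as.vector(bs0); flat_e <- as.vector(be0)
  flat_chrom <- rep(chroms, times = nb)
  flat_L <- rep(unname(L), times = nb)
  valid <- flat_s < flat_e & flat_e > 0 & flat_s < flat_L
  gr <- GenomicRanges::GRanges(
    flat_chrom[valid],
    IRanges::IRanges(pmax(flat_s[valid] + 1, 1),
                     pmin(flat_e[valid], flat_L[valid])))
  ridx <- rep(seq_len(n), times = nb)[valid]
  bidx <- rep(seq_len(nb), each = n)[valid]
  mat <- matrix(NA_real_, nrow = n, ncol = nb)
  hits <- GenomicRanges::findOverlaps(gr, track, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gr)[qh],
      GenomicRanges::ranges(track)[sh]))
    dt <- data.table::data.table(r = ridx[qh], b = bidx[qh],
                                 wv = w * track$score[sh], w = w)
    agg <- dt[, list(v = sum(wv) / sum(w)), by = c("r", "b")]
    mat[cbind(agg$r, agg$b)] <- agg$v
  }
  mat[minus, ] <- mat[minus, nb:1, drop = FALSE]
  out <- list()
  for (cls in unique(as.character(classes$class))) {
    rows <- which(as.character(classes$class) == cls)
    if (!length(rows)) next
    sub <- mat[rows, , drop = FALSE]
    out[[cls]] <- new_binned_profile(
      values = colMeans(sub, na.rm = TRUE),
      n_contrib = colSums(!is.na(sub)),
      statistic = paste0("metagene_", cls),
      scheme = list(body_bins = body_bins, flank_bp = flank,
                    flank_bin_bp = bin),
      n_regions = length(rows),
      matrix = sub
    )
  }
  missing_cls <- setdiff(levels(factor(classes$class)), names(out))
  if (length(missing_cls)) {
    warning("expression class(es) with zero genes omitted: ",
            paste(missing_cls, collapse = ", "))
  }
  out
}
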