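# Internal helpers shared across modules.

# let data.table find its methods although we only use data.table::
.datatable.aware <- TRUE

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Restores the caller's .Random.seed afterwards so library calls do not
# perturb user-level reproducibility. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# Validate a named chromosome-size vector.
check_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)) ||
      any(names(chrom_sizes) == "")) {
    stop("chrom_sizes must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(names(chrom_sizes))) {
    stop("duplicate chromosome names in chrom_sizes")
  }
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
}

# Check that every interval lies on a known chromosome (and, optionally,
# within its bounds).
check_on_genome <- function(gr, chrom_sizes, within = TRUE,
                            what = "interval") {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(chrom_sizes))
  if (any(bad)) {
    stop(sprintf("%s on unknown chromosome: %s", what,
                 paste(unique(as.character(
                   GenomicRanges::seqnames(gr)[bad])), collapse = ", ")))
  }
  if (within) {
    len <- chrom_sizes[as.character(GenomicRanges::seqnames(gr))]
    if (any(GenomicRanges::start(gr) < 1 | GenomicRanges::end(gr) > len)) {
      stop(sprintf("%s extends beyond chromosome bounds", what))
    }
  }
  invisible(gr)
}

# Midpoint base of an interval, matching floor((start0 + end0) / 2) in
# 0-based half-open coordinates; returned 1-based.
interval_midpoint <- function(gr) {
  floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2) + 1
}

# Deterministic number -> character formatting used by all writers, so
# that write(read(x)) round-trips byte-identically for files the package
# itself emits.
fmt_num <- function(x) {
  x <- as.numeric(x)
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- "."
  ints <- !na & is.finite(x) & x == round(x) & abs(x) < 1e15
  if (any(ints)) {
    out[ints] <- format(x[ints], scientific = FALSE, trim = TRUE)
  }
  rest <- !na & !ints
  if (any(rest)) out[rest] <- as.character(x[rest])
  out
}

# Constructor for the fixed-shape binned profile container used by the
# composition, signal and methylation profilers.
new_binned_profile <- function(values, n_contrib, statistic, scheme,
                               n_regions, matrix = NULL) {
  structure(
    list(values = as.numeric(values),
         n_contrib = as.integer(n_contrib),
         statistic = statistic,
         scheme = scheme,
         n_regions = as.integer(n_regions),
         matrix = matrix),
    class = "binned_profile"
  )
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("binned_profile: %s over %d region(s), %d bins\n",
              x$statistic, x$n_regions, length(x$values)))
  sch <- x$scheme
  cat(sprintf("  scheme: %s body bins, %d bp flanks in %d bp bins\n",
              if (is.null(sch$body_bins)) "no" else sch$body_bins,
              sch$flank_bp, sch$flank_bin_bp))
  fin <- x$values[is.finite(x$values)]
  if (length(fin)) {
    cat(sprintf("  value range: [%.4g, %.4g]\n", min(fin), max(fin)))
  }
  invisible(x)
}

#' @export
as.data.frame.binned_profile <- function(x, ...) {
  data.frame(bin = seq_along(x$values),
             offset = profile_bin_offsets(x),
             value = x$values,
             n = x$n_contrib)
}

# Human-readable genomic offset label per bin (flank bins in bp relative
# to the region edge or center; body bins as fractions).
profile_bin_offsets <- function(x) {
  sch <- x$scheme
  nf <- sch$flank_bp / sch$flank_bin_bp
  if (is.null(sch$body_bins) || sch$body_bins == 0) {
    # center-anchored profile: bins span [-flank, +flank)
    starts <- seq(-sch$flank_bp, sch$flank_bp - sch$flank_bin_bp,
                  by = sch$flank_bin_bp)
    return(sprintf("%+d", starts + sch$flank_bin_bp / 2))
  }
  left <- sprintf("%+d", seq(-sch$flank_bp, -sch$flank_bin_bp,
                             by = sch$flank_bin_bp) + sch$flank_bin_bp / 2)
  body <- sprintf("body%02d", seq_len(sch$body_bins))
  right <- sprintf("%+d", seq(0, sch$flank_bp - sch$flank_bin_bp,
                              by = sch$flank_bin_bp) + sch$flank_bin_bp / 2)
  c(left, body, right)
}
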