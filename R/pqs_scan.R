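#' Classify a putative G-quadruplex sequence by tract and loop lengths
#'
#' Subtype nomenclature follows the GxLy-z scheme used for plant PQS
#' catalogues: tracts of at least two ("G2") or three ("G3") guanines,
#' with loop classes L1-7 (all loops at most 7 nt) and L8-12 (at least
#' one loop of 8-12 nt).
#'
#' @param tract_len Minimum guanine run per tract, 2 or 3.
#' @param loop_lens Integer vector of loop lengths, each in 1..12.
#' @return A subtype label: one of "G2L1-7", "G2L8-12", "G3L1-7",
#'   "G3L8-12".
#' @export
classify_pqs <- function(tract_len, loop_lens) {
  if (!tract_len %in% c(2L, 3L)) stop("tract_len must be 2 or 3")
  if (length(loop_lens) < 3L) stop("a PQS has at least 3 loops")
  if (any(loop_lens < 1L | loop_lens > 12L)) {
    stop("loop length outside [1, 12]")
  }
  sprintf("G%dL%s", tract_len,
          if (max(loop_lens) <= 7L) "1-7" else "8-12")
}

#' Names of the four exclusive PQS subtypes
#' @export
pqs_subtypes <- function() c("G2L1-7", "G2L8-12", "G3L1-7", "G3L8-12")

# Maximal runs of `base` with length >= min_len in an uppercase string.
# Returns a data.frame of 1-based (start, end).
.find_runs <- function(s, base, min_len) {
  m <- gregexpr(sprintf("%s{%d,}", base, min_len), s)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  st <- as.integer(m)
  data.frame(start = st, end = st + attr(m, "match.length") - 1L)
}

# Chain maximal tract runs into leftmost-longest, non-overlapping PQS
# matches. Runs are linked when separated by a loop of 1..12 bases
# containing no N; every maximal linked block of >= 4 runs yields one
# match spanning the whole block (surplus guanines are absorbed into the
# tracts, never counted as loop).
.chain_runs <- function(runs, s, min_loop = 1L, max_loop = 12L) {
  n <- nrow(runs)
  out <- list()
  if (n < 4L) return(out)
  gap_len <- runs$start[-1] - runs$end[-n] - 1L
  link <- gap_len >= min_loop & gap_len <= max_loop
  # reject loops containing N (candidate rejected, not an error)
  for (i in which(link)) {
    loop <- substr(s, runs$end[i] + 1L, runs$start[i + 1L] - 1L)
    if (grepl("N", loop, fixed = TRUE)) link[i] <- FALSE
  }
  block_id <- cumsum(c(TRUE, !link))
  for (b in split(seq_len(n), block_id)) {
    if (length(b) < 4L) next
    loops <- gap_len[b[-length(b)]]
    out[[length(out) + 1L]] <- list(
      start = runs$start[b[1L]],
      end = runs$end[b[length(b)]],
      n_tracts = length(b),
      loops = as.integer(loops)
    )
  }
  out
}

.scan_one_strand <- function(s, chrom, strand, tract_len) {
  base <- if (strand == "+") "G" else "C"
  runs <- .find_runs(s, base, tract_len)
  matches <- .chain_runs(runs, s)
  if (length(matches) == 0L) return(GenomicRanges::GRanges())
  start <- vapply(matches, `[[`, integer(1), "start")
  end <- vapply(matches, `[[`, integer(1), "end")
  loops <- lapply(matches, `[[`, "loops")
  if (strand == "-") loops <- lapply(loops, rev)  # 5'->3' on G-rich strand
  seqs <- substring(s, start, end)
  if (strand == "-") {
    seqs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
  }
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end), strand = strand,
    tract_len = tract_len,
    n_tracts = vapply(matches, `[[`, integer(1), "n_tracts"),
    max_loop = vapply(loops, max, integer(1)),
    loops = vapply(loops, paste, character(1), collapse = ","),
    subtype = vapply(loops, function(l) classify_pqs(tract_len, l),
                     character(1)),
    sequence = seqs
  )
}

#' Scan a genome for putative G-quadruplex sequences
#'
#' Finds, on both strands, runs of at least \code{min_tract} guanines
#' (tracts) separated by 1-12 nt loops, with at least four tracts per
#' match: the G3 pattern G\{3,\}(N\{1,12\}G\{3,\})\{3,\} and its G2
#' counterpart. Matching is leftmost-longest and non-overlapping within
#' a strand and tract class; maximal guanine runs are absorbed whole
#' into tracts. Minus-strand PQSs are detected as C-patterns on the
#' forward sequence and reported with strand "-" in forward coordinates.
#' A G2-class match overlapping a G3-class match on the same strand is
#' suppressed, so the four subtypes partition the reported records.
#' Candidates whose loops contain N are rejected silently; characters
#' outside A/C/G/T/N are an error.
#'
#' @param genome A named \code{DNAStringSet} or named character vector of
#'   chromosome sequences (case-insensitive).
#' @param tract_classes Which tract classes to report, subset of
#'   \code{c(3, 2)}. G3 is always scanned first so that G2/G3
#'   exclusivity is well defined.
#' @return A \code{GRanges} sorted by (chrom, start) with metadata
#'   columns \code{tract_len}, \code{n_tracts}, \code{max_loop},
#'   \code{loops} (comma-separated, 5' to 3' on the G-rich strand),
#'   \code{subtype} and \code{sequence} (the G-rich strand sequence).
#' @export
scan_pqs <- function(genome, tract_classes = c(3L, 2L)) {
  if (!is.character(genome)) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome))) stop("genome sequences must be named")
  stopifnot(all(tract_classes %in% c(2L, 3L)))
  res <- list()
  for (chrom in names(genome)) {
    s <- toupper(genome[[chrom]])
    if (grepl("[^ACGTN]", s)) {
      stop(sprintf("non-IUPAC character in sequence '%s' ",
                   chrom), "(only A/C/G/T/N are supported)")
    }
    for (strand in c("+", "-")) {
      g3 <- .scan_one_strand(s, chrom, strand, 3L)
      hits <- list()
      if (3L %in% tract_classes) hits <- c(hits, list(g3))
      if (2L %in% tract_classes) {
        g2 <- .scan_one_strand(s, chrom, strand, 2L)
        if (length(g2) && length(g3)) {
          keep <- !IRanges::overlapsAny(IRanges::ranges(g2),
                                        IRanges::ranges(g3))
          g2 <- g2[keep]
        }
        hits <- c(hits, list(g2))
      }
      res[[length(res) + 1L]] <- do.call(c, hits)
    }
  }
  out <- suppressWarnings(do.call(c, res))  # chrom-wise seqinfo merge
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  out[order(as.character(GenomicRanges::seqnames(out)),
            GenomicRanges::start(out), GenomicRanges::end(out),
            as.character(GenomicRanges::strand(out)))]
}

#' Summarize PQS content of a peak set
#'
#' A PQS is attributed to a peak when their intervals overlap by at
#' least 1 bp (strand-agnostic). For every subtype (and the aggregate
#' G3L1-12 class) the table reports the number of attributed PQS
#' records, the percentage of peaks containing at least one such PQS,
#' and the density per kb of total peak length.
#'
#' @param peaks A \code{GRanges} of peaks.
#' @param pqs A \code{GRanges} from \code{\link{scan_pqs}}.
#' @return A data.frame with columns subtype, count, percent_peaks,
#'   density_per_kb. Empty peak set gives a zero-row table.
#' @export
pqs_content <- function(peaks, pqs) {
  if (length(peaks) == 0L) {
    return(data.frame(subtype = character(0), count = integer(0),
                      percent_peaks = numeric(0),
                      density_per_kb = numeric(0)))
  }
  total_kb <- sum(GenomicRanges::width(peaks)) / 1000
  groups <- c(as.list(pqs_subtypes()),
              list(c("G3L1-7", "G3L8-12")))
  labels <- c(pqs_subtypes(), "G3L1-12")
  rows <- lapply(seq_along(groups), function(i) {
    sub <- pqs[pqs$subtype %in% groups[[i]]]
    if (length(sub) == 0L) {
      return(data.frame(subtype = labels[i], count = 0L,
                        percent_peaks = 0, density_per_kb = 0))
    }
    inpeak <- IRanges::overlapsAny(sub, peaks, ignore.strand = TRUE)
    with_pqs <- IRanges::overlapsAny(peaks, sub, ignore.strand = TRUE)
    data.frame(subtype = labels[i],
               count = sum(inpeak),
               percent_peaks = 100 * mean(with_pqs),
               density_per_kb = sum(inpeak) / total_kb)
  })
  do.call(rbind, rows)
}

#' Export fixed windows around peak centers for motif discovery
#'
#' Extracts the genome sequence of the +/- \code{half_width} bp window
#' around each peak center (center = floor((start + end) / 2) in
#' 0-based coordinates, window half-open of width 2 * half_width),
#' suitable as MEME-ChIP input. Windows extending past a chromosome end
#' are clipped and flagged in the FASTA header. Headers encode the
#' window and source-peak coordinates (0-based half-open).
#'
#' @param peaks A \code{GRanges}.
#' @param genome A named \code{DNAStringSet} or character vector.
#' @param half_width Half window width in bp.
#' @param path Optional FASTA output path.
#' @return A \code{DNAStringSet} (invisibly written to \code{path} when
#'   given).
#' @export
export_meme_windows <- function(peaks, genome, half_width = 100L,
                                path = NULL) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  check_on_genome(peaks, lens, what = "peak")
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  mid0 <- floor((GenomicRanges::start(peaks) - 1 +
                   GenomicRanges::end(peaks)) / 2)
  ws1 <- mid0 - half_width + 1
  we1 <- mid0 + half_width
  cl_s <- pmax(ws1, 1)
  cl_e <- pmin(we1, lens[chrom])
  clipped <- cl_s != ws1 | cl_e != we1
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(peaks), function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]], cl_s[i], cl_e[i]))
  }, character(1)))
  names(seqs) <- sprintf(
    "%s:%d-%d|src=%s:%d-%d%s",
    chrom, cl_s - 1, cl_e, chrom,
    GenomicRanges::start(peaks) - 1, GenomicRanges::end(peaks),
    ifelse(clipped, "|clipped", "")
  )
  if (!is.null(path)) write_fasta(seqs, path)
  invisible(seqs)
}
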