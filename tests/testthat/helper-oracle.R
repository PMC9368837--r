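# Independent brute-force PQS enumerator used as the scanner oracle.
#
# Works from first principles on the character vector: maximal base
# runs are found with rle(), every ordered run pair is tested as a
# candidate match (all consecutive loops 1-12 nt and N-free, >= 4
# tracts), and the leftmost-longest non-overlapping selection is
# applied to the full candidate list. Deliberately quadratic and
# independent of the package's chaining implementation.
oracle_scan <- function(seq_str, tract_classes = c(3L, 2L)) {
  ch <- strsplit(toupper(seq_str), "", fixed = TRUE)[[1]]
  n <- length(ch)

  runs_of <- function(base, min_len) {
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values == base & r$lengths >= min_len
    cbind(start = starts[sel], end = ends[sel])
  }

  candidates <- function(base, min_len) {
    runs <- runs_of(base, min_len)
    out <- list()
    if (nrow(runs) < 4L) return(out)
    for (i in seq_len(nrow(runs) - 3L)) {
      for (j in seq(i + 3L, nrow(runs))) {
        gaps <- runs[(i + 1L):j, "start"] - runs[i:(j - 1L), "end"] - 1L
        if (any(gaps < 1L | gaps > 12L)) next
        loop_ok <- all(vapply(seq_len(j - i), function(k) {
          !any(ch[(runs[i + k - 1L, "end"] + 1L):
                    (runs[i + k, "start"] - 1L)] == "N")
        }, logical(1)))
        if (!loop_ok) next
        out[[length(out) + 1L]] <- list(start = runs[i, "start"],
                                        end = runs[j, "end"],
                                        loops = as.integer(gaps))
      }
    }
    out
  }

  select_llo <- function(cand) {
    if (!length(cand)) return(cand)
    ord <- order(vapply(cand, `[[`, integer(1), "start"),
                 -vapply(cand, `[[`, integer(1), "end"))
    cand <- cand[ord]
    kept <- list()
    last_end <- 0L
    for (cc in cand) {
      if (cc$start > last_end) {
        kept[[length(kept) + 1L]] <- cc
        last_end <- cc$end
      }
    }
    kept
  }

  rows <- list()
  for (strand in c("+", "-")) {
    base <- if (strand == "+") "G" else "C"
    g3 <- select_llo(candidates(base, 3L))
    sets <- list()
    if (3L %in% tract_classes) sets[["3"]] <- g3
    if (2L %in% tract_classes) {
      g2 <- select_llo(candidates(base, 2L))
      g2 <- Filter(function(cc) {
        !any(vapply(g3, function(m) {
          cc$start <= m$end && cc$end >= m$start
        }, logical(1)))
      }, g2)
      sets[["2"]] <- g2
    }
    for (tl in names(sets)) {
      for (cc in sets[[tl]]) {
        loops <- if (strand == "-") rev(cc$loops) else cc$loops
        rows[[length(rows) + 1L]] <- data.frame(
          start = cc$start, end = cc$end, strand = strand,
          subtype = classify_pqs(as.integer(tl), loops))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), subtype = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Canonical key-set for comparing scanner output with the oracle.
pqs_keys <- function(df) {
  sort(sprintf("%d:%d:%s:%s", df$start, df$end, df$strand, df$subtype))
}

# Random sequence with enough G/C density to exercise the scanner.
random_seq <- function(n, probs = c(A = 0.2, C = 0.3, G = 0.3,
                                    T = 0.2)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Small shared simulated bundle for IO/annotation tests (built once).
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_chroms = 2, chrom_len = 2e5, n_genes = 40,
                        pqs = list(n_per_subtype = 15),
                        peaks = list(n_per_condition = 150))
      cache <<- generate_dataset(cfg, dir = file.path(tempdir(),
                                                      "g4scape_tiny"),
                                 seed = 42)
    }
    cache
  }
})
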