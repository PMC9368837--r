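#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions the test-bed emulates: a
#' 2 x 2.5 Mb two-chromosome toy genome, 300 genes, two conditions with
#' two replicates of 2,000 peaks each, 80% replicate overlap and 60%
#' cross-condition overlap realized constructively, peak lengths ~
#' Normal(250, 40) truncated at 50 bp, CG methylation 0.8 inside peaks
#' over a 0.2 background with Poisson(20) coverage, and one signal
#' track with Gaussian coverage (amplitude 5, sigma 150 bp) planted at
#' condition-specific peak centers. The background base model forbids
#' GG and CC dinucleotides so that every scanner hit is a planted PQS.
#'
#' @param n_chroms,chrom_len Genome shape.
#' @param n_genes,gene_len_range,exon_count_range,utr5_len,utr3_len,te_fraction
#'   Gene layout parameters.
#' @param pqs List: \code{n_per_subtype}, \code{n_tracts}.
#' @param peaks List: \code{n_per_condition}, \code{len_mean},
#'   \code{len_sd}, \code{len_min}, \code{replicate_overlap},
#'   \code{cross_condition_overlap}, \code{n_conditions} (1 or 2),
#'   \code{compartment_fold} (named vector of planted
#'   observed/expected fold targets, e.g. \code{c(promoter = 3)}),
#'   \code{promoter_link_fraction}, \code{jitter}, \code{min_gap}.
#' @param methylation List: per-context \code{levels} (peak,
#'   background), \code{coverage_mean}, \code{beta_concentration}.
#' @param signal List of named tracks, each \code{background},
#'   \code{amplitude}, \code{sigma}, \code{peak_class} (one of
#'   a_specific, b_specific, common, all).
#' @param expression List: \code{meanlog}, \code{sdlog},
#'   \code{nonexpressed_fraction}, \code{promoter_peak_multiplier}.
#' @param condition_labels Length-2 condition names.
#' @param components Which optional layers to simulate (any of
#'   "methylation", "signal", "expression"); genome, genes, PQSs and
#'   peaks are always generated.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_chroms = 2L, chrom_len = 2.5e6,
                       n_genes = 300L,
                       gene_len_range = c(1000L, 5000L),
                       exon_count_range = c(1L, 4L),
                       utr5_len = 150L, utr3_len = 200L,
                       te_fraction = 0.5,
                       pqs = list(), peaks = list(),
                       methylation = list(), signal = NULL,
                       expression = list(),
                       condition_labels = c("K", "Na"),
                       components = c("methylation", "signal",
                                      "expression")) {
  pqs <- utils::modifyList(list(n_per_subtype = 100L, n_tracts = 4L),
                           pqs)
  peaks <- utils::modifyList(
    list(n_per_condition = 2000L, len_mean = 250, len_sd = 40,
         len_min = 50L, replicate_overlap = 0.8,
         cross_condition_overlap = 0.6, n_conditions = 2L,
         compartment_fold = NULL, promoter_link_fraction = 0,
         jitter = 20L, min_gap = 60L),
    peaks)
  methylation <- utils::modifyList(
    list(levels = list(CG = c(peak = 0.8, background = 0.2),
                       CHG = c(peak = 0.6, background = 0.15),
                       CHH = c(peak = 0.15, background = 0.05)),
         coverage_mean = 20, beta_concentration = 50),
    methylation)
  if (is.null(signal)) {
    signal <- list(signal = list(background = 1, amplitude = 5,
                                 sigma = 150,
                                 peak_class = "a_specific"))
  }
  expression <- utils::modifyList(
    list(meanlog = 1, sdlog = 1.2, nonexpressed_fraction = 0.25,
         promoter_peak_multiplier = 2),
    expression)
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_len = as.numeric(chrom_len),
              n_genes = as.integer(n_genes),
              gene_len_range = gene_len_range,
              exon_count_range = exon_count_range,
              utr5_len = utr5_len, utr3_len = utr3_len,
              te_fraction = te_fraction, pqs = pqs, peaks = peaks,
              methylation = methylation, signal = signal,
              expression = expression,
              condition_labels = condition_labels,
              components = components)
  with(cfg, {
    stopifnot(n_chroms >= 1, chrom_len >= 1e4, n_genes >= 0,
              te_fraction >= 0, te_fraction <= 1,
              peaks$replicate_overlap >= 0,
              peaks$replicate_overlap <= 1,
              peaks$cross_condition_overlap >= 0,
              peaks$cross_condition_overlap <= 1,
              peaks$n_conditions %in% c(1L, 2L),
              peaks$promoter_link_fraction >= 0,
              peaks$promoter_link_fraction <= 1,
              peaks$len_min >= 2 * peaks$jitter + 10)
  })
  structure(cfg, class = "sim_config")
}

# Background genome with no GG or CC dinucleotide, so the scanner's
# false-positive rate outside planted sites is structurally zero.
.sample_background_chrom <- function(len) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, len, replace = TRUE)
  repeat {
    prev <- c("", s[-len])
    viol <- which(s == prev & s %in% c("C", "G"))
    if (!length(viol)) break
    s[viol] <- sample(bases, length(viol), replace = TRUE)
  }
  paste(s, collapse = "")
}

# One subtype-conforming PQS motif string plus its loop lengths.
.make_pqs_motif <- function(subtype, n_tracts) {
  tract_len <- if (startsWith(subtype, "G2")) 2L else 3L
  long <- endsWith(subtype, "8-12")
  loops <- sample(1:7, n_tracts - 1L, replace = TRUE)
  if (long) loops[sample.int(n_tracts - 1L, 1L)] <- sample(8:12, 1L)
  tract <- strrep("G", tract_len)
  loop_seq <- vapply(loops, function(l) {
    paste(sample(c("A", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  motif <- paste0(tract,
                  paste0(loop_seq, tract, collapse = ""))
  list(motif = motif, loops = loops, tract_len = tract_len)
}

.rand_at <- function(n) {
  paste(sample(c("A", "T"), n, replace = TRUE), collapse = "")
}

#' Plant subtype-conforming PQS motifs into a genome
#'
#' Writes exact G-tract/loop motifs of the requested subtypes at
#' non-colliding random positions and strands, with 15 bp A/T-only
#' sanitized flanks so planted sites can never merge with neighbouring
#' guanine runs. Loops are A/T-only, so each planted site is scanned
#' back as exactly one record of its subtype.
#'
#' @param genome Named \code{DNAStringSet} or character vector.
#' @param n_per_subtype Count planted per subtype (single number or
#'   named vector over \code{\link{pqs_subtypes}}).
#' @param within Optional \code{GRanges}; planting sites are drawn
#'   inside these intervals instead of genome-wide.
#' @param seed Optional seed.
#' @param n_tracts Tracts per planted motif.
#' @param flank Sanitized flank width.
#' @param max_tries Placement retries per site before erroring.
#' @return A list with \code{genome} (modified character vector) and
#'   \code{records} (a \code{GRanges} with subtype, strand, loops).
#' @export
plant_pqs <- function(genome, n_per_subtype = 100L, within = NULL,
                      seed = NULL, n_tracts = 4L, flank = 15L,
                      max_tries = 200L) {
  if (!is.character(genome)) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  lens <- nchar(genome)
  if (length(n_per_subtype) == 1L && is.null(names(n_per_subtype))) {
    n_per_subtype <- stats::setNames(rep(n_per_subtype, 4),
                                     pqs_subtypes())
  }
  # collision checks on sorted occupied spans (one pooled number line)
  offsets <- stats::setNames(
    c(0, cumsum(unname(lens) + 1))[seq_along(lens)], names(lens))
  acc_s <- numeric(0); acc_e <- numeric(0)
  collides <- function(s, e) {
    if (!length(acc_s)) return(FALSE)
    i <- findInterval(e, acc_s)
    i >= 1L && acc_e[i] >= s
  }
  with_seed(seed, {
    rows <- list()
    inserts <- list()  # per chrom: list of (start, end, string)
    for (subtype in names(n_per_subtype)) {
      for (i in seq_len(n_per_subtype[[subtype]])) {
        m <- .make_pqs_motif(subtype, n_tracts)
        strand <- sample(c("+", "-"), 1L)
        site_len <- nchar(m$motif) + 2L * flank
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          if (is.null(within)) {
            chrom <- sample(names(genome), 1L, prob = lens)
            if (lens[[chrom]] < site_len) next
            start <- sample.int(lens[[chrom]] - site_len + 1L, 1L)
          } else {
            j <- sample.int(length(within), 1L,
                            prob = GenomicRanges::width(within))
            chrom <- as.character(GenomicRanges::seqnames(within))[j]
            room <- GenomicRanges::width(within)[j] - site_len
            if (room < 0) next
            start <- GenomicRanges::start(within)[j] +
              sample.int(room + 1L, 1L) - 1L
          }
          ps <- start + offsets[[chrom]]
          pe <- ps + site_len - 1L
          if (collides(ps, pe)) next
          acc_s <- c(acc_s, ps); acc_e <- c(acc_e, pe)
          o <- order(acc_s)
          acc_s <- acc_s[o]; acc_e <- acc_e[o]
          ins <- paste0(.rand_at(flank),
                        if (strand == "+") m$motif else
                          as.character(Biostrings::reverseComplement(
                            Biostrings::DNAString(m$motif))),
                        .rand_at(flank))
          inserts[[length(inserts) + 1L]] <- list(
            chrom = chrom, start = start,
            end = start + site_len - 1L, string = ins)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom,
            start = start + flank,
            end = start + flank + nchar(m$motif) - 1L,
            strand = strand, subtype = subtype,
            tract_len = m$tract_len,
            loops = paste(m$loops, collapse = ","))
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place a ", subtype, " site after ",
               max_tries, " tries")
        }
      }
    }
    # apply all insertions per chromosome in one reconstruction pass
    if (length(inserts)) {
      ins_chrom <- vapply(inserts, `[[`, character(1), "chrom")
      for (chrom in unique(ins_chrom)) {
        sub <- inserts[ins_chrom == chrom]
        ord <- order(vapply(sub, `[[`, numeric(1), "start"))
        sub <- sub[ord]
        starts <- vapply(sub, `[[`, numeric(1), "start")
        ends <- vapply(sub, `[[`, numeric(1), "end")
        gap_from <- c(1, ends + 1)
        gap_to <- c(starts - 1, lens[[chrom]])
        gaps <- substring(genome[[chrom]], gap_from, gap_to)
        pieces <- character(2L * length(sub) + 1L)
        pieces[seq(1, length(pieces), by = 2)] <- gaps
        pieces[seq(2, length(pieces), by = 2)] <-
          vapply(sub, `[[`, character(1), "string")
        genome[[chrom]] <- paste(pieces, collapse = "")
      }
    }
    rec <- do.call(rbind, rows)
    records <- if (is.null(rec)) GenomicRanges::GRanges() else
      GenomicRanges::GRanges(rec$chrom,
                             IRanges::IRanges(rec$start, rec$end),
                             strand = rec$strand,
                             subtype = rec$subtype,
                             tract_len = rec$tract_len,
                             loops = rec$loops)
    list(genome = genome, records = records)
  })
}

# Random gene layout: non-overlapping territories with room for
# promoter and downstream windows, random strands, exon/intron
# structure and edge UTRs.
.make_genes <- function(cfg, chrom_sizes) {
  n <- cfg$n_genes
  if (n == 0L) {
    g <- GenomicRanges::GRanges()
    g$gene_id <- character(0); g$is_TE_gene <- logical(0)
    return(gene_models(genes = g, exons = GenomicRanges::GRangesList()))
  }
  margin <- 1200L
  per_chrom <- diff(round(seq(0, n, length.out = length(chrom_sizes) +
                                1)))
  rows <- list(); exon_l <- list(); utr5_l <- list(); utr3_l <- list()
  gid <- 0L
  for (ci in seq_along(chrom_sizes)) {
    chrom <- names(chrom_sizes)[ci]
    k <- per_chrom[ci]
    if (k == 0L) next
    glen <- sample(seq(cfg$gene_len_range[1], cfg$gene_len_range[2]),
                   k, replace = TRUE)
    terr <- glen + 2L * margin
    slack <- chrom_sizes[[ci]] - sum(terr)
    if (slack <= 0) stop("infeasible gene packing on ", chrom)
    cuts <- sort(stats::runif(k, 0, slack))
    tstart <- round(cuts) + cumsum(c(0, terr[-k])) + 1
    gstart <- tstart + margin
    gend <- gstart + glen - 1
    strand <- sample(c("+", "-"), k, replace = TRUE)
    for (j in seq_len(k)) {
      gid <- gid + 1L
      id <- sprintf("gene_%04d", gid)
      n_ex <- sample(seq(cfg$exon_count_range[1],
                         cfg$exon_count_range[2]), 1L)
      # split the span into alternating exon/intron blocks
      if (n_ex == 1L) {
        ex_s <- gstart[j]; ex_e <- gend[j]
      } else {
        inner <- sort(sample(seq(gstart[j] + 50, gend[j] - 50),
                             2L * (n_ex - 1L)))
        ex_s <- c(gstart[j], inner[seq(2, length(inner), by = 2)] + 1)
        ex_e <- c(inner[seq(1, length(inner), by = 2)], gend[j])
      }
      exon_l[[id]] <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(ex_s, ex_e))
      first_len <- ex_e[1] - ex_s[1] + 1
      last_len <- ex_e[n_ex] - ex_s[n_ex] + 1
      u5 <- min(cfg$utr5_len, first_len %/% 2)
      u3 <- min(cfg$utr3_len, last_len %/% 2)
      if (strand[j] == "+") {
        utr5_l[[id]] <- GenomicRanges::GRanges(
          chrom, IRanges::IRanges(ex_s[1], ex_s[1] + u5 - 1))
        utr3_l[[id]] <- GenomicRanges::GRanges(
          chrom, IRanges::IRanges(ex_e[n_ex] - u3 + 1, ex_e[n_ex]))
      } else {
        utr5_l[[id]] <- GenomicRanges::GRanges(
          chrom, IRanges::IRanges(ex_e[n_ex] - u5 + 1, ex_e[n_ex]))
        utr3_l[[id]] <- GenomicRanges::GRanges(
          chrom, IRanges::IRanges(ex_s[1], ex_s[1] + u3 - 1))
      }
      rows[[id]] <- data.frame(chrom = chrom, start = gstart[j],
                               end = gend[j], strand = strand[j],
                               gene_id = id)
    }
  }
  tab <- do.call(rbind, rows)
  genes <- GenomicRanges::GRanges(tab$chrom,
                                  IRanges::IRanges(tab$start, tab$end),
                                  strand = tab$strand)
  genes$gene_id <- tab$gene_id
  genes$is_TE_gene <- stats::runif(length(genes)) < cfg$te_fraction
  gene_models(genes = genes,
              exons = GenomicRanges::GRangesList(exon_l[tab$gene_id]),
              utr5 = GenomicRanges::GRangesList(utr5_l[tab$gene_id]),
              utr3 = GenomicRanges::GRangesList(utr3_l[tab$gene_id]))
}

# Vectorized midpoint sampler honoring the compartment fold targets
# (p_cat = fold * bp-share, remainder spread over unbiased categories
# proportionally to their share). Returns a function(k) giving k
# midpoints as a data.frame(chrom, pos).
.compartment_sampler <- function(partition, compartment_fold) {
  shares <- partition_shares(partition)
  probs <- shares
  if (!is.null(compartment_fold)) {
    for (cat in names(compartment_fold)) {
      probs[cat] <- compartment_fold[[cat]] * shares[cat]
    }
    rest <- setdiff(names(shares), names(compartment_fold))
    probs[rest] <- shares[rest] *
      (1 - sum(probs[names(compartment_fold)])) / sum(shares[rest])
    if (any(probs < 0) || sum(probs) > 1 + 1e-9) {
      stop("compartment_fold targets are infeasible")
    }
  }
  cats <- names(probs)
  terr <- partition$categories
  widths <- lapply(terr, GenomicRanges::width)
  # categories are drawn once per anchor and kept fixed across
  # placement retries, so rejection sampling cannot drift the planted
  # compartment distribution away from its target
  list(
    draw_categories = function(k) {
      sample(cats, k, replace = TRUE, prob = probs)
    },
    draw_positions = function(cat_draw) {
      k <- length(cat_draw)
      chrom <- character(k); pos <- numeric(k)
      for (cat in unique(cat_draw)) {
        sel <- which(cat_draw == cat)
        j <- sample.int(length(terr[[cat]]), length(sel),
                        replace = TRUE, prob = widths[[cat]])
        off <- floor(stats::runif(length(sel)) * widths[[cat]][j])
        chrom[sel] <- as.character(
          GenomicRanges::seqnames(terr[[cat]]))[j]
        pos[sel] <- GenomicRanges::start(terr[[cat]])[j] + off
      }
      data.frame(chrom = chrom, pos = pos)
    }
  )
}

# Place `n` non-overlapping anchors (with min_gap spacing) by batched
# rejection sampling of midpoints from `sampler`. `state` carries the
# already-occupied territory on a pooled number line and is updated by
# reference (environment with sorted acc_s/acc_e and chrom offsets).
.place_anchors <- function(n, lens_bp, chrom_sizes, state, sampler,
                           min_gap, max_rounds = 500L) {
  if (n == 0L) {
    return(GenomicRanges::GRanges())
  }
  offsets <- state$offsets
  placed <- rep(FALSE, n)
  out_pos <- numeric(n)
  anchor_cat <- sampler$draw_categories(n)
  hits_sorted <- function(s, e) {
    if (length(state$acc_s) == 0L) return(rep(FALSE, length(s)))
    i <- findInterval(e, state$acc_s)
    i >= 1L & state$acc_e[pmax(i, 1L)] >= s
  }
  for (round in seq_len(max_rounds)) {
    todo <- which(!placed)
    if (!length(todo)) break
    mid <- sampler$draw_positions(anchor_cat[todo])
    len <- lens_bp[todo]
    start <- mid$pos - floor(len / 2)
    end <- start + len - 1
    L <- chrom_sizes[mid$chrom]
    keep <- start >= 1 & end <= L
    o <- unname(offsets[mid$chrom])
    ps <- start + o - min_gap
    pe <- end + o + min_gap
    keep <- keep & !hits_sorted(ps, pe)
    sel <- which(keep)
    if (length(sel) > 1L) {
      ord <- sel[order(ps[sel])]
      last_end <- -Inf
      for (j in ord) {
        if (ps[j] > last_end) last_end <- pe[j] else keep[j] <- FALSE
      }
    }
    idx <- todo[keep]
    placed[idx] <- TRUE
    out_pos[idx] <- start[keep] + o[keep]
    if (length(idx)) {
      state$acc_s <- c(state$acc_s, ps[keep])
      state$acc_e <- c(state$acc_e, pe[keep])
      so <- order(state$acc_s)
      state$acc_s <- state$acc_s[so]
      state$acc_e <- state$acc_e[so]
    }
  }
  if (!all(placed)) {
    stop("infeasible peak packing: ", sum(!placed),
         " anchor(s) unplaced after ", max_rounds, " rounds")
  }
  ci <- findInterval(out_pos, unname(offsets))
  GenomicRanges::GRanges(
    names(chrom_sizes)[ci],
    IRanges::IRanges(out_pos - unname(offsets)[ci], width = lens_bp))
}

# Fresh placement state for .place_anchors.
.placement_state <- function(chrom_sizes) {
  st <- new.env(parent = emptyenv())
  off <- c(0, cumsum(unname(chrom_sizes) + 2 * 100 + 1))
  st$offsets <- stats::setNames(off[seq_along(chrom_sizes)],
                                names(chrom_sizes))
  st$acc_s <- numeric(0)
  st$acc_e <- numeric(0)
  st
}

# Reserve a span (1-based chrom coordinates) in the placement state.
.reserve_span <- function(state, chrom, start, end) {
  o <- unname(state$offsets[chrom])
  state$acc_s <- c(state$acc_s, start + o)
  state$acc_e <- c(state$acc_e, end + o)
  so <- order(state$acc_s)
  state$acc_s <- state$acc_s[so]
  state$acc_e <- state$acc_e[so]
  invisible(state)
}

.jitter_peaks <- function(gr, jitter, chrom_sizes) {
  shift <- sample(seq(-jitter, jitter), length(gr), replace = TRUE)
  s <- GenomicRanges::start(gr) + shift
  L <- chrom_sizes[as.character(GenomicRanges::seqnames(gr))]
  s <- pmax(1, pmin(s, L - GenomicRanges::width(gr) + 1))
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::IRanges(s, width = GenomicRanges::width(gr)))
}

.np_mcols <- function(gr, prefix) {
  n <- length(gr)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("%s_%d", prefix, seq_len(n)),
    score = round(stats::runif(n, 100, 1000)),
    signalValue = round(stats::runif(n, 2, 20), 3),
    pValue = round(stats::runif(n, 3, 30), 3),
    qValue = round(stats::runif(n, 2, 20), 3),
    peak = floor(GenomicRanges::width(gr) / 2))
  gr
}

#' Generate a complete synthetic dataset with a truth manifest
#'
#' Emits an internally consistent toy dataset exercising every pipeline
#' stage: genome FASTA (PQS-suppressed background with planted PQS
#' motifs), GFF3 gene annotation, chrom.sizes, narrowPeak files
#' (conditions x replicates with constructively realized replicate and
#' cross-condition overlap fractions), a per-cytosine methylation
#' report, one bedGraph per configured signal track, an expression
#' table and a machine-readable truth manifest. Fully deterministic
#' given (config, seed).
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param write_files Write the file bundle (otherwise only in-memory
#'   objects and the manifest are returned).
#' @return A list with \code{paths}, \code{manifest} and
#'   \code{objects} (genome, gene models, peak \code{GRanges} sets,
#'   planted PQS records, chrom sizes).
#' @export
generate_dataset <- function(config = sim_config(), dir = tempfile(),
                             seed = 1L, write_files = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (write_files && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  cfg <- config
  with_seed(seed, {
    chrom_sizes <- stats::setNames(rep(cfg$chrom_len, cfg$n_chroms),
                                   sprintf("chr%d", seq_len(cfg$n_chroms)))
    genome <- vapply(chrom_sizes, .sample_background_chrom, character(1))

    models <- .make_genes(cfg, chrom_sizes)
    partition <- build_partition(models, chrom_sizes)

    planted <- plant_pqs(genome, cfg$pqs$n_per_subtype,
                         n_tracts = cfg$pqs$n_tracts)
    genome <- planted$genome

    ## ---- peaks: anchors by role, realized constructively ----
    pk <- cfg$peaks
    n <- as.integer(pk$n_per_condition)
    n_rep <- as.integer(round(n * pk$replicate_overlap))
    n_rep_only <- n - n_rep
    two_cond <- pk$n_conditions == 2L
    if (two_cond) {
      n_common <- as.integer(round(n_rep * pk$cross_condition_overlap))
      n_spec <- n_rep - n_common
      roles <- c(rep("common", n_common),
                 rep("a_specific", n_spec), rep("b_specific", n_spec),
                 rep("a_rep1", n_rep_only), rep("a_rep2", n_rep_only),
                 rep("b_rep1", n_rep_only), rep("b_rep2", n_rep_only))
    } else {
      n_common <- 0L; n_spec <- n_rep
      roles <- c(rep("a_specific", n_spec),
                 rep("a_rep1", n_rep_only), rep("a_rep2", n_rep_only))
    }
    n_anchor <- length(roles)
    lens_bp <- pmax(pk$len_min,
                    round(stats::rnorm(n_anchor, pk$len_mean,
                                       pk$len_sd)))
    if (sum(lens_bp + 2 * pk$min_gap) >= sum(chrom_sizes)) {
      stop("infeasible peak packing for this genome size")
    }
    state <- .placement_state(chrom_sizes)
    sampler <- .compartment_sampler(partition, pk$compartment_fold)
    # promoter-linked a-specific anchors come first
    n_link <- round(pk$promoter_link_fraction * cfg$n_genes)
    linked_genes <- character(0)
    link_anchors <- GenomicRanges::GRanges()
    if (n_link > 0) {
      if (n_link > n_spec) {
        stop("promoter_link_fraction requires more a-specific peaks ",
             "than configured")
      }
      gsel <- sample(seq_along(models$genes), n_link)
      linked_genes <- models$genes$gene_id[gsel]
      prom <- .promoter_regions(models$genes[gsel],
                                partition$promoter_len, chrom_sizes)
      lchrom <- character(n_link); lstart <- numeric(n_link)
      for (i in seq_len(n_link)) {
        len <- lens_bp[i]
        room <- GenomicRanges::width(prom)[i] - len
        if (room < 0) stop("promoter too small for a linked peak")
        start <- GenomicRanges::start(prom)[i] +
          sample.int(room + 1L, 1L) - 1L
        chrom <- as.character(GenomicRanges::seqnames(prom))[i]
        .reserve_span(state, chrom, start - pk$min_gap,
                      start + len - 1 + pk$min_gap)
        lchrom[i] <- chrom; lstart[i] <- start
      }
      link_anchors <- GenomicRanges::GRanges(
        lchrom, IRanges::IRanges(lstart,
                                 width = lens_bp[seq_len(n_link)]))
    }
    rest <- .place_anchors(n_anchor - n_link,
                           lens_bp[seq_len(n_anchor - n_link) + n_link],
                           chrom_sizes, state, sampler, pk$min_gap)
    anchors <- if (length(link_anchors)) {
      suppressWarnings(c(link_anchors, rest))
    } else {
      rest
    }
    # promoter-linked anchors are a-specific: order roles accordingly
    role_order <- c(rep("a_specific", n_link),
                    roles[roles != "a_specific"],
                    rep("a_specific", n_spec - n_link))
    anchors$role <- role_order
    anchors$linked_gene <- c(linked_genes,
                             rep(NA_character_, n_anchor - n_link))

    by_role <- function(r) anchors[anchors$role %in% r]
    peak_sets <- list()
    peak_sets[["a_rep1"]] <- .np_mcols(
      c(GenomicRanges::granges(by_role(c("common", "a_specific"))),
        GenomicRanges::granges(by_role("a_rep1"))), "pkA1")
    peak_sets[["a_rep2"]] <- .np_mcols(
      c(.jitter_peaks(by_role(c("common", "a_specific")), pk$jitter,
                      chrom_sizes),
        GenomicRanges::granges(by_role("a_rep2"))), "pkA2")
    if (two_cond) {
      peak_sets[["b_rep1"]] <- .np_mcols(
        c(.jitter_peaks(by_role("common"), pk$jitter, chrom_sizes),
          GenomicRanges::granges(by_role("b_specific")),
          GenomicRanges::granges(by_role("b_rep1"))), "pkB1")
      peak_sets[["b_rep2"]] <- .np_mcols(
        c(.jitter_peaks(by_role("common"), pk$jitter, chrom_sizes),
          .jitter_peaks(by_role("b_specific"), pk$jitter, chrom_sizes),
          GenomicRanges::granges(by_role("b_rep2"))), "pkB2")
    }
    all_peaks <- GenomicRanges::reduce(
      do.call(c, lapply(unname(peak_sets), GenomicRanges::granges)),
      ignore.strand = TRUE)

    ## ---- methylation: per-cytosine report ----
    meth_cfg <- cfg$methylation
    meth_dt <- if ("methylation" %in% cfg$components) {
      .simulate_methylation(genome, all_peaks, meth_cfg)
    }

    ## ---- signal tracks ----
    class_mids <- function(peak_class) {
      sel <- switch(peak_class,
        all = anchors,
        common = by_role("common"),
        a_specific = by_role("a_specific"),
        b_specific = by_role("b_specific"),
        stop("unknown peak_class: ", peak_class))
      sel
    }
    tracks <- if ("signal" %in% cfg$components) {
      lapply(cfg$signal, function(tr) {
        .simulate_track(chrom_sizes, class_mids(tr$peak_class), tr)
      })
    } else {
      list()
    }

    ## ---- expression ----
    ex <- cfg$expression
    n_genes <- length(models$genes)
    expr <- NULL
    boosted <- rep(FALSE, n_genes)
    if ("expression" %in% cfg$components) {
      fpkm <- ifelse(stats::runif(n_genes) < ex$nonexpressed_fraction,
                     0,
                     round(stats::rlnorm(n_genes, ex$meanlog,
                                         ex$sdlog), 3))
      if (n_genes > 0 && length(by_role("a_specific"))) {
        prom <- GenomicRanges::promoters(
          models$genes, upstream = partition$promoter_len,
          downstream = 0)
        boosted <- IRanges::overlapsAny(prom, by_role("a_specific"),
                                        ignore.strand = TRUE)
        fpkm[boosted] <- round(fpkm[boosted] *
                                 ex$promoter_peak_multiplier, 3)
      }
      expr <- data.frame(gene_id = models$genes$gene_id, fpkm = fpkm,
                         is_TE = models$genes$is_TE_gene)
    }

    ## ---- manifest and files ----
    manifest <- list(
      seed = seed,
      chrom_sizes = as.list(chrom_sizes),
      n_genes = n_genes,
      pqs = as.data.frame(planted$records),
      peak_counts = list(
        n_per_condition = n, n_reproducible = n_rep,
        n_common = n_common, n_a_specific = n_spec,
        n_b_specific = if (two_cond) n_spec else 0L,
        replicate_overlap = n_rep / n,
        cross_condition_overlap = if (n_rep > 0) n_common / n_rep else 0),
      anchors = as.data.frame(anchors),
      methylation = list(levels = meth_cfg$levels,
                         coverage_mean = meth_cfg$coverage_mean,
                         region_definition = "union of all peak files"),
      expression = list(boosted_genes =
                          models$genes$gene_id[boosted],
                        multiplier = ex$promoter_peak_multiplier),
      promoter_linked_genes = linked_genes,
      condition_labels = cfg$condition_labels
    )

    paths <- list()
    if (write_files) {
      paths$fasta <- file.path(dir, "genome.fa")
      write_fasta(genome, paths$fasta)
      paths$chrom_sizes <- file.path(dir, "genome.chrom.sizes")
      write_chrom_sizes(chrom_sizes, paths$chrom_sizes)
      paths$gff3 <- file.path(dir, "genes.gff3")
      write_gff3_genes(models, paths$gff3)
      lab <- cfg$condition_labels
      fname <- c(a_rep1 = sprintf("peaks_%s_rep1.narrowPeak", lab[1]),
                 a_rep2 = sprintf("peaks_%s_rep2.narrowPeak", lab[1]),
                 b_rep1 = sprintf("peaks_%s_rep1.narrowPeak", lab[2]),
                 b_rep2 = sprintf("peaks_%s_rep2.narrowPeak", lab[2]))
      for (k in names(peak_sets)) {
        paths[[k]] <- file.path(dir, fname[[k]])
        write_intervals(peak_sets[[k]], paths[[k]],
                        format = "narrowPeak")
      }
      if (!is.null(meth_dt)) {
        paths$cytosine_report <- file.path(dir, "cytosine_report.tsv")
        data.table::fwrite(meth_dt, paths$cytosine_report, sep = "\t",
                           col.names = FALSE)
      }
      for (tn in names(tracks)) {
        paths[[paste0("track_", tn)]] <- file.path(
          dir, paste0(tn, ".bedGraph"))
        write_bedgraph(tracks[[tn]], paths[[paste0("track_", tn)]])
      }
      if (!is.null(expr)) {
        paths$expression <- file.path(dir, "expression.tsv")
        utils::write.table(expr, paths$expression, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      paths$manifest <- file.path(dir, "manifest.json")
      jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    meth_gr <- if (!is.null(meth_dt)) {
      GenomicRanges::GRanges(
        meth_dt$chrom, IRanges::IRanges(meth_dt$pos, meth_dt$pos),
        strand = meth_dt$strand,
        meth_count = as.integer(meth_dt$meth),
        total_count = as.integer(meth_dt$meth + meth_dt$unmeth),
        context = meth_dt$context)
    }
    list(paths = paths, manifest = manifest,
         objects = list(genome = Biostrings::DNAStringSet(genome),
                        chrom_sizes = chrom_sizes,
                        models = models, partition = partition,
                        pqs = planted$records,
                        anchors = anchors, peak_sets = peak_sets,
                        methylation = meth_gr,
                        tracks = tracks, expression = expr))
  })
}

# Per-cytosine simulated report: every C (both strands) of the genome
# with context from the sequence, Beta-Binomial methylation at the
# peak or background level, Poisson coverage.
.simulate_methylation <- function(genome, peak_union, meth_cfg) {
  out <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    L <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    plus <- which(ch == "C")
    plus <- plus[plus <= L - 2L]
    minus <- which(ch == "G")
    minus <- minus[minus >= 3L]
    ctx_plus <- ifelse(ch[plus + 1L] == "G", "CG",
                       ifelse(ch[plus + 2L] == "G", "CHG", "CHH"))
    ctx_minus <- ifelse(ch[minus - 1L] == "C", "CG",
                        ifelse(ch[minus - 2L] == "C", "CHG", "CHH"))
    pos <- c(plus, minus)
    strand <- rep(c("+", "-"), c(length(plus), length(minus)))
    context <- c(ctx_plus, ctx_minus)
    ord <- order(pos)
    pos <- pos[ord]; strand <- strand[ord]; context <- context[ord]
    sel <- peak_union[GenomicRanges::seqnames(peak_union) == chrom]
    inpeak <- IRanges::overlapsAny(
      IRanges::IRanges(pos, pos), GenomicRanges::ranges(sel))
    lv <- numeric(length(pos))
    for (ctx in names(meth_cfg$levels)) {
      m <- context == ctx
      lv[m & inpeak] <- meth_cfg$levels[[ctx]][["peak"]]
      lv[m & !inpeak] <- meth_cfg$levels[[ctx]][["background"]]
    }
    k <- meth_cfg$beta_concentration
    site_lv <- stats::rbeta(length(pos), lv * k, (1 - lv) * k)
    cov <- stats::rpois(length(pos), meth_cfg$coverage_mean)
    meth <- stats::rbinom(length(pos), cov, site_lv)
    out[[chrom]] <- data.table::data.table(
      chrom = chrom, pos = pos, strand = strand, meth = meth,
      unmeth = cov - meth, context = context)
  }
  data.table::rbindlist(out)
}

# Gaussian coverage bumps at region midpoints on a fixed grid.
.simulate_track <- function(chrom_sizes, regions, tr, grid = 20L) {
  out <- list()
  for (chrom in names(chrom_sizes)) {
    L <- chrom_sizes[[chrom]]
    nbin <- ceiling(L / grid)
    centers <- (seq_len(nbin) - 0.5) * grid
    v <- rep(tr$background, nbin)
    sel <- regions[as.character(GenomicRanges::seqnames(regions)) ==
                     chrom]
    if (length(sel)) {
      mids <- interval_midpoint(sel) - 0.5
      reach <- ceiling(4 * tr$sigma / grid)
      for (m in mids) {
        j0 <- max(1L, floor(m / grid) - reach)
        j1 <- min(nbin, floor(m / grid) + reach)
        j <- j0:j1
        v[j] <- v[j] + tr$amplitude *
          exp(-((centers[j] - m)^2) / (2 * tr$sigma^2))
      }
    }
    starts <- (seq_len(nbin) - 1L) * grid + 1
    ends <- pmin(seq_len(nbin) * grid, L)
    out[[chrom]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts, ends), score = round(v, 4))
  }
  suppressWarnings(do.call(c, unname(out)))
}
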