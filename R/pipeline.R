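#' Run the full analysis pipeline end to end
#'
#' Orchestrates every stage on a synthetic bundle: simulate, read all
#' files back through the package's own readers, scan PQSs, derive
#' reproducible and condition-specific peaks, annotate them against the
#' seven-category subgenomic partition, compute shuffle-null fold
#' enrichments, sequence-composition, signal and methylation profiles,
#' and the expression association, then write a single JSON report of
#' every table a study of cation-favorable G4 landscapes builds its
#' figures from. Deterministic: the same (config, seed) produces a
#' byte-identical report.
#'
#' @param out_dir Output directory (simulated inputs under
#'   \code{<out_dir>/sim}, report at \code{<out_dir>/report.json}).
#' @param seed Integer master seed for every stochastic stage.
#' @param config A \code{\link{sim_config}} for the simulated inputs.
#' @param n_subgenomic Randomizations for subgenomic fold enrichment.
#' @param n_pqs Randomizations for PQS fold enrichment.
#' @param write_report Write \code{report.json}.
#' @return Invisibly, a list with \code{report} and \code{paths}.
#' @export
run_g4_pipeline <- function(out_dir, seed = 1L, config = sim_config(),
                            n_subgenomic = 3L, n_pqs = 100L,
                            write_report = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- generate_dataset(config, file.path(out_dir, "sim"),
                          seed = seed)
  p <- sim$paths
  lab <- config$condition_labels
  two_cond <- config$peaks$n_conditions == 2L

  ## stage: read everything back through the package readers
  genome <- read_fasta(p$fasta)
  chrom_sizes <- read_chrom_sizes(p$chrom_sizes)
  models <- read_gff3_genes(p$gff3)
  reps <- lapply(p[intersect(c("a_rep1", "a_rep2", "b_rep1", "b_rep2"),
                             names(p))],
                 read_intervals, format = "narrowPeak",
                 chrom_sizes = chrom_sizes)
  meth <- read_cytosine_report(p$cytosine_report)
  track_paths <- p[startsWith(names(p), "track_")]
  tracks <- lapply(track_paths, read_bedgraph)
  names(tracks) <- sub("^track_", "", names(track_paths))
  expr <- read_expression_table(p$expression)

  ## stage: PQS scan
  pqs <- scan_pqs(genome)

  ## stage: peak-set operations
  rep_a <- reproducible_peaks(reps$a_rep1, reps$a_rep2)
  if (two_cond) {
    rep_b <- reproducible_peaks(reps$b_rep1, reps$b_rep2)
    cls <- classify_conditions(rep_a$peaks, rep_b$peaks, labels = lab)
    classes <- list(common = cls$common, a_specific = cls$a_specific,
                    b_specific = cls$b_specific)
  } else {
    cls <- NULL
    classes <- list(a_specific = rep_a$peaks)
  }
  size_stats <- lapply(classes, function(g) {
    st <- length_stats(g)
    list(n = st$n, mean = st$mean, median = st$median)
  })
  for (cl in names(classes)) {
    write_intervals(GenomicRanges::granges(classes[[cl]]),
                    file.path(out_dir, paste0("peaks_", cl, ".bed")),
                    format = "BED3")
  }

  ## stage: subgenomic annotation and enrichment
  partition <- build_partition(models, chrom_sizes)
  assignment <- lapply(classes, function(g) assign_peaks(g,
                                                         partition)$table)
  sub_fold <- lapply(seq_along(classes), function(i) {
    subgenomic_fold(classes[[i]], partition, n = n_subgenomic,
                    seed = seed + 1000L + i)
  })
  names(sub_fold) <- names(classes)

  ## stage: PQS content and fold enrichment per peak class
  content <- lapply(classes, function(g) pqs_content(g, pqs))
  pq_fold <- lapply(seq_along(classes), function(i) {
    pqs_fold(classes[[i]], chrom_sizes = chrom_sizes, pqs = pqs,
             n = n_pqs, seed = seed + 2000L + i)
  })
  names(pq_fold) <- names(classes)

  ## stage: sequence-composition profiles
  comp <- lapply(classes, function(g) {
    lapply(c(gc_content = "gc_content", gc_skew = "gc_skew",
             at_skew = "at_skew"), function(st) {
      round(composition_profile(g, genome, st)$values, 6)
    })
  })

  ## stage: signal and methylation profiles
  sig <- lapply(tracks, function(tr) {
    out <- lapply(classes, function(g) {
      round(center_profile(tr, g, chrom_sizes)$values, 6)
    })
    ctrl <- shuffle_intervals(classes[[1]], chrom_sizes,
                              seed = seed + 3000L)
    out$random <- round(center_profile(tr, ctrl, chrom_sizes)$values, 6)
    out
  })
  meth_prof <- lapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"),
                      function(ctx) {
    lapply(classes, function(g) {
      round(methylation_profile(meth, g, ctx, chrom_sizes)$values, 6)
    })
  })

  ## stage: expression association
  expr_classes <- classify_expression(expr)
  assoc <- lapply(classes, function(g) {
    list(promoter = overlap_genes(g, models, "promoter",
                                  chrom_sizes = chrom_sizes),
         gene_body = overlap_genes(g, models, "gene_body",
                                   chrom_sizes = chrom_sizes))
  })
  expr_assoc <- lapply(c(promoter = "promoter",
                         gene_body = "gene_body"), function(rg) {
    res <- expression_by_peak_class(
      expr, lapply(assoc, `[[`, rg))
    list(summary = res$summary, tests = res$tests)
  })
  meta <- lapply(tracks[1], function(tr) {
    lapply(metagene_profile(tr, models, expr_classes, chrom_sizes),
           function(pr) round(pr$values, 6))
  })

  strip_rv <- function(df) df[, setdiff(names(df), "random_values")]
  report <- list(
    seed = seed,
    conditions = lab,
    peaks = list(
      replicate_overlap_ratio_a = rep_a$overlap_ratio,
      replicate_overlap_ratio_b = if (two_cond) {
        reproducible_peaks(reps$b_rep1, reps$b_rep2)$overlap_ratio
      },
      class_counts = lapply(classes, length),
      size_stats = size_stats
    ),
    pqs = list(n_records = length(pqs),
               by_subtype = as.list(table(pqs$subtype)),
               content = content),
    subgenomic = list(assignment = assignment,
                      fold = lapply(sub_fold, strip_rv)),
    pqs_fold = lapply(pq_fold, strip_rv),
    composition_profiles = comp,
    signal_profiles = sig,
    methylation_profiles = meth_prof,
    expression = list(class_sizes = as.list(table(expr_classes$class)),
                      by_peak_class = expr_assoc,
                      metagene = meta)
  )
  paths <- list(sim = p)
  if (write_report) {
    paths$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE, na = "null")
  }
  invisible(list(report = report, paths = paths))
}
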