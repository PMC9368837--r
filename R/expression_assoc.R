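#' Read a gene-expression table
#'
#' Expects a TSV with header columns \code{gene_id}, \code{fpkm} and a
#' TE flag column (\code{is_TE}, values true/false or 1/0).
#'
#' @param path Path to the TSV.
#' @return A data.frame with gene_id, fpkm, is_TE_gene.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "fpkm", "is_TE")
  if (!all(need %in% names(tab))) {
    stop("expression table must have columns: ",
         paste(need, collapse = ", "))
  }
  if (any(!is.finite(tab$fpkm)) || any(tab$fpkm < 0)) {
    stop("FPKM values must be finite and non-negative")
  }
  data.frame(gene_id = as.character(tab$gene_id),
             fpkm = as.numeric(tab$fpkm),
             is_TE_gene = tolower(as.character(tab$is_TE)) %in%
               c("true", "1", "yes"))
}

#' Classify genes into expression strata
#'
#' Genes with FPKM = 0 are non-expressed; expressed genes are split
#' into low/medium/high at the empirical 1/3 and 2/3 quantiles of their
#' FPKM values (quantile type 7; values at or below a cut point fall in
#' the lower class, so ties break toward the lower class).
#'
#' @param table A data.frame with gene_id and fpkm columns.
#' @return A data.frame with gene_id and class (factor with levels non,
#'   low, medium, high).
#' @export
classify_expression <- function(table) {
  if (nrow(table) == 0L) stop("expression table is empty")
  fpkm <- table$fpkm
  cls <- rep("non", nrow(table))
  expressed <- fpkm > 0
  if (!any(expressed)) {
    warning("all genes are non-expressed")
  } else {
    q <- stats::quantile(fpkm[expressed], c(1, 2) / 3, type = 7,
                         names = FALSE)
    cls[expressed] <- ifelse(fpkm[expressed] <= q[1], "low",
                             ifelse(fpkm[expressed] <= q[2], "medium",
                                    "high"))
  }
  data.frame(gene_id = table$gene_id,
             class = factor(cls, levels = c("non", "low", "medium",
                                            "high")))
}

#' Expression of genes grouped by overlapping peak class
#'
#' Crosses each peak class' gene associations (from
#' \code{\link{overlap_genes}}) with TE status, reporting the member
#' genes' FPKM distribution (mean, median, expressed fraction) and the
#' pairwise rank-sum comparisons between peak classes within each
#' TE stratum. Genes overlapped by several peak classes are counted in
#' every matching class.
#'
#' @param expr_table A data.frame from
#'   \code{\link{read_expression_table}}.
#' @param assoc_list Named list of association data.frames (one per
#'   peak class, e.g. common / a_specific / b_specific), all for the
#'   same region.
#' @return A list with \code{summary} (one row per peak class x TE
#'   stratum), \code{tests} (pairwise rank-sum p-values) and
#'   \code{fpkm} (the grouped FPKM vectors).
#' @export
expression_by_peak_class <- function(expr_table, assoc_list) {
  stopifnot(is.list(assoc_list), !is.null(names(assoc_list)))
  fpkm_of <- stats::setNames(expr_table$fpkm, expr_table$gene_id)
  groups <- list()
  rows <- list()
  for (cls in names(assoc_list)) {
    assoc <- assoc_list[[cls]]
    for (te in c(FALSE, TRUE)) {
      ids <- assoc$gene_id[assoc$is_TE_gene == te]
      ids <- ids[ids %in% names(fpkm_of)]
      key <- paste0(cls, ".", if (te) "TEG" else "nonTEG")
      v <- unname(fpkm_of[ids])
      groups[[key]] <- v
      rows[[key]] <- data.frame(
        peak_class = cls,
        te_status = if (te) "TEG" else "nonTEG",
        n = length(v),
        mean_fpkm = if (length(v)) mean(v) else NA_real_,
        median_fpkm = if (length(v)) stats::median(v) else NA_real_,
        expressed_fraction = if (length(v)) mean(v > 0) else NA_real_
      )
    }
  }
  tests <- list()
  for (te in c("nonTEG", "TEG")) {
    keys <- paste0(names(assoc_list), ".", te)
    keys <- keys[vapply(groups[keys], length, integer(1)) > 0]
    if (length(keys) >= 2) {
      cmb <- utils::combn(keys, 2)
      for (j in seq_len(ncol(cmb))) {
        tests[[length(tests) + 1L]] <- data.frame(
          group_a = cmb[1, j], group_b = cmb[2, j],
          p_value = rank_sum(groups[[cmb[1, j]]],
                             groups[[cmb[2, j]]]))
      }
    }
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       tests = if (length(tests)) {
         do.call(rbind, tests)
       } else {
         data.frame(group_a = character(0), group_b = character(0),
                    p_value = numeric(0))
       },
       fpkm = groups)
}
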