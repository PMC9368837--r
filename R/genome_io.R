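#' Read a two-column chrom.sizes table
#'
#' @param path Path to a TSV with columns chromosome name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric"),
                           col.names = c("chrom", "length"))
  check_chrom_sizes(stats::setNames(tab$length, tab$chrom))
}

#' Write a chrom.sizes table
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  writeLines(paste(names(chrom_sizes), fmt_num(chrom_sizes), sep = "\t"),
             path)
  invisible(path)
}

.bed_ncol <- c(BED3 = 3L, BED6 = 6L, narrowPeak = 10L)

#' Read genomic intervals from BED-family files
#'
#' Parses BED3, BED6 or ENCODE narrowPeak into a \code{GRanges}. File
#' coordinates are 0-based half-open and are converted to the package's
#' internal 1-based closed \code{GRanges} convention on read
#' (\code{write_intervals} inverts the conversion). The narrowPeak summit
#' offset is retained in metadata column \code{peak}. Input order is
#' preserved.
#'
#' @param path Path to the file.
#' @param format One of \code{"BED3"}, \code{"BED6"}, \code{"narrowPeak"}.
#' @param chrom_sizes Optional named vector; when given, every interval
#'   must lie on a known chromosome within its bounds.
#' @return A \code{GRanges}; BED6/narrowPeak carry \code{name},
#'   \code{score} (and narrowPeak \code{signalValue}, \code{pValue},
#'   \code{qValue}, \code{peak}) metadata columns.
#' @export
read_intervals <- function(path, format = c("BED6", "BED3", "narrowPeak"),
                           chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^track|^browser|^#", lines)]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    return(gr)
  }
  sp <- strsplit(lines, "\t", fixed = TRUE)
  need <- .bed_ncol[[format]]
  nf <- lengths(sp)
  if (any(nf < need)) {
    bad <- which(nf < need)[1L]
    stop(sprintf("malformed %s line %d: expected >= %d fields, got %d",
                 format, bad, need, nf[bad]))
  }
  field <- function(i) vapply(sp, `[[`, character(1), i)
  chrom <- field(1)
  start0 <- suppressWarnings(as.numeric(field(2)))
  end0 <- suppressWarnings(as.numeric(field(3)))
  if (anyNA(start0) || anyNA(end0)) {
    bad <- which(is.na(start0) | is.na(end0))[1L]
    stop(sprintf("malformed %s line %d: non-numeric coordinate",
                 format, bad))
  }
  if (any(start0 >= end0)) {
    bad <- which(start0 >= end0)[1L]
    stop(sprintf("invalid interval at line %d: start (%s) >= end (%s)",
                 bad, fmt_num(start0[bad]), fmt_num(end0[bad])))
  }
  strand <- "*"
  mcols <- S4Vectors::DataFrame()
  if (format %in% c("BED6", "narrowPeak")) {
    name <- field(4)
    score <- suppressWarnings(as.numeric(field(5)))
    score[field(5) == "."] <- NA_real_
    strand <- field(6)
    if (any(!strand %in% c("+", "-", "."))) {
      bad <- which(!strand %in% c("+", "-", "."))[1L]
      stop(sprintf("malformed strand at line %d: '%s'", bad, strand[bad]))
    }
    strand[strand == "."] <- "*"
    mcols <- S4Vectors::DataFrame(name = name, score = score)
  }
  if (format == "narrowPeak") {
    mcols$signalValue <- suppressWarnings(as.numeric(field(7)))
    mcols$pValue <- suppressWarnings(as.numeric(field(8)))
    mcols$qValue <- suppressWarnings(as.numeric(field(9)))
    mcols$peak <- suppressWarnings(as.numeric(field(10)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand
  )
  if (format != "BED3") S4Vectors::mcols(gr) <- mcols
  if (!is.null(chrom_sizes)) {
    check_on_genome(gr, chrom_sizes, what = "peak/interval")
  }
  gr
}

#' Write genomic intervals to a BED-family file
#'
#' Inverts \code{\link{read_intervals}}: internal 1-based closed
#' coordinates are emitted as 0-based half-open.
#'
#' @param gr A \code{GRanges}.
#' @param path Output path.
#' @param format One of \code{"BED3"}, \code{"BED6"}, \code{"narrowPeak"}.
#' @export
write_intervals <- function(gr, path,
                            format = c("BED6", "BED3", "narrowPeak")) {
  format <- match.arg(format)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- fmt_num(GenomicRanges::start(gr) - 1)
  end0 <- fmt_num(GenomicRanges::end(gr))
  if (format == "BED3") {
    writeLines(paste(chrom, start0, end0, sep = "\t"), path)
    return(invisible(path))
  }
  mc <- S4Vectors::mcols(gr)
  name <- if ("name" %in% names(mc)) as.character(mc$name) else
    rep(".", length(gr))
  score <- if ("score" %in% names(mc)) fmt_num(mc$score) else
    rep("0", length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  base <- paste(chrom, start0, end0, name, score, strand, sep = "\t")
  if (format == "BED6") {
    writeLines(base, path)
    return(invisible(path))
  }
  getcol <- function(col, default) {
    if (col %in% names(mc)) fmt_num(mc[[col]]) else
      rep(default, length(gr))
  }
  writeLines(paste(base,
                   getcol("signalValue", "0"),
                   getcol("pValue", "-1"),
                   getcol("qValue", "-1"),
                   getcol("peak", "-1"),
                   sep = "\t"), path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A \code{DNAStringSet} named by the first word of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("FASTA with duplicate headers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs A named \code{DNAStringSet} or named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a bedGraph file (0-based half-open runs).
#' @param chrom_sizes Optional named vector for bounds checking.
#' @return A \code{GRanges} with metadata column \code{score}, sorted,
#'   with non-overlapping runs per chromosome.
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^track|^browser|^#", lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges(score = numeric()))
  sp <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(sp)
  if (any(nf < 4L)) {
    bad <- which(nf < 4L)[1L]
    stop(sprintf("malformed bedGraph line %d: expected 4 fields", bad))
  }
  chrom <- vapply(sp, `[[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(sp, `[[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(sp, `[[`, character(1), 3)))
  value <- suppressWarnings(as.numeric(vapply(sp, `[[`, character(1), 4)))
  if (anyNA(start0) || anyNA(end0) || anyNA(value)) {
    bad <- which(is.na(start0) | is.na(end0) | is.na(value))[1L]
    stop(sprintf("malformed bedGraph line %d: non-numeric field", bad))
  }
  if (any(start0 >= end0)) {
    bad <- which(start0 >= end0)[1L]
    stop(sprintf("invalid bedGraph run at line %d: start >= end", bad))
  }
  if (any(!is.finite(value))) stop("bedGraph values must be finite")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               score = value)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE,
                                      ignore.strand = TRUE)
  if (length(hits) > 0L) {
    stop("overlapping bedGraph runs detected (first pair of rows after ",
         "sorting: ", S4Vectors::queryHits(hits)[1L], ", ",
         S4Vectors::subjectHits(hits)[1L], ")")
  }
  if (!is.null(chrom_sizes)) check_on_genome(gr, chrom_sizes,
                                             what = "bedGraph run")
  gr
}

#' Write a signal track to bedGraph
#'
#' @param track A \code{GRanges} with a \code{score} metadata column.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot("score" %in% names(S4Vectors::mcols(track)))
  writeLines(paste(as.character(GenomicRanges::seqnames(track)),
                   fmt_num(GenomicRanges::start(track) - 1),
                   fmt_num(GenomicRanges::end(track)),
                   fmt_num(track$score), sep = "\t"), path)
  invisible(path)
}

#' Read a Bismark-style per-cytosine report
#'
#' Expects the cytosine-report dialect: chromosome, 1-based position,
#' strand, methylated count, unmethylated count, context (CG/CHG/CHH),
#' optionally the trinucleotide. Methylation level of a record is
#' meth / (meth + unmeth), the C/(C+T) ratio of bisulfite calls.
#'
#' @param path Path to the TSV (no header).
#' @param chrom_sizes Optional named vector for bounds checking.
#' @return A width-1 \code{GRanges} with metadata columns
#'   \code{meth_count}, \code{total_count}, \code{context}.
#' @export
read_cytosine_report <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, header = FALSE, sep = "\t",
                           showProgress = FALSE)
  if (nrow(tab) == 0L) {
    return(GenomicRanges::GRanges(meth_count = integer(),
                                  total_count = integer(),
                                  context = character()))
  }
  if (ncol(tab) < 6L) {
    stop("cytosine report must have >= 6 columns ",
         "(chrom, pos, strand, meth, unmeth, context)")
  }
  chrom <- as.character(tab[[1]])
  pos <- tab[[2]]
  strand <- as.character(tab[[3]])
  meth <- tab[[4]]
  unmeth <- tab[[5]]
  context <- as.character(tab[[6]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop(sprintf("invalid strand at line %d", bad[1L]))
  bad <- which(!context %in% c("CG", "CHG", "CHH"))
  if (length(bad)) {
    stop(sprintf("invalid context '%s' at line %d", context[bad[1L]],
                 bad[1L]))
  }
  bad <- which(!is.finite(meth) | !is.finite(unmeth) | meth < 0 |
                 unmeth < 0 | meth != round(meth) | unmeth != round(unmeth))
  if (length(bad)) stop(sprintf("invalid counts at line %d", bad[1L]))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                               strand = strand,
                               meth_count = as.integer(meth),
                               total_count = as.integer(meth + unmeth),
                               context = context)
  if (!is.null(chrom_sizes)) check_on_genome(gr, chrom_sizes,
                                             what = "cytosine record")
  gr
}

#' Write a per-cytosine report
#'
#' Inverts \code{\link{read_cytosine_report}} (unmethylated count is
#' emitted as total - meth).
#'
#' @param meth A \code{GRanges} as returned by
#'   \code{read_cytosine_report}.
#' @param path Output path.
#' @export
write_cytosine_report <- function(meth, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(meth)),
    pos = GenomicRanges::start(meth),
    strand = as.character(GenomicRanges::strand(meth)),
    meth = meth$meth_count,
    unmeth = meth$total_count - meth$meth_count,
    context = meth$context
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 annotation
#'
#' Builds one gene model per gene from its longest mRNA (by genomic
#' span), with exon and UTR structure. GFF3 1-based inclusive
#' coordinates map directly onto the internal \code{GRanges} convention.
#' TE-gene status is read from a configurable gene attribute.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon/five_prime_UTR/
#'   three_prime_UTR records.
#' @param te_attribute Gene attribute key flagging transposable-element
#'   genes; values TRUE/1/yes (case-insensitive) mark a TE gene.
#' @return An object of class \code{gene_models}: a list with
#'   \code{genes} (a \code{GRanges} of transcript spans with
#'   \code{gene_id} and \code{is_TE_gene}), and \code{exons},
#'   \code{utr5}, \code{utr3} (\code{GRangesList} indexed by gene).
#' @export
read_gff3_genes <- function(path, te_attribute = "is_TE") {
  if (!file.exists(path)) stop("file not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  if (length(genes) == 0L) stop("no gene records in GFF3")
  if (any(as.character(GenomicRanges::strand(genes)) == "*")) {
    stop("gene with missing strand in GFF3")
  }
  mrna <- gff[type == "mRNA"]
  parent_of <- function(x) {
    p <- x$Parent
    vapply(p, function(v) if (length(v)) v[[1]] else NA_character_,
           character(1))
  }
  mrna_gene <- parent_of(mrna)
  # longest mRNA (genomic span) per gene
  keep <- rep(FALSE, length(mrna))
  for (g in unique(mrna_gene)) {
    idx <- which(mrna_gene == g)
    keep[idx[which.max(GenomicRanges::width(mrna)[idx])]] <- TRUE
  }
  mrna <- mrna[keep]
  mrna_gene <- mrna_gene[keep]
  gene_ids <- as.character(genes$ID)
  te <- rep(FALSE, length(genes))
  if (te_attribute %in% names(S4Vectors::mcols(genes))) {
    v <- as.character(S4Vectors::mcols(genes)[[te_attribute]])
    te <- !is.na(v) & tolower(v) %in% c("true", "1", "yes")
  }
  children <- gff[type %in% c("exon", "five_prime_UTR", "three_prime_UTR")]
  child_parent <- parent_of(children)
  # map children through their mRNA to the gene
  mrna_ids <- as.character(mrna$ID)
  gene_of_mrna <- stats::setNames(mrna_gene, mrna_ids)
  keep_child <- child_parent %in% mrna_ids
  children <- children[keep_child]
  child_gene <- unname(gene_of_mrna[child_parent[keep_child]])
  # validate: children within parent mRNA span
  sel_mrna <- mrna[match(child_parent[keep_child], mrna_ids)]
  if (any(GenomicRanges::start(children) < GenomicRanges::start(sel_mrna) |
          GenomicRanges::end(children) > GenomicRanges::end(sel_mrna))) {
    stop("child feature outside its parent mRNA span")
  }
  tx <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(mrna),
    IRanges::IRanges(GenomicRanges::start(mrna), GenomicRanges::end(mrna)),
    strand = GenomicRanges::strand(mrna)
  )
  ord <- match(mrna_gene, gene_ids)
  tx$gene_id <- gene_ids[ord]
  tx$is_TE_gene <- te[ord]
  tx <- tx[order(match(tx$gene_id, gene_ids))]
  split_by_gene <- function(what) {
    sel <- as.character(children$type) == what
    grl <- GenomicRanges::split(
      children[sel],
      factor(child_gene[sel], levels = tx$gene_id)
    )
    grl <- GenomicRanges::reduce(GenomicRanges::sort(grl))
    grl
  }
  gene_models(genes = tx,
              exons = split_by_gene("exon"),
              utr5 = split_by_gene("five_prime_UTR"),
              utr3 = split_by_gene("three_prime_UTR"))
}

#' Construct a gene-models object
#'
#' @param genes \code{GRanges} of transcript spans with \code{gene_id}
#'   and \code{is_TE_gene} metadata columns; strand must be + or -.
#' @param exons,utr5,utr3 \code{GRangesList} objects indexed by
#'   \code{gene_id} (same order as \code{genes}).
#' @return A list of class \code{gene_models}.
#' @export
gene_models <- function(genes, exons, utr5 = NULL, utr3 = NULL) {
  stopifnot(all(c("gene_id", "is_TE_gene") %in%
                  names(S4Vectors::mcols(genes))))
  if (any(as.character(GenomicRanges::strand(genes)) == "*")) {
    stop("gene strand must be + or -")
  }
  empty <- GenomicRanges::GRangesList(
    stats::setNames(rep(list(GenomicRanges::GRanges()), length(genes)),
                    genes$gene_id))
  if (is.null(utr5)) utr5 <- empty
  if (is.null(utr3)) utr3 <- empty
  # exons sorted, non-overlapping, within the transcript span
  red <- GenomicRanges::reduce(GenomicRanges::sort(exons))
  rng <- unlist(range(red))
  has <- lengths(red) > 0
  if (any(GenomicRanges::start(rng)[has] <
            GenomicRanges::start(genes)[has] |
          GenomicRanges::end(rng)[has] > GenomicRanges::end(genes)[has])) {
    stop("exons outside transcript span")
  }
  structure(list(genes = genes, exons = red, utr5 = utr5, utr3 = utr3),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d TE genes) on %d chromosome(s)\n",
              length(x$genes), sum(x$genes$is_TE_gene),
              length(unique(as.character(
                GenomicRanges::seqnames(x$genes))))))
  invisible(x)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and UTR records (one mRNA per gene), inverting
#' \code{\link{read_gff3_genes}}.
#'
#' @param models A \code{gene_models} object.
#' @param path Output path.
#' @param te_attribute Attribute key used for the TE flag.
#' @export
write_gff3_genes <- function(models, path, te_attribute = "is_TE") {
  g <- models$genes
  lines <- character(0)
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tg4scape\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attrs)
  }
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    chrom <- as.character(GenomicRanges::seqnames(g)[i])
    strand <- as.character(GenomicRanges::strand(g)[i])
    s <- GenomicRanges::start(g)[i]; e <- GenomicRanges::end(g)[i]
    lines <- c(lines,
               fmt(chrom, "gene", s, e, strand,
                   sprintf("ID=%s;%s=%s", gid, te_attribute,
                           tolower(as.character(g$is_TE_gene[i])))),
               fmt(chrom, "mRNA", s, e, strand,
                   sprintf("ID=%s.1;Parent=%s", gid, gid)))
    emit <- function(set, type) {
      gr <- set[[gid]]
      if (is.null(gr) || length(gr) == 0L) return(character(0))
      fmt(chrom, type, GenomicRanges::start(gr), GenomicRanges::end(gr),
          strand, sprintf("Parent=%s.1", gid))
    }
    lines <- c(lines, emit(models$exons, "exon"),
               emit(models$utr5, "five_prime_UTR"),
               emit(models$utr3, "three_prime_UTR"))
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
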