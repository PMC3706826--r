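## File-format boundary. BED and GTF go through rtracklayer (which handles
## the 0-based/1-based conversion); tabular formats are plain TSV.

#' Read ChIP-seq tags from a BED file
#'
#' Each record contributes one tag at its strand-aware 5' end (start for
#' `+`/unstranded records, end for `-`). Gzipped files are accepted.
#'
#' @param path BED file path.
#' @param mark histone mark identifier to label the collection with.
#' @param layout optional [GenomeLayout-class] whose Seqinfo is imposed.
#' @return a [TagCollection-class].
#' @export
readTagsBed <- function(path, mark, layout = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  pos <- ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
  tg <- GRanges(seqnames(gr), IRanges(pos, width = 1), strand = strand(gr))
  if (!is.null(layout)) {
    seqlevels(tg) <- chromNames(layout)
    seqinfo(tg) <- seqinfo(layout)
  }
  TagCollection(mark, tg)
}

#' Write a TagCollection as 6-column BED
#' @param tags a [TagCollection-class].
#' @param path output path.
#' @export
writeTagsBed <- function(tags, path) {
  gr <- tagPositions(tags)
  gr$name <- paste0("tag_", seq_along(gr))
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from BED6
#'
#' The BED name column is taken as `gene_id`.
#' @param path BED file path.
#' @param layout optional [GenomeLayout-class] whose Seqinfo is imposed.
#' @return `GRanges` with a `gene_id` metadata column.
#' @export
readGenesBed <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$gene_id <- gr$name
  gr$name <- NULL
  gr$score <- NULL
  if (!is.null(layout)) {
    seqlevels(gr) <- chromNames(layout)
    seqinfo(gr) <- seqinfo(layout)
  }
  gr
}

#' Read gene models from GTF
#'
#' Records sharing a `gene_id` are collapsed to their spanning range; a
#' gene with several annotated starts therefore uses the 5'-most start on
#' its coding strand, and a warning reports how many genes were collapsed.
#'
#' @inheritParams readGenesBed
#' @return `GRanges` with a `gene_id` metadata column.
#' @export
readGenesGtf <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "GTF")
  if (is.null(gr$gene_id)) stop("GTF records carry no gene_id attribute")
  if ("type" %in% names(mcols(gr)) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  spl <- split(gr, gr$gene_id)
  multi <- sum(lengths(spl) > 1L)
  if (multi > 0)
    warning(multi, " gene(s) had multiple records; collapsed to the ",
            "spanning range (5'-most start on the coding strand)")
  rng <- unlist(range(spl))
  out <- GRanges(seqnames(rng), ranges(rng), strand = strand(rng))
  out$gene_id <- names(rng)
  if (!is.null(layout)) {
    seqlevels(out) <- chromNames(layout)
    seqinfo(out) <- seqinfo(layout)
  }
  unname(out)
}

#' Write gene models as BED6
#' @param genes `GRanges` with `gene_id`.
#' @param path output path.
#' @export
writeGenesBed <- function(genes, path) {
  gr <- genes
  gr$name <- gr$gene_id
  gr$score <- 0L
  gr$gene_id <- NULL
  gr$truth_class <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a DomainSet as BED plus a JSON sidecar
#'
#' BED columns: chrom, start, end, `island_<k>`, island score, strand.
#' The sidecar (`<path>.json`) records the background rate, eligibility
#' threshold, calibrated score threshold and caller parameters.
#'
#' @param x a [DomainSet-class].
#' @param path output BED path.
#' @param sidecar write the JSON sidecar (TRUE).
#' @export
writeDomainsBed <- function(x, path, sidecar = TRUE) {
  gr <- domains(x)
  gr$name <- paste0("island_", seq_along(gr))
  gr$score <- gr$island_score
  gr$island_score <- NULL
  rtracklayer::export(gr, path, format = "BED")
  if (sidecar) {
    p <- x@params
    jsonlite::write_json(
      list(mark = x@mark, gap = x@gapSize, lambda = x@lambda,
           k_min = x@kMin, score_threshold = x@scoreThreshold,
           window = p@windowSize, e_value = p@eValue, p0 = p@p0,
           shift = p@shift, mc_reps = p@mcReps, seed = p@seed,
           n_domains = length(gr)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write an ExpressionMatrix as TSV
#'
#' One `probe_id` column plus paired `<sample>` and `<sample>.se` columns.
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @export
writeExpressionTsv <- function(x, path) {
  y <- intensities(x)
  s <- standardErrors(x)
  out <- data.frame(probe_id = rownames(y), check.names = FALSE)
  for (j in colnames(y)) {
    out[[j]] <- y[, j]
    out[[paste0(j, ".se")]] <- s[, j]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV and sample sheet into an ExpressionMatrix
#'
#' @param path expression TSV as written by [writeExpressionTsv].
#' @param sampleSheet path to a TSV with columns `sample`, `group`, or a
#'   data.frame of the same shape.
#' @return an [ExpressionMatrix-class].
#' @export
readExpressionTsv <- function(path, sampleSheet) {
  tab <- read.delim(path, check.names = FALSE)
  if (is.character(sampleSheet)) sampleSheet <- read.delim(sampleSheet)
  samples <- sampleSheet$sample
  missing <- setdiff(c(samples, paste0(samples, ".se")), names(tab))
  if (length(missing) > 0)
    stop("expression matrix lacks column(s): ", paste(missing, collapse = ", "))
  y <- as.matrix(tab[, samples, drop = FALSE])
  s <- as.matrix(tab[, paste0(samples, ".se"), drop = FALSE])
  rownames(y) <- rownames(s) <- tab$probe_id
  colnames(s) <- samples
  ExpressionMatrix(y, s, as.character(sampleSheet$group))
}

#' Write the planted truth as TSV (gene table) for inspection
#' @param truth a [PlantedTruth-class].
#' @param path output path.
#' @export
writeTruthTsv <- function(truth, path) {
  g <- plantedGenes(truth)
  write.table(
    data.frame(gene_id = g$gene_id, chrom = as.character(seqnames(g)),
               start = start(g) - 1L, end = end(g),
               strand = as.character(strand(g)), truth_class = g$truth_class),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
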