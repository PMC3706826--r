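## Integration layer: probe-to-gene collapse, the Table-1-style report
## joining differential expression with bivalency scores and a user-supplied
## transcription-factor annotation, and the end-to-end pipeline driver.

#' Collapse probe-level results to one row per gene
#'
#' Probes without a mapping are dropped (their count is reported via
#' `message`); when several probes map to one gene the representative is
#' the probe with the smallest q, ties broken by larger absolute fold
#' change, then lexicographic probe id.
#'
#' @param de data.frame of probe-level results with columns `probe_id`,
#'   `fold_change`, `q` (as produced by [pairwiseDE]).
#' @param mapping data.frame with columns `probe_id`, `gene_symbol` (an
#'   optional `entrez_name` column is carried through).
#' @return data.frame with one row per gene: `gene_symbol`, `probe_id`,
#'   `fold_change`, `fdr_q` (and `entrez_name` when mapped).
#' @export
mapProbesToGenes <- function(de, mapping) {
  if (nrow(mapping) == 0) stop("empty probe-to-gene mapping")
  merged <- merge(de, mapping, by = "probe_id")
  dropped <- length(setdiff(de$probe_id, mapping$probe_id))
  if (dropped > 0)
    message(dropped, " probe(s) had no gene mapping and were dropped")
  if (nrow(merged) == 0) {
    out <- data.frame(gene_symbol = character(0), probe_id = character(0),
                      fold_change = numeric(0), fdr_q = numeric(0))
    return(out)
  }
  ord <- order(merged$gene_symbol, merged$q, -abs(merged$fold_change),
               merged$probe_id)
  merged <- merged[ord, ]
  best <- merged[!duplicated(merged$gene_symbol), ]
  cols <- c("gene_symbol", "probe_id", "fold_change")
  if ("entrez_name" %in% names(best)) cols <- c(cols, "entrez_name")
  out <- best[, cols]
  out$fdr_q <- best$q
  rownames(out) <- NULL
  out
}

#' Build the annotated gene report
#'
#' Left-joins the differentially expressed gene table with bivalency scores
#' and flags transcription factors by membership in `tfList`. Genes absent
#' from the bivalency table keep an `NA` score: an unscored gene is
#' distinguished from a gene scored 0 (never bivalent).
#'
#' @param deGenes data.frame from [mapProbesToGenes] (columns
#'   `gene_symbol`, `fold_change`, `fdr_q`, optionally `entrez_name`).
#' @param bivalency data.frame from [scoreBivalency] / [bivalencyScore]
#'   (columns `gene_id`, `score`).
#' @param tfList character vector of transcription-factor gene symbols.
#' @return data.frame sorted by gene symbol with columns `gene_symbol`,
#'   `entrez_name`, `fold_change`, `fdr_q`, `bivalency_score`, `is_tf`.
#' @export
buildReport <- function(deGenes, bivalency, tfList = character(0)) {
  out <- merge(deGenes,
               data.frame(gene_symbol = bivalency$gene_id,
                          bivalency_score = bivalency$score),
               by = "gene_symbol", all.x = TRUE)
  missing <- sum(is.na(out$bivalency_score))
  if (missing > 0)
    message(missing, " gene(s) without a bivalency score (reported as NA)")
  if (!"entrez_name" %in% names(out)) out$entrez_name <- NA_character_
  out$is_tf <- out$gene_symbol %in% tfList
  out <- out[order(out$gene_symbol),
             c("gene_symbol", "entrez_name", "fold_change", "fdr_q",
               "bivalency_score", "is_tf")]
  rownames(out) <- NULL
  out
}

.requiredConfigPaths <- c("k4_tags", "k27_tags", "genes", "chrom_sizes",
                          "expression", "samples", "probe_gene_map")

.configDefaults <- list(
  window = 200, gaps = c(200, 400, 600, 800, 1000), evalue = 0.1, p0 = 0.2,
  shift = 0, mc_reps = 100, effective_fraction = 1, flank = 2000,
  alpha = 0.05, seed = 1, reference_group = "day0", focal_group = "day2",
  test_groups = c("day2", "day4", "day10")
)

#' Run the full pipeline from a configuration
#'
#' Orchestrates differential expression, timepoint-specific set extraction,
#' probe-to-gene collapse, domain calling and bivalency scoring at every
#' gap size, and the final report, writing all intermediates, a plain-text
#' log with stage timings and a JSON manifest of parameters to the output
#' directory. Re-running with the same configuration and seed reproduces
#' the report byte for byte.
#'
#' @param config path to a YAML file or an equivalent named list. Required
#'   path fields: `k4_tags`, `k27_tags` (BED tags per mark), `genes` (BED6
#'   or GTF, by extension), `chrom_sizes` (TSV), `expression` (TSV as in
#'   [writeExpressionTsv]), `samples` (TSV sample sheet),
#'   `probe_gene_map` (TSV with `probe_id`, `gene_symbol`). Optional:
#'   `tf_list` (one symbol per line), plus the tuning fields `window`,
#'   `gaps`, `evalue`, `p0`, `shift`, `mc_reps`, `effective_fraction`,
#'   `flank`, `alpha`, `seed`, `reference_group`, `focal_group`,
#'   `test_groups`.
#' @param outDir output directory (defaults to the config's `out_dir`).
#' @return (invisibly) a list with the report, the DE tables, the bivalency
#'   table and the output directory.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in .requiredConfigPaths) {
    if (is.null(config[[f]]))
      stop("config field missing: ", f)
    if (!file.exists(config[[f]]))
      stop("config field '", f, "' points to a missing file: ", config[[f]])
  }
  cfg <- utils::modifyList(.configDefaults, config)
  if (is.null(outDir)) outDir <- cfg$out_dir
  if (is.null(outDir)) stop("config field missing: out_dir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  logPath <- file.path(outDir, "pipeline.log")
  cat("", file = logPath)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    cat(sprintf("[%s] %-24s %6.2fs\n", format(Sys.time(), "%H:%M:%S"), name,
                as.numeric(difftime(Sys.time(), tic, units = "secs"))),
        file = logPath, append = TRUE)
    res
  }

  layout <- stage("read_genome", readChromSizes(cfg$chrom_sizes,
                                                cfg$effective_fraction))
  em <- stage("read_expression", readExpressionTsv(cfg$expression, cfg$samples))
  genes <- stage("read_genes", {
    if (grepl("\\.gtf(\\.gz)?$", cfg$genes, ignore.case = TRUE))
      readGenesGtf(cfg$genes, layout)
    else readGenesBed(cfg$genes, layout)
  })

  contrasts <- lapply(cfg$test_groups, function(g) c(cfg$reference_group, g))
  deList <- stage("pairwise_de", pairwiseDE(em, contrasts, cfg$alpha))
  for (nm in names(deList))
    write.table(deList[[nm]], file.path(outDir, paste0("de_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  focal <- paste0(cfg$focal_group, "_vs_", cfg$reference_group)
  specific <- stage("timepoint_specific",
                    timepointSpecificSet(deList, focal = focal))
  writeLines(specific, file.path(outDir, "focal_specific_probes.txt"))

  mapping <- read.delim(cfg$probe_gene_map)
  deFocal <- deList[[focal]]
  deGenes <- stage("map_probes_to_genes",
                   mapProbesToGenes(deFocal[deFocal$probe_id %in% specific, ],
                                    mapping))

  params <- CallerParams(windowSize = cfg$window, gapSize = cfg$gaps[1],
                         eValue = cfg$evalue, p0 = cfg$p0, shift = cfg$shift,
                         mcReps = cfg$mc_reps, seed = cfg$seed)
  k4 <- stage("read_k4_tags", readTagsBed(cfg$k4_tags, "H3K4me3", layout))
  k27 <- stage("read_k27_tags", readTagsBed(cfg$k27_tags, "H3K27me3", layout))
  biv <- stage("score_bivalency",
               scoreBivalency(genes, k4, k27, layout, params,
                              gaps = as.integer(cfg$gaps), flank = cfg$flank))
  write.table(biv, file.path(outDir, "bivalency.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  domSets <- attr(biv, "domainSets")
  for (mk in names(domSets))
    for (gp in names(domSets[[mk]]))
      writeDomainsBed(domSets[[mk]][[gp]],
                      file.path(outDir, paste0("domains_", mk, "_", gp, ".bed")))

  tfList <- if (!is.null(cfg$tf_list)) readLines(cfg$tf_list) else character(0)
  report <- stage("build_report", buildReport(deGenes, biv, tfList))
  write.table(report, file.path(outDir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "bivalScore",
    version = as.character(packageVersion("bivalScore")),
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    columns = list(
      fold_change = paste0("de_", focal, ".tsv"),
      fdr_q = paste0("de_", focal, ".tsv"),
      bivalency_score = "bivalency.tsv",
      is_tf = "tf_list"),
    outputs = list.files(outDir),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, de = deList, bivalency = biv,
                 outDir = outDir))
}

#' Write a self-contained synthetic demo input set
#'
#' Generates a two-chromosome 1 Mb genome with planted bivalent, single-mark
#' and unmarked genes, simulated tags for both marks, a 500-probe expression
#' matrix with effects planted at day 2, a probe-to-gene mapping that ties
#' planted differential probes to the planted genes, a transcription-factor
#' list containing the bivalent genes, and a ready-to-run `config.yaml`.
#'
#' @param dir directory to create the files in.
#' @param seed integer seed controlling every simulated input.
#' @return path to the written `config.yaml`.
#' @examples
#' \dontrun{
#' cfg <- writeDemoInputs(tempfile("demo"))
#' res <- runPipeline(cfg)
#' head(res$report)
#' }
#' @export
writeDemoInputs <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- makeGenome(2, 500000)
  truth <- plantTruth(layout, 5, 5, 5, 5, seed = seed)
  k4 <- simulateTags(truth, layout, "H3K4me3", seed = seed + 1)
  k27 <- simulateTags(truth, layout, "H3K27me3", seed = seed + 2)

  design <- rep(c("day0", "day2", "day4", "day10", "HSVEC"), each = 3)
  em <- simulateExpression(500, design, nDe = 50, lfc = 1.5, seScale = 0.05,
                           seed = seed + 3)

  ## mapping: tie planted day-2 probes to the planted genes so the report
  ## exercises the full join; remaining genes get null probes
  genes <- plantedGenes(truth)
  deProbes <- rownames(em)[rowData(em)$is_de]
  nullProbes <- setdiff(rownames(em), deProbes)
  n <- length(genes)
  mapping <- data.frame(
    probe_id = c(deProbes[seq_len(n)], nullProbes[seq_len(n)]),
    gene_symbol = rep(genes$gene_id, 2),
    entrez_name = rep(paste("synthetic gene", seq_len(n)), 2))

  paths <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    k4_tags = file.path(dir, "k4_tags.bed"),
    k27_tags = file.path(dir, "k27_tags.bed"),
    genes = file.path(dir, "genes.bed"),
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    probe_gene_map = file.path(dir, "probe_gene_map.tsv"),
    tf_list = file.path(dir, "tf_list.txt"))

  write.table(data.frame(chromNames(layout), chromLengths(layout)),
              paths$chrom_sizes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeTagsBed(k4, paths$k4_tags)
  writeTagsBed(k27, paths$k27_tags)
  writeGenesBed(genes, paths$genes)
  writeExpressionTsv(em, paths$expression)
  write.table(data.frame(sample = colnames(em), group = design),
              paths$samples, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mapping, paths$probe_gene_map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(genes$gene_id[genes$truth_class == "bivalent"], paths$tf_list)
  writeTruthTsv(truth, file.path(dir, "truth.tsv"))

  cfg <- c(lapply(paths, normalizePath),
           list(out_dir = file.path(normalizePath(dir), "out"), seed = seed))
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  cfgPath
}
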