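#' GenomeLayout: chromosome names, lengths and effective genome fraction
#'
#' Thin wrapper around a [GenomeInfoDb::Seqinfo] that additionally carries
#' the effective (mappable) genome fraction used to set the Poisson
#' background rate of the island caller. Synthetic genomes are fully
#' mappable (fraction 1); for real human tag data a value around 0.74 is
#' conventional.
#'
#' @slot seqinfo a `Seqinfo` with chromosome names and lengths.
#' @slot effectiveFraction unitless scalar in (0, 1].
#' @exportClass GenomeLayout
setClass("GenomeLayout",
  slots = c(seqinfo = "Seqinfo", effectiveFraction = "numeric")
)

setValidity("GenomeLayout", function(object) {
  sl <- seqlengths(object@seqinfo)
  if (length(sl) < 1L) return("layout must contain at least one chromosome")
  if (anyNA(sl) || any(sl <= 0)) return("chromosome lengths must be positive")
  if (anyDuplicated(names(sl))) return("chromosome names must be unique")
  ef <- object@effectiveFraction
  if (length(ef) != 1L || is.na(ef) || ef <= 0 || ef > 1)
    return("effectiveFraction must be a single value in (0, 1]")
  TRUE
})

#' PlantedTruth: synthetic ground truth for two-mark enrichment
#'
#' Holds the planted H3K4me3 / H3K27me3 enriched regions, the synthetic gene
#' models with their truth class (bivalent, k4_only, k27_only, unmarked),
#' and the simulation rates. Region and gene coordinates are GRanges tied to
#' the generating [GenomeLayout].
#'
#' @slot k4Regions,k27Regions `GRanges` of planted enriched regions.
#' @slot genes `GRanges` with metadata columns `gene_id` and `truth_class`.
#' @slot enrichmentFold fold increase of the Poisson tag rate inside regions.
#' @slot backgroundRate background tags per window.
#' @exportClass PlantedTruth
setClass("PlantedTruth",
  slots = c(
    k4Regions = "GRanges", k27Regions = "GRanges", genes = "GRanges",
    enrichmentFold = "numeric", backgroundRate = "numeric"
  )
)

setValidity("PlantedTruth", function(object) {
  g <- object@genes
  if (length(g) > 0) {
    if (is.null(g$gene_id) || is.null(g$truth_class))
      return("genes must carry gene_id and truth_class metadata columns")
    if (!all(g$truth_class %in% c("bivalent", "k4_only", "k27_only", "unmarked")))
      return("unknown truth_class value")
  }
  if (object@enrichmentFold < 1) return("enrichmentFold must be >= 1")
  if (object@backgroundRate <= 0) return("backgroundRate must be positive")
  TRUE
})

#' TagCollection: single-mark ChIP-seq tag positions
#'
#' Tags are stored as width-1 GRanges (the counted genomic position of each
#' tag), sorted, with the layout's Seqinfo attached so out-of-bounds
#' positions are rejected at construction.
#'
#' @slot mark histone mark identifier, e.g. `"H3K4me3"`.
#' @slot tags width-1 `GRanges`, sorted.
#' @exportClass TagCollection
setClass("TagCollection", slots = c(mark = "character", tags = "GRanges"))

setValidity("TagCollection", function(object) {
  if (length(object@mark) != 1L || !nzchar(object@mark))
    return("mark must be a single non-empty identifier")
  tg <- object@tags
  if (length(tg) > 0) {
    if (any(width(tg) != 1L)) return("tags must have width 1")
    if (is.unsorted(order(as.integer(seqnames(tg)), start(tg))))
      return("tags must be sorted")
    sl <- seqlengths(tg)
    if (!anyNA(sl)) {
      ends <- end(tg)
      if (any(start(tg) < 1L) || any(ends > sl[as.character(seqnames(tg))]))
        return("tag positions outside chromosome bounds")
    }
  }
  TRUE
})

#' WindowCounts: per-window tag counts for one mark
#'
#' @slot windowSize window width in bp.
#' @slot counts named list of integer vectors, one per chromosome; element
#'   `i` counts tags assigned to window `i` (windows tile each chromosome
#'   from its first base, `ceiling(length / windowSize)` windows).
#' @slot totalTags total tag count (conserved through windowing).
#' @exportClass WindowCounts
setClass("WindowCounts",
  slots = c(windowSize = "integer", counts = "list", totalTags = "integer")
)

setValidity("WindowCounts", function(object) {
  if (object@windowSize < 1L) return("windowSize must be positive")
  s <- sum(vapply(object@counts, sum, numeric(1)))
  if (s != object@totalTags)
    return("window counts do not sum to totalTags (tag conservation violated)")
  TRUE
})

#' CallerParams: parameters of the island caller
#'
#' Defaults follow the published parameterisation: 200 bp windows, E-value
#' 0.1, gap size one of 200/400/600/800/1000 bp. `p0` is the Poisson upper
#' tail probability below which a window is eligible; `mcReps`/`seed`
#' control the Monte-Carlo E-value calibration; `shift` moves raw read
#' 5' positions toward the fragment centre (0 for pre-positioned tags).
#'
#' @slot windowSize,gapSize,shift bp.
#' @slot eValue expected number of background islands genome-wide.
#' @slot p0 window eligibility tail probability.
#' @slot mcReps,seed Monte-Carlo calibration replicates and seed.
#' @exportClass CallerParams
setClass("CallerParams",
  slots = c(
    windowSize = "integer", gapSize = "integer", eValue = "numeric",
    p0 = "numeric", shift = "integer", mcReps = "integer", seed = "integer"
  )
)

setValidity("CallerParams", function(object) {
  if (object@windowSize < 1L) return("windowSize must be positive")
  if (object@gapSize < 0L) return("gapSize must be non-negative")
  if (object@gapSize %% object@windowSize != 0L)
    return("gapSize must be a multiple of windowSize")
  if (object@eValue <= 0) return("eValue must be positive")
  if (object@p0 <= 0 || object@p0 >= 1) return("p0 must lie in (0, 1)")
  if (object@mcReps < 1L) return("mcReps must be >= 1")
  TRUE
})

#' DomainSet: called enriched domains for one mark at one gap size
#'
#' Domains are window-aligned, non-overlapping, sorted GRanges carrying an
#' `island_score` metadata column; every retained island's score is at least
#' the calibrated threshold.
#'
#' @slot mark histone mark identifier.
#' @slot gapSize gap size (bp) the set was called at.
#' @slot domains `GRanges` with `island_score`.
#' @slot lambda background rate (tags per window).
#' @slot kMin window eligibility count threshold.
#' @slot scoreThreshold calibrated island-score threshold.
#' @slot params the `CallerParams` used.
#' @exportClass DomainSet
setClass("DomainSet",
  slots = c(
    mark = "character", gapSize = "integer", domains = "GRanges",
    lambda = "numeric", kMin = "integer", scoreThreshold = "numeric",
    params = "CallerParams"
  )
)

setValidity("DomainSet", function(object) {
  d <- object@domains
  if (length(d) > 0) {
    if (is.null(d$island_score)) return("domains must carry island_score")
    if (any(d$island_score < object@scoreThreshold))
      return("island below the calibrated score threshold")
    if (!isDisjoint(d)) return("domains must be non-overlapping")
  }
  TRUE
})

#' ExpressionMatrix: probe x sample intensities with per-value SEs
#'
#' A [SummarizedExperiment] with two assays, `intensity` (linear scale,
#' strictly positive) and `se` (per-value standard errors, positive), and a
#' `group` column in `colData`. Synthetic matrices additionally carry
#' `is_de` and `true_lfc` truth columns in `rowData`.
#'
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  an <- assayNames(object)
  if (!all(c("intensity", "se") %in% an))
    return("assays 'intensity' and 'se' are required")
  if (!"group" %in% colnames(colData(object)))
    return("colData must contain a 'group' column")
  if (any(assay(object, "se") <= 0)) return("standard errors must be positive")
  if (any(assay(object, "intensity") <= 0))
    return("intensities must be strictly positive")
  TRUE
})
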