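## Bivalency scoring: TSS +/- flank windows intersected with both marks'
## domain sets at each gap size; the score counts the gap sizes at which a
## gene overlaps enriched domains of both H3K4me3 and H3K27me3.

.DEFAULT_GAPS <- c(200L, 400L, 600L, 800L, 1000L)

#' Transcription start site of a gene model
#'
#' Plus-strand genes start at their leftmost base; minus-strand genes at
#' their rightmost. Coordinates are 1-based (GRanges convention).
#'
#' @param genes a `GRanges` of gene models with strand `+` or `-`.
#' @return integer vector of TSS positions.
#' @export
tssPosition <- function(genes) {
  st <- as.character(strand(genes))
  if (any(!st %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  ifelse(st == "+", start(genes), end(genes))
}

#' TSS +/- flank windows
#'
#' Builds the symmetric promoter interval `[TSS - flank, TSS + flank]`
#' (inclusive, so `2 * flank + 1` bases when unclamped) for each gene and
#' clips it to the chromosome bounds.
#'
#' @param genes `GRanges` gene models with a `gene_id` metadata column.
#' @param flank half-width in bp (2000 by default, the published interval).
#' @param layout optional [GenomeLayout-class]; when supplied its Seqinfo is
#'   imposed before clipping.
#' @return `GRanges` named by `gene_id`, width at most `2 * flank + 1`.
#' @export
tssWindows <- function(genes, flank = 2000, layout = NULL) {
  if (flank < 0) stop("flank must be non-negative")
  tss <- tssPosition(genes)
  gr <- GRanges(seqnames(genes),
                IRanges(pmax(tss - flank, 1L), tss + flank),
                seqinfo = if (is.null(layout)) seqinfo(genes) else seqinfo(layout))
  gr <- trim(gr)
  if (!is.null(genes$gene_id)) names(gr) <- genes$gene_id
  gr
}

#' Does each window overlap any called domain?
#'
#' Overlap means at least one shared base; abutting intervals do not count.
#'
#' @param windows `GRanges` of TSS windows.
#' @param domainSet a [DomainSet-class].
#' @return logical vector along `windows`.
#' @export
overlapsAnyDomain <- function(windows, domainSet) {
  overlapsAny(windows, domains(domainSet), minoverlap = 1L)
}

#' Bivalency at a single gap size
#'
#' A gene is bivalent at a gap size when its TSS window overlaps at least
#' one enriched domain of each mark, with both marks called at that same
#' gap size. The two overlaps may involve different domains at different
#' parts of the window; co-location is not required.
#'
#' @param windows `GRanges` of TSS windows.
#' @param k4Set,k27Set [DomainSet-class] for H3K4me3 and H3K27me3 called at
#'   the same gap size.
#' @return logical vector along `windows`.
#' @export
bivalentAtGap <- function(windows, k4Set, k27Set) {
  if (gapSize(k4Set) != gapSize(k27Set))
    stop("gap sizes differ between the two marks (",
         gapSize(k4Set), " vs ", gapSize(k27Set), ")")
  overlapsAnyDomain(windows, k4Set) & overlapsAnyDomain(windows, k27Set)
}

#' Bivalency score from pre-called domain sets
#'
#' Counts, per gene, the gap sizes at which its TSS window overlaps
#' enriched domains of both marks. Score 0: never bivalent; score equal to
#' the number of gap sizes (5 for the default collection): bivalent
#' regardless of the gap size chosen.
#'
#' @param genes `GRanges` gene models with `gene_id`.
#' @param k4Sets,k27Sets named lists of [DomainSet-class], one per gap
#'   size; both must cover an identical gap-size collection.
#' @param flank TSS window half-width in bp.
#' @param layout optional [GenomeLayout-class] for window clipping.
#' @return data.frame with `gene_id`, one logical `flag_g<gap>` column per
#'   gap size, and `score`.
#' @export
bivalencyScore <- function(genes, k4Sets, k27Sets, flank = 2000,
                           layout = NULL) {
  g4 <- sort(vapply(k4Sets, gapSize, integer(1)))
  g27 <- sort(vapply(k27Sets, gapSize, integer(1)))
  if (!identical(unname(g4), unname(g27)))
    stop("the two marks do not cover the same gap-size collection")
  k4Sets <- k4Sets[order(vapply(k4Sets, gapSize, integer(1)))]
  k27Sets <- k27Sets[order(vapply(k27Sets, gapSize, integer(1)))]

  win <- tssWindows(genes, flank, layout)
  flags <- vapply(seq_along(k4Sets), function(i)
    bivalentAtGap(win, k4Sets[[i]], k27Sets[[i]]), logical(length(win)))
  flags <- matrix(flags, nrow = length(win),
                  dimnames = list(NULL, paste0("flag_g", unname(g4))))
  data.frame(gene_id = genes$gene_id, flags,
             score = as.integer(rowSums(flags)))
}

#' Score bivalency for all genes from tag data
#'
#' Calls domains for each mark at each gap size with [callDomains], then
#' computes per-gene bivalency flags and the 0-5 score.
#'
#' @param genes `GRanges` gene models with `gene_id`.
#' @param k4Tags,k27Tags [TagCollection-class] for the two marks.
#' @param layout a [GenomeLayout-class].
#' @param params a [CallerParams-class]; its `gapSize` is ignored and
#'   replaced by each element of `gaps` in turn.
#' @param gaps integer vector of gap sizes (default 200-1000 bp).
#' @param flank TSS window half-width in bp.
#' @return data.frame as for [bivalencyScore]; the called
#'   [DomainSet-class] lists are attached as attribute `"domainSets"`.
#' @export
scoreBivalency <- function(genes, k4Tags, k27Tags, layout,
                           params = CallerParams(), gaps = .DEFAULT_GAPS,
                           flank = 2000) {
  if (totalTags(k4Tags) == 0 || totalTags(k27Tags) == 0)
    stop("both tag collections must be non-empty")
  callAt <- function(tags) {
    sets <- lapply(gaps, function(g) {
      p <- params
      p@gapSize <- as.integer(g)
      callDomains(tags, layout, p)
    })
    names(sets) <- paste0("g", gaps)
    sets
  }
  k4Sets <- callAt(k4Tags)
  k27Sets <- callAt(k27Tags)
  res <- bivalencyScore(genes, k4Sets, k27Sets, flank, layout)
  attr(res, "domainSets") <- list(H3K4me3 = k4Sets, H3K27me3 = k27Sets)
  res
}
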