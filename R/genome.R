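#' Construct a synthetic genome layout
#'
#' Builds a layout of `nChroms` equally sized chromosomes named
#' `chrS1 ... chrSn`. Construction is fully deterministic; the `seed`
#' argument is accepted for interface symmetry with the other generators
#' but no randomness is consumed.
#'
#' @param nChroms number of chromosomes (>= 1).
#' @param chromLength length of each chromosome in bp (>= 10000).
#' @param seed ignored (deterministic construction); kept so all generator
#'   signatures look alike.
#' @param effectiveFraction effective (mappable) genome fraction in (0, 1];
#'   1 for synthetic genomes.
#' @return a [GenomeLayout-class].
#' @examples
#' layout <- makeGenome(2, 500000)
#' chromLengths(layout)
#' @export
makeGenome <- function(nChroms, chromLength, seed = NULL, effectiveFraction = 1) {
  if (nChroms < 1) stop("nChroms must be >= 1")
  if (chromLength < 10000) stop("chromLength must be >= 10000")
  nChroms <- as.integer(nChroms)
  si <- Seqinfo(
    seqnames = paste0("chrS", seq_len(nChroms)),
    seqlengths = rep(as.integer(chromLength), nChroms)
  )
  new("GenomeLayout", seqinfo = si, effectiveFraction = effectiveFraction)
}

#' Read a chromosome-sizes table into a GenomeLayout
#'
#' Expects a two-column tab-separated file (chrom, length) with no header,
#' the standard "chrom.sizes" format.
#'
#' @param path path to the table.
#' @param effectiveFraction effective genome fraction, see
#'   [GenomeLayout-class].
#' @return a [GenomeLayout-class].
#' @export
readChromSizes <- function(path, effectiveFraction = 1) {
  tab <- read.delim(path, header = FALSE, col.names = c("chrom", "length"))
  si <- Seqinfo(seqnames = as.character(tab$chrom),
                seqlengths = as.integer(tab$length))
  new("GenomeLayout", seqinfo = si, effectiveFraction = effectiveFraction)
}

#' @rdname GenomeLayout-class
#' @export
setMethod("chromNames", "GenomeLayout", function(x) seqlevels(x@seqinfo))

#' @rdname GenomeLayout-class
#' @export
setMethod("chromLengths", "GenomeLayout", function(x) seqlengths(x@seqinfo))

#' @rdname GenomeLayout-class
#' @export
setMethod("effectiveFraction", "GenomeLayout", function(x) x@effectiveFraction)

#' @rdname GenomeLayout-class
#' @export
setMethod("genomeLength", "GenomeLayout", function(x) sum(as.numeric(chromLengths(x))))

#' @rdname GenomeLayout-class
#' @export
setMethod("seqinfo", "GenomeLayout", function(x) x@seqinfo)

setMethod("show", "GenomeLayout", function(object) {
  sl <- chromLengths(object)
  cat("GenomeLayout with", length(sl), "chromosome(s),",
      format(sum(as.numeric(sl)), big.mark = ","), "bp total;",
      "effective fraction", object@effectiveFraction, "\n")
})
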