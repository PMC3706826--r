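#' Construct a TagCollection
#'
#' @param mark histone mark identifier (e.g. `"H3K4me3"`).
#' @param tags a `GRanges` of width-1 tag positions; sorted on construction.
#' @return a [TagCollection-class].
#' @export
TagCollection <- function(mark, tags) {
  new("TagCollection", mark = mark, tags = sort(tags, ignore.strand = TRUE))
}

#' @rdname TagCollection-class
#' @export
setMethod("mark", "TagCollection", function(x) x@mark)

#' @rdname TagCollection-class
#' @export
setMethod("tagPositions", "TagCollection", function(x) x@tags)

#' @rdname TagCollection-class
#' @export
setMethod("totalTags", "TagCollection", function(x) length(x@tags))

setMethod("show", "TagCollection", function(object) {
  cat("TagCollection:", object@mark, "with",
      format(length(object@tags), big.mark = ","), "tags on",
      length(unique(seqnames(object@tags))), "chromosome(s)\n")
})
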