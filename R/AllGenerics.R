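#' @rdname GenomeLayout-class
#' @param object,x a `GenomeLayout`
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))
#' @rdname GenomeLayout-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname GenomeLayout-class
#' @export
setGeneric("effectiveFraction", function(x) standardGeneric("effectiveFraction"))
#' @rdname GenomeLayout-class
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname TagCollection-class
#' @export
setGeneric("mark", function(x) standardGeneric("mark"))
#' @rdname TagCollection-class
#' @export
setGeneric("tagPositions", function(x) standardGeneric("tagPositions"))
#' @rdname TagCollection-class
#' @export
setGeneric("totalTags", function(x) standardGeneric("totalTags"))

#' @rdname DomainSet-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))
#' @rdname DomainSet-class
#' @export
setGeneric("gapSize", function(x) standardGeneric("gapSize"))
#' @rdname DomainSet-class
#' @export
setGeneric("lambdaBackground", function(x) standardGeneric("lambdaBackground"))
#' @rdname DomainSet-class
#' @export
setGeneric("scoreThreshold", function(x) standardGeneric("scoreThreshold"))

#' @rdname PlantedTruth-class
#' @export
setGeneric("plantedGenes", function(x) standardGeneric("plantedGenes"))
#' @rdname PlantedTruth-class
#' @export
setGeneric("plantedRegions", function(x, mark) standardGeneric("plantedRegions"))
#' @rdname PlantedTruth-class
#' @export
setGeneric("truthClasses", function(x) standardGeneric("truthClasses"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname ExpressionMatrix-class
#' @export
setGeneric("standardErrors", function(x) standardGeneric("standardErrors"))
#' @rdname ExpressionMatrix-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
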