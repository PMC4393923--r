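#' @import methods
#' @importFrom stats cor rnorm rbeta rlnorm median quantile setNames t.test
#'   rmultinom runif var sd
#' @importFrom utils read.table write.table head tail
NULL

#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @export
setGeneric("exonicLength", function(x) standardGeneric("exonicLength"))

#' @export
setGeneric("txStrand", function(x) standardGeneric("txStrand"))

#' @export
setGeneric("txChrom", function(x) standardGeneric("txChrom"))

#' @export
setGeneric("txSpan", function(x) standardGeneric("txSpan"))

#' @export
setGeneric("overlapTable", function(x) standardGeneric("overlapTable"))

#' @export
setGeneric("maxOverlapPct", function(x, ...) standardGeneric("maxOverlapPct"))
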