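#' @import methods
NULL

#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @export
setGeneric("penaltyScore", function(x) standardGeneric("penaltyScore"))

#' @export
setGeneric("roleAssignment", function(x) standardGeneric("roleAssignment"))

#' @export
setGeneric("tsPose", function(x) standardGeneric("tsPose"))

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("indicatorVector", function(x) standardGeneric("indicatorVector"))

#' @export
setGeneric("conformerCount", function(x) standardGeneric("conformerCount"))
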