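#' @importFrom ProtGenerics mz intensity peaks
#' @importFrom methods new validObject show is slot
#' @importFrom stats approx lm coef median mad quantile rnorm setNames
#' @importFrom utils read.csv write.csv head
NULL

#' @export
setGeneric("formulaString", function(object, ...) standardGeneric("formulaString"))

#' @export
setGeneric("elementCounts", function(object) standardGeneric("elementCounts"))

#' @export
setGeneric("ionCharge", function(object) standardGeneric("ionCharge"))

#' @export
setGeneric("monoisotopicMass", function(object) standardGeneric("monoisotopicMass"))

#' @export
setGeneric("rdbe", function(object) standardGeneric("rdbe"))

#' @export
setGeneric("electronParity", function(object) standardGeneric("electronParity"))

#' @export
setGeneric("candidates", function(object) standardGeneric("candidates"))

#' @export
setGeneric("fwhmAt", function(object, mz) standardGeneric("fwhmAt"))

#' @export
setGeneric("applyMassAxis", function(object, mz) standardGeneric("applyMassAxis"))
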