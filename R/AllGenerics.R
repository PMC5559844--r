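#' @rdname MethylomeTable-class
#' @param object,x a `MethylomeTable`.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname MethylomeTable-class
#' @export
setGeneric("methData", function(x) standardGeneric("methData"))

#' @rdname BinSet-class
#' @param x an object with bin structure.
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))

#' @rdname BinSet-class
#' @export
setGeneric("binPositions", function(x) standardGeneric("binPositions"))

#' @rdname EpigenotypeMap-class
#' @export
setGeneric("finalStates", function(x) standardGeneric("finalStates"))

#' @rdname EpigenotypeMap-class
#' @export
setGeneric("lrStates", function(x) standardGeneric("lrStates"))

#' @rdname EpigenotypeMap-class
#' @export
setGeneric("fbStates", function(x) standardGeneric("fbStates"))

#' @rdname EpigenotypeMap-class
#' @export
setGeneric("lrProbs", function(x) standardGeneric("lrProbs"))

#' @rdname EpigenotypeMap-class
#' @export
setGeneric("fbPosteriors", function(x) standardGeneric("fbPosteriors"))

#' @rdname EpigenotypeMap-class
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))

#' @rdname breakpoints
#' @export
setGeneric("breakpoints", function(x, ...) standardGeneric("breakpoints"))

#' @rdname countCrossovers
#' @export
setGeneric("countCrossovers", function(x, ...) standardGeneric("countCrossovers"))
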