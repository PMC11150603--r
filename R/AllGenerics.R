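#' @rdname AnalyticSeries-class
#' @param object,x An object.
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @rdname AnalyticSeries-class
#' @export
setGeneric("phase", function(x) standardGeneric("phase"))

#' @rdname AnalyticSeries-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname GammaGlmFit-class
#' @export
setGeneric("shape", function(x) standardGeneric("shape"))

#' @rdname GammaGlmFit-class
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))

#' @rdname PacResult-class
#' @export
setGeneric("pacValue", function(x) standardGeneric("pacValue"))
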