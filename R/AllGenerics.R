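#' @rdname CellNetwork-class
#' @param x a \code{CellNetwork}
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname CellNetwork-class
#' @export
setGeneric("couplings", function(x) standardGeneric("couplings"))

#' @rdname CellNetwork-class
#' @export
setGeneric("architecture", function(x) standardGeneric("architecture"))

#' @rdname CalciumSimulation-class
#' @param x a \code{CalciumSimulation}
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname CalciumSimulation-class
#' @export
setGeneric("regimes", function(x) standardGeneric("regimes"))

#' @rdname CalciumSimulation-class
#' @export
setGeneric("simTimes", function(x) standardGeneric("simTimes"))

#' @rdname CalciumSimulation-class
#' @export
setGeneric("activationSteps", function(x) standardGeneric("activationSteps"))

#' @rdname CalciumSimulation-class
#' @export
setGeneric("activationTimes", function(x) standardGeneric("activationTimes"))

#' @rdname FluorescenceTraceSet-class
#' @param x a \code{FluorescenceTraceSet}
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname FluorescenceTraceSet-class
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname FluorescenceTraceSet-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
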