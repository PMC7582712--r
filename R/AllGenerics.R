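#' @rdname FactorialArrayExperiment-accessors
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))

#' @rdname FactorialArrayExperiment-accessors
#' @export
setGeneric("designCells", function(x) standardGeneric("designCells"))

#' @rdname FactorialArrayExperiment-accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname FactorialArrayExperiment-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname ModeratedFit-accessors
#' @export
setGeneric("contrastNames", function(x) standardGeneric("contrastNames"))

#' @rdname ModeratedFit-accessors
#' @export
setGeneric("logFoldChanges", function(x) standardGeneric("logFoldChanges"))

#' @rdname ModeratedFit-accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname ModeratedFit-accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname ModeratedFit-accessors
#' @export
setGeneric("contrastStates", function(x) standardGeneric("contrastStates"))

#' @rdname ModeratedFit-accessors
#' @export
setGeneric("priorParameters", function(x) standardGeneric("priorParameters"))
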