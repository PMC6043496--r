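# Accessor generics for the package's S4 classes.

#' @rdname PropensityScale-class
#' @param x A \linkS4class{PropensityScale}.
#' @export
setGeneric("scaleName", function(x) standardGeneric("scaleName"))

#' @rdname PropensityScale-class
#' @export
setGeneric("scaleValues", function(x) standardGeneric("scaleValues"))

#' @rdname PropensityScale-class
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))

#' @rdname InteractionDataset-class
#' @param x An \linkS4class{InteractionDataset}.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname InteractionDataset-class
#' @export
setGeneric("sequenceStore", function(x) standardGeneric("sequenceStore"))

#' @rdname InteractionDataset-class
#' @export
setGeneric("idpIds", function(x) standardGeneric("idpIds"))

#' @rdname InteractionDataset-class
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname EvaluationReport-class
#' @param x An \linkS4class{EvaluationReport}.
#' @export
setGeneric("perRepeat", function(x) standardGeneric("perRepeat"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("aggregated", function(x) standardGeneric("aggregated"))
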