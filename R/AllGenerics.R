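#' @rdname ToxicityStudy
#' @param x a `ToxicityStudy`.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ToxicityStudy
#' @export
setGeneric("occurrence", function(x) standardGeneric("occurrence"))

#' @rdname ToxicityStudy
#' @export
setGeneric("sampleDrugs", function(x) standardGeneric("sampleDrugs"))

#' @rdname ToxicityStudy
#' @export
setGeneric("sampleOrgans", function(x) standardGeneric("sampleOrgans"))

#' @rdname ToxicityStudy
#' @export
setGeneric("findingNames", function(x) standardGeneric("findingNames"))

#' Predict pathology prediction scores (PPS)
#'
#' @param object a trained model.
#' @param expr expression matrix, samples x genes (canonical text layout), or
#'   a [ToxicityStudy-class].
#' @param ... further arguments.
#' @return numeric PPS per sample (for a [PathologyModel-class]) or a
#'   samples x findings matrix (for an [IntegrativeToxModel-class]).
#' @export
setGeneric("predictPPS", function(object, expr, ...) standardGeneric("predictPPS"))
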