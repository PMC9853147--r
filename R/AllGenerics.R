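#' @rdname ItemBank-accessors
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname ItemBank-accessors
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname ItemBank-accessors
#' @export
setGeneric("difficulties", function(x, ...) standardGeneric("difficulties"))

#' @rdname ItemBank-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname ItemBank-accessors
#' @export
setGeneric("itemData", function(x) standardGeneric("itemData"))

#' @rdname ReferenceCurve-eval
#' @export
setGeneric("curveMedian", function(curve, age) standardGeneric("curveMedian"))

#' @rdname ReferenceCurve-eval
#' @export
setGeneric("curveSD", function(curve, age) standardGeneric("curveSD"))

#' @rdname ReferenceCurve-eval
#' @export
setGeneric("ageSpan", function(curve) standardGeneric("ageSpan"))

#' @rdname Form-accessors
#' @export
setGeneric("formItems", function(x) standardGeneric("formItems"))

#' @rdname Form-accessors
#' @export
setGeneric("formGroups", function(x) standardGeneric("formGroups"))

#' @rdname Form-accessors
#' @export
setGeneric("startRule", function(x) standardGeneric("startRule"))

#' @rdname Form-accessors
#' @export
setGeneric("stopRuleK", function(x) standardGeneric("stopRuleK"))

#' @rdname Form-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
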