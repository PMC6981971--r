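#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @export
setGeneric("maf", function(x) standardGeneric("maf"))

#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @export
setGeneric("markerEffects", function(object) standardGeneric("markerEffects"))

#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))
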