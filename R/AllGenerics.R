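#' @rdname TrioCallSet-accessors
#' @export
setGeneric("callsetName", function(x) standardGeneric("callsetName"))

#' @rdname TrioCallSet-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname TrioCallSet-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname TrioCallSet-accessors
#' @export
setGeneric("skipLog", function(x) standardGeneric("skipLog"))

#' @rdname TrioCallSet-accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname TiTvSummary-accessors
#' @export
setGeneric("nTransitions", function(x) standardGeneric("nTransitions"))

#' @rdname TiTvSummary-accessors
#' @export
setGeneric("nTransversions", function(x) standardGeneric("nTransversions"))

#' @rdname TiTvSummary-accessors
#' @export
setGeneric("titvRatio", function(x) standardGeneric("titvRatio"))
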