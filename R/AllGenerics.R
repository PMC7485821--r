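#' Accessors for segbo objects
#'
#' Small accessor generics so slots are never reached into directly:
#' `specNames` and `spaceDim` describe a [SearchSpace-class]; `boTrace`,
#' `bestConfiguration`, `bestQS` and `terminatedReason` read a
#' [BOResult-class]; `sampleImage` and `sampleMasks` read a
#' [SyntheticSample-class]; `objectMeasurements` reads a
#' [PipelineResult-class].
#'
#' @param x An object of the documented class.
#' @param class For `sampleMasks`/`objectMeasurements`, which mask class or
#'   object class to return (NULL returns the full list).
#' @return The accessed component.
#' @examples
#' sp <- defaultSearchSpace()
#' specNames(sp)
#' spaceDim(sp)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("specNames", function(x) standardGeneric("specNames"))
#' @rdname accessors
#' @export
setGeneric("spaceDim", function(x) standardGeneric("spaceDim"))
#' @rdname accessors
#' @export
setGeneric("boTrace", function(x) standardGeneric("boTrace"))
#' @rdname accessors
#' @export
setGeneric("bestConfiguration", function(x) standardGeneric("bestConfiguration"))
#' @rdname accessors
#' @export
setGeneric("bestQS", function(x) standardGeneric("bestQS"))
#' @rdname accessors
#' @export
setGeneric("terminatedReason", function(x) standardGeneric("terminatedReason"))
#' @rdname accessors
#' @export
setGeneric("sampleImage", function(x) standardGeneric("sampleImage"))
#' @rdname accessors
#' @export
setGeneric("sampleMasks", function(x, class = NULL) standardGeneric("sampleMasks"))
#' @rdname accessors
#' @export
setGeneric("objectMeasurements",
           function(x, class = NULL) standardGeneric("objectMeasurements"))

#' @rdname accessors
#' @export
setMethod("specNames", "SearchSpace",
          function(x) vapply(x@specs, function(s) s@name, character(1)))
#' @rdname accessors
#' @export
setMethod("spaceDim", "SearchSpace", function(x) length(x@specs))
#' @rdname accessors
#' @export
setMethod("boTrace", "BOResult", function(x) x@trace)
#' @rdname accessors
#' @export
setMethod("bestConfiguration", "BOResult", function(x) x@best$configuration)
#' @rdname accessors
#' @export
setMethod("bestQS", "BOResult", function(x) x@best$qs)
#' @rdname accessors
#' @export
setMethod("terminatedReason", "BOResult", function(x) x@terminatedReason)
#' @rdname accessors
#' @export
setMethod("sampleImage", "SyntheticSample", function(x) x@image)
#' @rdname accessors
#' @export
setMethod("sampleMasks", "SyntheticSample", function(x, class = NULL) {
  if (is.null(class)) return(x@masks)
  if (!class %in% names(x@masks))
    stop("unknown mask class '", class, "'")
  x@masks[[class]]
})
#' @rdname accessors
#' @export
setMethod("objectMeasurements", "PipelineResult", function(x, class = NULL) {
  if (is.null(class)) return(x@measurements)
  if (!class %in% names(x@measurements))
    stop("unknown object class '", class, "'")
  x@measurements[[class]]
})
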