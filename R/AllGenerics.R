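#' Accessors for dollotrace classes
#'
#' Small accessor generics so that user code never reaches into slots.
#'
#' @param object a dollotrace S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesName", function(object) standardGeneric("speciesName"))

#' @rdname accessors
#' @export
setGeneric("locusFeatures", function(object) standardGeneric("locusFeatures"))

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(object) standardGeneric("geneSymbols"))

#' @rdname accessors
#' @export
setGeneric("windowStatus", function(object) standardGeneric("windowStatus"))

#' @rdname accessors
#' @export
setGeneric("callStatus", function(object) standardGeneric("callStatus"))

#' @rdname accessors
#' @export
setGeneric("lesions", function(object) standardGeneric("lesions"))

#' @rdname accessors
#' @export
setGeneric("integrityStatus", function(object) standardGeneric("integrityStatus"))

#' @rdname accessors
#' @export
setGeneric("nmdPredicted", function(object) standardGeneric("nmdPredicted"))

#' @rdname accessors
#' @export
setGeneric("truncatesRod", function(object) standardGeneric("truncatesRod"))

#' @rdname accessors
#' @export
setGeneric("functionalCall", function(object) standardGeneric("functionalCall"))

#' @rdname accessors
#' @export
setGeneric("presenceStates", function(object) standardGeneric("presenceStates"))

#' @rdname accessors
#' @export
setGeneric("gainEdge", function(object) standardGeneric("gainEdge"))

#' @rdname accessors
#' @export
setGeneric("lossEdges", function(object) standardGeneric("lossEdges"))

#' @rdname accessors
#' @export
setGeneric("eventIntervals", function(object) standardGeneric("eventIntervals"))

#' @rdname accessors
#' @export
setMethod("speciesName", "LocusMap", function(object) object@species)

#' @rdname accessors
#' @export
setMethod("speciesName", "CodingModel", function(object) object@species)

#' @rdname accessors
#' @export
setMethod("speciesName", "IntegrityReport", function(object) object@species)

#' @rdname accessors
#' @export
setMethod("locusFeatures", "LocusMap", function(object) object@features)

#' @rdname accessors
#' @export
setMethod("locusFeatures", "GeneWindow", function(object) object@features)

#' @rdname accessors
#' @export
setMethod("geneSymbols", "LocusMap",
          function(object) S4Vectors::mcols(object@features)$symbol)

#' @rdname accessors
#' @export
setMethod("geneSymbols", "GeneWindow",
          function(object) S4Vectors::mcols(object@features)$symbol)

#' @rdname accessors
#' @export
setMethod("windowStatus", "GeneWindow", function(object) object@status)

#' @rdname accessors
#' @export
setMethod("callStatus", "OrthologCall", function(object) object@status)

#' @rdname accessors
#' @export
setMethod("lesions", "IntegrityReport", function(object) object@lesions)

#' @rdname accessors
#' @export
setMethod("integrityStatus", "IntegrityReport",
          function(object) object@status)

#' @rdname accessors
#' @export
setMethod("nmdPredicted", "IntegrityReport",
          function(object) object@nmdPredicted)

#' @rdname accessors
#' @export
setMethod("truncatesRod", "IntegrityReport",
          function(object) object@truncatesRod)

#' @rdname accessors
#' @export
setMethod("functionalCall", "IntegrityReport",
          function(object) object@functionalCall)

#' @rdname accessors
#' @export
setMethod("presenceStates", "PresenceMatrix", function(object) object@states)

#' @rdname accessors
#' @export
setMethod("gainEdge", "EventSet", function(object) object@gainEdge)

#' @rdname accessors
#' @export
setMethod("lossEdges", "EventSet", function(object) object@lossEdges)

#' @rdname accessors
#' @export
setMethod("eventIntervals", "EventSet", function(object) object@intervals)
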