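#' @rdname SystemLayout-class
#' @param object,x an object.
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname SystemLayout-class
#' @export
setGeneric("gridCoords", function(object) standardGeneric("gridCoords"))

#' @rdname SystemLayout-class
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @rdname WeightedRelation-class
#' @export
setGeneric("relationMatrix", function(object) standardGeneric("relationMatrix"))

#' @rdname WeightedRelation-class
#' @export
setGeneric("relationLabels", function(object) standardGeneric("relationLabels"))

#' @rdname TypicalData-class
#' @export
setGeneric("stateMatrix", function(object) standardGeneric("stateMatrix"))

#' @rdname TypicalData-class
#' @export
setGeneric("repertoire", function(object) standardGeneric("repertoire"))

#' @rdname TypicalData-class
#' @export
setGeneric("systemLayout", function(object) standardGeneric("systemLayout"))

#' @rdname TypicalData-class
#' @export
setGeneric("nObservations", function(object) standardGeneric("nObservations"))

#' @rdname StateSpace-class
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @rdname StateSpace-class
#' @export
setGeneric("stateProb", function(object) standardGeneric("stateProb"))

#' @rdname StateSpace-class
#' @param value replacement value.
#' @export
setGeneric("stateProb<-", function(object, value) standardGeneric("stateProb<-"))

#' @rdname EfeResult-class
#' @param object an object.
#' @export
setGeneric("efeValue", function(object) standardGeneric("efeValue"))

#' @rdname EfeResult-class
#' @export
setGeneric("feValues", function(object) standardGeneric("feValues"))

#' @rdname StatePartition-class
#' @param object an object.
#' @export
setGeneric("partitionBlocks", function(object) standardGeneric("partitionBlocks"))

#' @rdname StatePartition-class
#' @export
setGeneric("partitionSeeds", function(object) standardGeneric("partitionSeeds"))
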