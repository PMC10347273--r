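# Generics and accessors.  Slot access from user code goes through these.

#' @name accessors
#' @title Accessors for tripletKNN classes
#' @description Small accessor generics for the package's S4 classes.
#' @param x an object.
#' @return the corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("subclassLabels", function(x) standardGeneric("subclassLabels"))

#' @rdname accessors
#' @export
setGeneric("magnifications", function(x) standardGeneric("magnifications"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("foldIndex", function(x) standardGeneric("foldIndex"))

#' @rdname accessors
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))

#' @rdname accessors
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))

#' @rdname accessors
#' @export
setGeneric("foldScope", function(x) standardGeneric("foldScope"))

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname accessors
#' @export
setGeneric("modelDistance", function(x) standardGeneric("modelDistance"))

#' @rdname accessors
#' @export
setGeneric("modelMargin", function(x) standardGeneric("modelMargin"))

#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' @rdname accessors
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @rdname accessors
#' @export
setGeneric("inputDim", function(x) standardGeneric("inputDim"))

#' @rdname accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname accessors
#' @export
setGeneric("neighborEvidence", function(x) standardGeneric("neighborEvidence"))

#' @rdname accessors
#' @export
setGeneric("patientResults", function(x) standardGeneric("patientResults"))

#' @rdname accessors
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @rdname accessors
#' @export
setGeneric("confusionMatrices", function(x) standardGeneric("confusionMatrices"))

#' @rdname accessors
#' @export
setGeneric("metricSummary", function(x) standardGeneric("metricSummary"))

#' @rdname accessors
#' @export
setGeneric("patientGrid", function(x) standardGeneric("patientGrid"))

#' Apply a trained (or identity) embedding model to features
#'
#' @param model an [EmbeddingModel-class].
#' @param x a features matrix (images x input dimension) or a
#'   [PatchCorpus-class] with a features assay.
#' @return an images x embeddingDim numeric matrix (row names = image ids
#'   when available), L2-normalized when the model says so.
#' @export
setGeneric("embedFeatures", function(model, x) standardGeneric("embedFeatures"))
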