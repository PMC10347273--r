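# Accessor and show() methods.

#' @rdname accessors
#' @export
setMethod("imageIds", "PatchCorpus", function(x) {
  as.character(SummarizedExperiment::colData(x)$image_id)
})

#' @rdname accessors
#' @export
setMethod("patientIds", "PatchCorpus", function(x) {
  as.character(SummarizedExperiment::colData(x)$patient_id)
})

#' @rdname accessors
#' @export
setMethod("classLabels", "PatchCorpus", function(x) {
  as.character(SummarizedExperiment::colData(x)$class_label)
})

#' @rdname accessors
#' @export
setMethod("subclassLabels", "PatchCorpus", function(x) {
  as.character(SummarizedExperiment::colData(x)$subclass)
})

#' @rdname accessors
#' @export
setMethod("magnifications", "PatchCorpus", function(x) {
  as.integer(SummarizedExperiment::colData(x)$magnification)
})

#' @rdname accessors
#' @export
setMethod("featureMatrix", "PatchCorpus", function(x) {
  a <- SummarizedExperiment::assay(x, "features")
  if (nrow(a) == 0L) {
    stop("this PatchCorpus is a pure manifest: it carries no features",
         call. = FALSE)
  }
  t(a)  # images x features for downstream linear algebra
})

#' @rdname accessors
#' @export
setMethod("manifest", "PatchCorpus", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname accessors
#' @export
setMethod("provenance", "PatchCorpus", function(x) {
  p <- S4Vectors::metadata(x)$provenance
  if (is.null(p)) "" else p
})

setMethod("show", "PatchCorpus", function(object) {
  cd <- SummarizedExperiment::colData(object)
  nfeat <- nrow(SummarizedExperiment::assay(object, "features"))
  cat(sprintf("PatchCorpus: %d images, %d patients%s\n",
              ncol(object), length(unique(cd$patient_id)),
              if (nfeat > 0) sprintf(", %d features", nfeat) else " (manifest only)"))
  if (ncol(object) > 0L) {
    tab <- table(cd$class_label)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    cat("  magnifications:",
        paste(sort(unique(cd$magnification)), collapse = ", "), "\n")
  }
  if (nzchar(provenance(object))) cat("  provenance:", provenance(object), "\n")
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("foldIndex", "FoldSplit", function(x) x@foldIndex)

#' @rdname accessors
#' @export
setMethod("trainIds", "FoldSplit", function(x) x@trainIds)

#' @rdname accessors
#' @export
setMethod("testIds", "FoldSplit", function(x) x@testIds)

#' @rdname accessors
#' @export
setMethod("foldScope", "FoldSplit", function(x) {
  if (x@scope == "MSB") sprintf("MSB(%d)", x@magnification) else "MIB"
})

#' @rdname accessors
#' @export
setMethod("magnifications", "FoldSplit", function(x) x@magnification)

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit %d [%s]: %d train / %d test images\n",
              object@foldIndex, foldScope(object),
              length(object@trainIds), length(object@testIds)))
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("modelWeights", "EmbeddingModel", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("modelDistance", "EmbeddingModel", function(x) x@distance)

#' @rdname accessors
#' @export
setMethod("modelMargin", "EmbeddingModel", function(x) x@margin)

#' @rdname accessors
#' @export
setMethod("lossHistory", "EmbeddingModel", function(x) x@lossHistory)

#' @rdname accessors
#' @export
setMethod("embeddingDim", "EmbeddingModel", function(x) nrow(x@weights))

#' @rdname accessors
#' @export
setMethod("inputDim", "EmbeddingModel", function(x) ncol(x@weights))

setMethod("show", "EmbeddingModel", function(object) {
  cat(sprintf("EmbeddingModel: %d -> %d (%s distance, margin %g%s)\n",
              inputDim(object), embeddingDim(object), object@distance,
              object@margin,
              if (object@normalized) ", L2-normalized" else ""))
  if (length(object@lossHistory)) {
    cat(sprintf("  trained %d epochs; mined-triplet loss %.4g -> %.4g\n",
                length(object@lossHistory),
                object@lossHistory[1L],
                object@lossHistory[length(object@lossHistory)]))
  }
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("predictions", "PredictionSet", function(x) x@predictions)

#' @rdname accessors
#' @export
setMethod("neighborEvidence", "PredictionSet", function(x) x@neighbors)

setMethod("show", "PredictionSet", function(object) {
  p <- object@predictions
  acc <- if (nrow(p)) mean(p$predicted_label == p$true_label) else NA_real_
  cat(sprintf("PredictionSet: %d test images, k=%d (%s), image accuracy %.3f\n",
              nrow(p), object@k, object@distance, acc))
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("patientResults", "EvaluationReport", function(x) x@patientResults)

#' @rdname accessors
#' @export
setMethod("foldMetrics", "EvaluationReport", function(x) x@foldMetrics)

#' @rdname accessors
#' @export
setMethod("confusionMatrices", "EvaluationReport", function(x) x@confusion)

#' @rdname accessors
#' @export
setMethod("metricSummary", "EvaluationReport", function(x) x@summary)

#' @rdname accessors
#' @export
setMethod("patientGrid", "EvaluationReport", function(x) x@grid)

setMethod("show", "EvaluationReport", function(object) {
  s <- object@summary
  pla_row <- s[s$metric == "pla", , drop = FALSE]
  cat(sprintf("EvaluationReport [%s]: %d fold(s)\n", object@tag,
              nrow(object@foldMetrics)))
  if (nrow(pla_row)) {
    cat(sprintf("  PLA %.2f%% +/- %.2f over folds\n",
                100 * pla_row$mean, 100 * pla_row$sd))
  }
  invisible(NULL)
})

setMethod("show", "EmbeddingProjector", function(object) {
  cat(sprintf("EmbeddingProjector [%s]: %d -> 2 (seed %d)\n",
              object@method, object@inputDim, object@seed))
  invisible(NULL)
})
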