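# S4 classes for the corpus, folds, embedding model, predictions,
# evaluation reports and 2-D projectors.

#' PatchCorpus: image patches, their labels and (optionally) their features
#'
#' `PatchCorpus` extends [SummarizedExperiment::SummarizedExperiment] and is
#' the central data container of the package.  Columns are image patches;
#' the (optional) `"features"` assay holds one backbone feature vector per
#' image (features x images, following the Bioconductor convention of
#' samples in columns).  `colData` carries the manifest: `image_id`,
#' `patient_id`, `class_label` (`benign`/`malignant`), `subclass`
#' (`A`/`F`/`TA`/`PT` for benign, `DC`/`LC`/`MC`/`PC` for malignant),
#' `magnification` (40/100/200/400) and `source` (file path or feature-table
#' provenance).  A corpus with a zero-row assay is a pure manifest, e.g. as
#' returned by [parseBreakhisTree()] before feature extraction.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [PatchCorpus()], [featureMatrix()], [readManifest()]
#' @export
setClass("PatchCorpus", contains = "SummarizedExperiment")

setValidity("PatchCorpus", function(object) {
  cd <- SummarizedExperiment::colData(object)
  required <- c("image_id", "patient_id", "class_label", "subclass",
                "magnification", "source")
  missing_cols <- setdiff(required, colnames(cd))
  if (length(missing_cols)) {
    return(sprintf("colData lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  if (ncol(object) == 0L) return(TRUE)
  if (anyDuplicated(cd$image_id)) return("image_id values must be unique")
  if (!all(cd$class_label %in% CLASS_LEVELS)) {
    return("class_label must be 'benign' or 'malignant'")
  }
  if (!all(cd$subclass %in% c(BENIGN_SUBCLASSES, MALIGNANT_SUBCLASSES))) {
    return("unknown subclass code")
  }
  implied <- subclassClass(cd$subclass)
  if (!all(implied == cd$class_label)) {
    bad <- cd$image_id[implied != cd$class_label][1L]
    return(sprintf("subclass/class mismatch for image '%s'", bad))
  }
  if (!all(cd$magnification %in% MAGNIFICATIONS)) {
    return("magnification must be one of 40, 100, 200, 400")
  }
  TRUE
})

#' Construct a PatchCorpus
#'
#' @param manifest a `data.frame` (or `DataFrame`) with columns `image_id`,
#'   `patient_id`, `class_label`, `subclass`, `magnification` and optionally
#'   `source`.
#' @param features optional numeric matrix of backbone features, either
#'   images x features (rows matched to `manifest` order) or
#'   features x images.
#' @param provenance free-text provenance stored in `metadata()`.
#' @return a [PatchCorpus-class] object.
#' @examples
#' mf <- data.frame(image_id = c("i1", "i2"), patient_id = c("p1", "p2"),
#'                  class_label = c("benign", "malignant"),
#'                  subclass = c("TA", "DC"), magnification = c(40L, 40L))
#' PatchCorpus(mf, features = matrix(rnorm(8), nrow = 2))
#' @export
PatchCorpus <- function(manifest, features = NULL, provenance = "") {
  manifest <- as.data.frame(manifest)
  if (is.null(manifest$source)) manifest$source <- NA_character_
  manifest$image_id <- as.character(manifest$image_id)
  manifest$patient_id <- as.character(manifest$patient_id)
  manifest$class_label <- as.character(manifest$class_label)
  manifest$subclass <- as.character(manifest$subclass)
  manifest$magnification <- as.integer(manifest$magnification)
  cd <- S4Vectors::DataFrame(manifest)
  rownames(cd) <- manifest$image_id
  n <- nrow(manifest)
  if (is.null(features)) {
    assay_list <- list(features = matrix(numeric(0), nrow = 0L, ncol = n,
                                         dimnames = list(NULL, manifest$image_id)))
  } else {
    features <- as.matrix(features)
    if (nrow(features) == n && ncol(features) != n) {
      features <- t(features)
    } else if (ncol(features) != n) {
      stop("feature matrix dimensions do not match the manifest")
    }
    colnames(features) <- manifest$image_id
    assay_list <- list(features = features)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assay_list, colData = cd,
    metadata = list(provenance = provenance))
  methods::new("PatchCorpus", se)
}

#' FoldSplit: one patient-disjoint train/test partition
#'
#' @slot foldIndex integer fold number (1-based).
#' @slot trainIds,testIds character vectors of `image_id`s.
#' @slot scope `"MIB"` (all magnifications) or `"MSB"` (one magnification).
#' @slot magnification the magnification an MSB fold is restricted to
#'   (`NA` for MIB).
#' @seealso [FoldSplit()], [validateFold()], [makeDefaultFolds()]
#' @export
setClass("FoldSplit",
  representation(foldIndex = "integer", trainIds = "character",
                 testIds = "character", scope = "character",
                 magnification = "integer"))

setValidity("FoldSplit", function(object) {
  if (length(object@scope) != 1L || !object@scope %in% c("MIB", "MSB")) {
    return("scope must be 'MIB' or 'MSB'")
  }
  if (object@scope == "MSB" && is.na(object@magnification)) {
    return("MSB folds must carry a magnification")
  }
  if (length(intersect(object@trainIds, object@testIds))) {
    return("train and test image ids overlap")
  }
  TRUE
})

#' @rdname FoldSplit-class
#' @param foldIndex,trainIds,testIds,scope,magnification see slots.
#' @export
FoldSplit <- function(foldIndex, trainIds, testIds, scope = "MIB",
                      magnification = NA_integer_) {
  methods::new("FoldSplit", foldIndex = as.integer(foldIndex),
               trainIds = as.character(trainIds),
               testIds = as.character(testIds),
               scope = scope, magnification = as.integer(magnification))
}

#' EmbeddingModel: the trainable linear map and its metric
#'
#' The single trainable component of the pipeline: a bias-free linear map
#' from backbone-feature space (2048-dim by convention) to embedding space
#' (512-dim by default), together with the distance used both for triplet
#' mining and k-NN classification, the triplet margin, and an optional
#' L2-normalization flag.
#'
#' @slot weights numeric matrix, `embeddingDim x inputDim`.
#' @slot distance `"euclidean"` or `"cosine"`.
#' @slot margin positive triplet margin `m`.
#' @slot normalized logical; L2-normalize embeddings after projection.
#' @slot config list: the [trainConfig()] used (empty before training).
#' @slot lossHistory numeric vector of per-epoch mean mined-triplet losses.
#' @seealso [embeddingModel()], [trainEmbedding()], [embedFeatures()]
#' @export
setClass("EmbeddingModel",
  representation(weights = "matrix", distance = "character",
                 margin = "numeric", normalized = "logical",
                 config = "list", lossHistory = "numeric"))

setValidity("EmbeddingModel", function(object) {
  if (!object@distance %in% c("euclidean", "cosine")) {
    return("distance must be 'euclidean' or 'cosine'")
  }
  if (object@margin <= 0) return("margin must be positive")
  TRUE
})

#' PredictionSet: k-NN predictions plus their neighbour evidence
#'
#' @slot predictions `DataFrame` with one row per test image: `image_id`,
#'   `patient_id`, `true_label`, `predicted_label`, `score` (fraction of the
#'   k neighbours labelled benign; benign is the positive class).
#' @slot neighbors long-format `DataFrame` of evidence: `image_id`, `rank`,
#'   `neighbor_id`, `distance`, `neighbor_label`.
#' @slot k integer neighbourhood size actually used.
#' @slot distance distance name.
#' @seealso [knnPredict()], [explainPrediction()]
#' @export
setClass("PredictionSet",
  representation(predictions = "DataFrame", neighbors = "DataFrame",
                 k = "integer", distance = "character"))

#' EvaluationReport: fold-level and aggregated patient-level evaluation
#'
#' @slot patientResults `DataFrame` of per-patient results across folds:
#'   `fold`, `patient_id`, `n_images`, `n_correct`, `patient_score`,
#'   `assigned_label`, `true_label`, `fraction_malignant`.
#' @slot foldMetrics `data.frame`, one row per fold: `fold`, `pla`,
#'   `accuracy`, `precision`, `recall`, `f1`, `auc`, `n_test`, `n_patients`.
#' @slot confusion list with `perFold` (list of 2x2 matrices, rows = truth,
#'   cols = prediction) and `average` (element-wise mean).
#' @slot summary `data.frame` with `metric`, `mean`, `sd` rows for every
#'   scalar metric (sample sd over folds).
#' @slot grid `data.frame`: the patient x fold grid of
#'   fraction-labelled-malignant values and assigned labels.
#' @slot tag free-text tag (`"main"` or `"ablation"`, plus scope).
#' @seealso [foldAverage()], [runMIB()]
#' @export
setClass("EvaluationReport",
  representation(patientResults = "DataFrame", foldMetrics = "data.frame",
                 confusion = "list", summary = "data.frame",
                 grid = "data.frame", tag = "character"))

#' EmbeddingProjector: a reusable 2-D projector fitted on training embeddings
#'
#' Fitted on TRAIN embeddings only; test and foreign corpora are transformed
#' out-of-sample so they can never influence the projection basis.
#'
#' @slot method projection method name (`"pca"`).
#' @slot center numeric centring vector (input dimension).
#' @slot rotation numeric matrix, input dimension x 2.
#' @slot inputDim expected embedding dimensionality.
#' @slot seed integer seed recorded for provenance.
#' @slot params list of method parameters.
#' @seealso [fitProjection()], [projectEmbeddings()]
#' @export
setClass("EmbeddingProjector",
  representation(method = "character", center = "numeric",
                 rotation = "matrix", inputDim = "integer",
                 seed = "integer", params = "list"))
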