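# Interpretability artifacts: 2-D projection of embeddings, per-patient
# views, nearest-neighbour explanations and out-of-distribution summaries.
#
# The projector contract is "a reusable 2-D projector fitted on TRAIN
# embeddings only, applying out-of-sample to anything else".  The
# implementation is PCA: the package's separation claims live in the full
# embedding space, the 2-D view is presentation, and a linear projector
# keeps the view deterministic and honest (test/foreign points can never
# reshape the basis).

#' Fit a 2-D projector on training embeddings
#'
#' @param embeddings numeric matrix (rows = training images).  At least 10
#'   points are required.
#' @param method projection method; `"pca"` is implemented.
#' @param seed integer recorded in the projector (PCA itself is
#'   deterministic; the seed keeps provenance uniform across methods).
#' @param params list of extra parameters recorded for provenance.
#' @return an [EmbeddingProjector-class].
#' @export
fitProjection <- function(embeddings, method = "pca", seed = 1L,
                          params = list()) {
  x <- as.matrix(embeddings)
  if (nrow(x) < 10L) stop("need at least 10 training points to fit a projection")
  method <- match.arg(method, "pca")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
  methods::new("EmbeddingProjector", method = method,
               center = as.numeric(pc$center),
               rotation = pc$rotation[, 1:2, drop = FALSE],
               inputDim = ncol(x), seed = as.integer(seed), params = params)
}

#' Project embeddings through a fitted projector
#'
#' @param projector an [EmbeddingProjector-class].
#' @param embeddings numeric matrix with `inputDim(projector)` columns.
#' @param role `"train"`, `"test"` or `"foreign"`; rendered distinctly and
#'   used by [patientView()] and [oodSeparation()].
#' @param labels,patients optional per-row class labels and patient ids.
#' @return a `data.frame` (`image_id`, `x`, `y`, `role`, `label`,
#'   `patient_id`) with finite coordinates.
#' @export
projectEmbeddings <- function(projector, embeddings,
                              role = c("test", "train", "foreign"),
                              labels = NULL, patients = NULL) {
  role <- match.arg(role)
  x <- as.matrix(embeddings)
  if (ncol(x) != projector@inputDim) {
    stop(sprintf("embeddings have %d columns; projector expects %d",
                 ncol(x), projector@inputDim))
  }
  coords <- sweep(x, 2L, projector@center) %*% projector@rotation
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("%s_%d", role, seq_len(nrow(x)))
  data.frame(image_id = ids, x = coords[, 1L], y = coords[, 2L],
             role = role,
             label = if (is.null(labels)) NA_character_ else as.character(labels),
             patient_id = if (is.null(patients)) NA_character_ else as.character(patients),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Highlight one patient against the training background
#'
#' Reports where a patient's projected points fall relative to the benign
#' and malignant training centroids — the view used to spot "straddling"
#' patients whose images occupy both class regions.
#'
#' @param projection a `data.frame` combining projected rows (e.g.
#'   `rbind(projectEmbeddings(..., "train"), projectEmbeddings(..., "test"))`)
#'   with labelled train rows present.
#' @param patientId the patient to highlight.
#' @return a list: `points` (the patient's rows), `centroids` (2x2 matrix),
#'   `n_near_benign`, `n_near_malignant`.
#' @export
patientView <- function(projection, patientId) {
  sel <- projection$patient_id == patientId & !is.na(projection$patient_id)
  if (!any(sel)) stop(sprintf("unknown patient '%s'", patientId))
  train <- projection[projection$role == "train" & !is.na(projection$label), ,
                      drop = FALSE]
  if (!nrow(train)) stop("projection contains no labelled train rows")
  cent <- vapply(CLASS_LEVELS, function(cl) {
    s <- train[train$label == cl, , drop = FALSE]
    c(mean(s$x), mean(s$y))
  }, numeric(2))
  pts <- projection[sel, , drop = FALSE]
  d_b <- sqrt((pts$x - cent[1, "benign"])^2 + (pts$y - cent[2, "benign"])^2)
  d_m <- sqrt((pts$x - cent[1, "malignant"])^2 + (pts$y - cent[2, "malignant"])^2)
  list(points = pts, centroids = t(cent),
       n_near_benign = sum(d_b < d_m), n_near_malignant = sum(d_m <= d_b))
}

#' Explanation bundle for one prediction
#'
#' The k training neighbours (ordered by distance) that produced a test
#' image's label — the per-prediction evidence a reviewer inspects.
#'
#' @param ps a [PredictionSet-class].
#' @param imageId a test image id present in `ps`.
#' @return a list of class `"ExplanationBundle"`: `image_id`,
#'   `predicted_label`, `score`, `neighbors` (data.frame with `rank`,
#'   `neighbor_id`, `distance`, `neighbor_label`).
#' @export
explainPrediction <- function(ps, imageId) {
  p <- as.data.frame(predictions(ps))
  if (!imageId %in% p$image_id) {
    stop(sprintf("image '%s' is not in this prediction set", imageId))
  }
  nb <- as.data.frame(neighborEvidence(ps))
  nb <- nb[nb$image_id == imageId, c("rank", "neighbor_id", "distance",
                                     "neighbor_label"), drop = FALSE]
  nb <- nb[order(nb$rank), , drop = FALSE]
  rownames(nb) <- NULL
  row <- p[p$image_id == imageId, , drop = FALSE]
  structure(list(image_id = imageId, predicted_label = row$predicted_label,
                 score = row$score, neighbors = nb),
            class = "ExplanationBundle")
}

#' @export
print.ExplanationBundle <- function(x, ...) {
  cat(sprintf("Explanation for '%s': predicted %s (benign score %.3f)\n",
              x$image_id, x$predicted_label, x$score))
  print(x$neighbors, row.names = FALSE)
  invisible(x)
}

#' Write and read explanation bundles
#'
#' @param bundle an `"ExplanationBundle"` from [explainPrediction()].
#' @param path file path (tab-delimited; round-trippable).
#' @return `writeExplanation` returns `path` invisibly; `readExplanation`
#'   the restored bundle.
#' @export
writeExplanation <- function(bundle, path) {
  out <- cbind(data.frame(image_id = bundle$image_id,
                          predicted_label = bundle$predicted_label,
                          score = bundle$score),
               bundle$neighbors)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname writeExplanation
#' @export
readExplanation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  structure(list(image_id = dt$image_id[1L],
                 predicted_label = dt$predicted_label[1L],
                 score = dt$score[1L],
                 neighbors = dt[, c("rank", "neighbor_id", "distance",
                                    "neighbor_label"), drop = FALSE]),
            class = "ExplanationBundle")
}

#' Write a projection as delimited text
#'
#' @param projection the `data.frame` from [projectEmbeddings()] (or several
#'   rbound together).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProjection <- function(projection, path) {
  data.table::fwrite(projection, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Out-of-distribution separation summary
#'
#' Quantifies the qualitative "foreign corpora land far from the training
#' clusters" check: for each projected foreign point, its distance to the
#' nearest projected train point is compared with the train set's median
#' nearest-neighbour distance.
#'
#' @param projection a `data.frame` with `role == "train"` and
#'   `role == "foreign"` rows.
#' @return a list: `fraction_beyond` (foreign points farther from every
#'   train point than the threshold), `threshold` (train median NN
#'   distance), `min_distances` per foreign point.
#' @export
oodSeparation <- function(projection) {
  tr <- as.matrix(projection[projection$role == "train", c("x", "y")])
  fo <- as.matrix(projection[projection$role == "foreign", c("x", "y")])
  if (!nrow(tr)) stop("projection has no train rows")
  if (!nrow(fo)) stop("projection has no foreign rows")
  D_tt <- pairwiseDistances(tr, tr, "euclidean")
  diag(D_tt) <- Inf
  threshold <- stats::median(apply(D_tt, 1L, min))
  D_ft <- pairwiseDistances(fo, tr, "euclidean")
  min_d <- apply(D_ft, 1L, min)
  list(fraction_beyond = mean(min_d > threshold), threshold = threshold,
       min_distances = min_d)
}

#' Plot a projection (train/test/foreign roles, class colours)
#'
#' @param projection a `data.frame` from [projectEmbeddings()].
#' @return a ggplot object.
#' @export
plotProjection <- function(projection) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package")
  }
  ggplot2::ggplot(projection,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$label, shape = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "projection 1", y = "projection 2",
                  colour = "class", shape = "role") +
    ggplot2::theme_minimal()
}
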