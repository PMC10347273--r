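# k-nearest-neighbour classification in embedding space, with neighbour
# evidence retained for every prediction.

#' k-NN prediction over training embeddings
#'
#' Majority vote among the `k` nearest training embeddings.  The positive
#' class is benign: `score` is the fraction of the k neighbours labelled
#' benign.  Vote ties predict malignant (the conservative choice for the
#' clinical framing: missing a malignancy is the costly error).  Equidistant
#' neighbours competing at the k-th rank are resolved by the stable order of
#' the training rows.
#'
#' @param trainEmbeddings,testEmbeddings numeric matrices (rows = images)
#'   with matching column counts; row names are used as image ids when set.
#' @param trainLabels class label per training row.
#' @param k neighbourhood size (default 3); values larger than the training
#'   set are clamped with a warning.
#' @param distance `"euclidean"` or `"cosine"`.
#' @param testLabels,testPatients optional truth and patient ids per test
#'   row, carried into the result for evaluation.
#' @return a [PredictionSet-class].
#' @export
knnPredict <- function(trainEmbeddings, trainLabels, testEmbeddings, k = 3L,
                       distance = c("euclidean", "cosine"),
                       testLabels = NULL, testPatients = NULL) {
  distance <- match.arg(distance)
  tr <- as.matrix(trainEmbeddings)
  te <- as.matrix(testEmbeddings)
  n_train <- nrow(tr)
  n_test <- nrow(te)
  if (n_train == 0L) stop("training set is empty")
  stopifnot(length(trainLabels) == n_train)
  k <- assertCount(k, "k")
  if (k > n_train) {
    warning(sprintf("k=%d exceeds the training size %d; clamped", k, n_train))
    k <- n_train
  }
  train_ids <- rownames(tr)
  if (is.null(train_ids)) train_ids <- sprintf("train_%d", seq_len(n_train))
  test_ids <- rownames(te)
  if (is.null(test_ids)) test_ids <- sprintf("test_%d", seq_len(n_test))
  if (is.null(testLabels)) testLabels <- rep(NA_character_, n_test)
  if (is.null(testPatients)) testPatients <- rep(NA_character_, n_test)

  if (n_test == 0L) {
    return(methods::new("PredictionSet",
      predictions = S4Vectors::DataFrame(image_id = character(0),
        patient_id = character(0), true_label = character(0),
        predicted_label = character(0), score = numeric(0)),
      neighbors = S4Vectors::DataFrame(image_id = character(0),
        rank = integer(0), neighbor_id = character(0),
        distance = numeric(0), neighbor_label = character(0)),
      k = k, distance = distance))
  }

  D <- pairwiseDistances(te, tr, distance)
  pred <- character(n_test)
  score <- numeric(n_test)
  nb_rows <- vector("list", n_test)
  for (i in seq_len(n_test)) {
    ord <- order(D[i, ], seq_len(n_train))[seq_len(k)]  # stable in train order
    lab <- trainLabels[ord]
    n_benign <- sum(lab == "benign")
    score[i] <- n_benign / k
    pred[i] <- if (n_benign > k - n_benign) "benign" else "malignant"
    nb_rows[[i]] <- data.frame(image_id = test_ids[i], rank = seq_len(k),
                               neighbor_id = train_ids[ord],
                               distance = D[i, ord], neighbor_label = lab,
                               stringsAsFactors = FALSE)
  }
  methods::new("PredictionSet",
    predictions = S4Vectors::DataFrame(
      image_id = test_ids, patient_id = as.character(testPatients),
      true_label = as.character(testLabels), predicted_label = pred,
      score = score, row.names = test_ids),
    neighbors = S4Vectors::DataFrame(do.call(rbind, nb_rows)),
    k = k, distance = distance)
}

#' Sweep the neighbourhood size k
#'
#' Recomputes image-level accuracy and patient-level accuracy for each value
#' of `k`, reproducing the flat accuracy-vs-k behaviour seen on
#' well-separated embeddings.
#'
#' @inheritParams knnPredict
#' @param testLabels truth per test row (required here).
#' @param testPatients patient id per test row (required for PLA).
#' @param ks vector of k values (non-empty).
#' @return a `data.frame` with columns `k`, `image_accuracy`, `pla`.
#' @export
kSweep <- function(trainEmbeddings, trainLabels, testEmbeddings, testLabels,
                   testPatients, ks, distance = c("euclidean", "cosine")) {
  distance <- match.arg(distance)
  if (!length(ks)) stop("k list must be non-empty")
  rows <- lapply(ks, function(k) {
    ps <- suppressWarnings(
      knnPredict(trainEmbeddings, trainLabels, testEmbeddings, k = k,
                 distance = distance, testLabels = testLabels,
                 testPatients = testPatients))
    p <- predictions(ps)
    data.frame(k = k,
               image_accuracy = mean(p$predicted_label == p$true_label),
               pla = pla(patientScores(ps)))
  })
  do.call(rbind, rows)
}

#' Write predictions (with neighbour evidence) as delimited text
#'
#' @param ps a [PredictionSet-class].
#' @param path output path for the per-image table; the k neighbour ids and
#'   distances are packed into `neighbors` as `id:distance` pairs separated
#'   by `;`.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(ps, path) {
  p <- as.data.frame(predictions(ps))
  nb <- as.data.frame(neighborEvidence(ps))
  packed <- vapply(split(nb, factor(nb$image_id, levels = p$image_id)),
                   function(s) {
                     s <- s[order(s$rank), , drop = FALSE]
                     paste(sprintf("%s:%.8g", s$neighbor_id, s$distance),
                           collapse = ";")
                   }, character(1))
  p$neighbors <- unname(packed)
  data.table::fwrite(p, path, sep = "\t", quote = FALSE)
  invisible(path)
}
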