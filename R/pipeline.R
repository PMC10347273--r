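# End-to-end orchestration: magnification-independent (MIB),
# magnification-specific (MSB) and ablation runs over patient-disjoint
# folds, with per-run artifacts and machine-readable metadata.

#' Configuration for an end-to-end run
#'
#' @param mode `"MIB"`, `"MSB"`, `"ablation_MIB"` or `"ablation_MSB"`.
#' @param k neighbourhood size for the main pipeline (default 3, used for
#'   both MIB and MSB).
#' @param kMapAblation per-magnification k for the ablation MSB pipeline
#'   (defaults 3/7/5/9 for 40/100/200/400, the values at which raw-feature
#'   k-NN performs best per magnification).
#' @param kAblationMIB k for the ablation MIB pipeline.
#' @param embeddingDim embedding width; `NULL` picks `min(512, inputDim/4)`
#'   mirroring the 2048 -> 512 published geometry.
#' @param distance `"euclidean"` or `"cosine"`.
#' @param margin triplet margin.
#' @param normalized L2-normalize embeddings.
#' @param train a [trainConfig()].
#' @param seed base seed; per-fold seeds are derived from it.
#' @return a list of class `"RunConfig"`.
#' @export
runConfig <- function(mode = c("MIB", "MSB", "ablation_MIB", "ablation_MSB"),
                      k = 3L,
                      kMapAblation = c("40" = 3L, "100" = 7L, "200" = 5L,
                                       "400" = 9L),
                      kAblationMIB = 3L,
                      embeddingDim = NULL,
                      distance = c("euclidean", "cosine"),
                      margin = 0.2, normalized = FALSE,
                      train = trainConfig(), seed = 1L) {
  cfg <- list(mode = match.arg(mode), k = assertCount(k, "k"),
              kMapAblation = kMapAblation,
              kAblationMIB = assertCount(kAblationMIB, "kAblationMIB"),
              embeddingDim = embeddingDim,
              distance = match.arg(distance),
              margin = assertPositive(margin, "margin"),
              normalized = isTRUE(normalized),
              train = train, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

resolveEmbeddingDim <- function(cfg, inputDim) {
  if (!is.null(cfg$embeddingDim)) return(assertCount(cfg$embeddingDim, "embeddingDim"))
  max(2L, min(512L, inputDim %/% 4L))
}

# Run one fold: (optionally) train the embedding, embed train/test, k-NN,
# evaluate.  Errors are re-signalled naming the fold and stage.
runFold <- function(corpus, fold, cfg, ablation, k) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("fold %d, stage '%s': %s", foldIndex(fold), name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  x <- featureMatrix(corpus)
  mf <- manifest(corpus)
  tr_ids <- trainIds(fold); te_ids <- testIds(fold)
  stage("validate", {
    v <- validateFold(fold, corpus)
    if (!v$pass) stop(paste(v$messages, collapse = "; "))
    if (!length(te_ids)) stop("fold has no test images")
  })
  lab <- setNames(mf$class_label, mf$image_id)
  pat <- setNames(mf$patient_id, mf$image_id)
  x_tr <- x[tr_ids, , drop = FALSE]
  x_te <- x[te_ids, , drop = FALSE]
  model <- NULL
  if (ablation) {
    e_tr <- x_tr; e_te <- x_te  # identity embedding on raw features
  } else {
    model <- stage("train_embedding", {
      init <- embeddingModel(inputDim = ncol(x),
                             embeddingDim = resolveEmbeddingDim(cfg, ncol(x)),
                             distance = cfg$distance, margin = cfg$margin,
                             normalized = cfg$normalized,
                             seed = deriveSeed(cfg$seed, foldIndex(fold)))
      tc <- cfg$train
      tc$seed <- deriveSeed(cfg$seed, 100L + foldIndex(fold))
      trainEmbedding(x_tr, lab[tr_ids], tc, init)
    })
    e_tr <- stage("embed", embedFeatures(model, x_tr))
    e_te <- stage("embed", embedFeatures(model, x_te))
  }
  ps <- stage("knn", suppressWarnings(
    knnPredict(e_tr, lab[tr_ids], e_te, k = k, distance = cfg$distance,
               testLabels = lab[te_ids], testPatients = pat[te_ids])))
  rep <- stage("evaluate", evaluateFold(ps, foldIndex(fold)))
  list(report = rep, model = model, predictions = ps)
}

writeRunMetadata <- function(outputDir, cfg, extra = list()) {
  meta <- c(list(config = unclass(cfg),
                 package_version = as.character(utils::packageVersion("tripletKNN")),
                 r_version = R.version.string), extra)
  meta$config$train <- unclass(meta$config$train)
  jsonlite::write_json(meta, file.path(outputDir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

runFoldSet <- function(corpus, folds, cfg, ablation, tag, k, outputDir) {
  if (!is.null(outputDir)) dir.create(outputDir, recursive = TRUE,
                                      showWarnings = FALSE)
  results <- lapply(folds, function(f) runFold(corpus, f, cfg, ablation, k))
  report <- foldAverage(lapply(results, `[[`, "report"), tag = tag)
  if (!is.null(outputDir)) {
    for (i in seq_along(results)) {
      f <- foldIndex(folds[[i]])
      writePredictions(results[[i]]$predictions,
                       file.path(outputDir, sprintf("fold%d_predictions.tsv", f)))
      if (!ablation && !is.null(results[[i]]$model)) {
        writeEmbeddingModel(results[[i]]$model,
                            file.path(outputDir, sprintf("fold%d_model.txt", f)))
      }
    }
    writeEvaluationReport(report, file.path(outputDir, "report"))
    writeRunMetadata(outputDir, cfg, list(tag = tag, n_folds = length(folds)))
  }
  attr(report, "models") <- lapply(results, `[[`, "model")
  attr(report, "predictions") <- lapply(results, `[[`, "predictions")
  report
}

#' Run the magnification-independent (MIB) pipeline
#'
#' For each fold: train the embedding layer on the training images (all
#' magnifications pooled), embed train and test, classify with k-NN, and
#' evaluate at the patient level; then aggregate over folds.
#'
#' @param corpus a [PatchCorpus-class] with features.
#' @param folds a list of [FoldSplit-class] (typically 5).
#' @param cfg a [runConfig()].
#' @param outputDir optional run directory; when given, per-fold models and
#'   predictions, the evaluation report and a `metadata.json` are written.
#' @return an [EvaluationReport-class]; trained per-fold models and
#'   prediction sets are attached as attributes `"models"` and
#'   `"predictions"`.
#' @export
runMIB <- function(corpus, folds, cfg = runConfig("MIB"), outputDir = NULL) {
  runFoldSet(corpus, folds, cfg, ablation = FALSE, tag = "main MIB",
             k = cfg$k, outputDir = outputDir)
}

#' Run the magnification-specific (MSB) pipeline
#'
#' Trains and evaluates one independent classifier per magnification on
#' magnification-restricted folds.  Magnifications with no test patients
#' are skipped with a warning.
#'
#' @inheritParams runMIB
#' @return a named list of [EvaluationReport-class] (one per magnification
#'   present), with a `summary` attribute: one row per magnification in
#'   mean +/- sd form.
#' @export
runMSB <- function(corpus, folds, cfg = runConfig("MSB"), outputDir = NULL) {
  mags <- sort(unique(magnifications(corpus)))
  reports <- list()
  for (m in MAGNIFICATIONS) {
    if (!m %in% mags) {
      warning(sprintf("magnification %dx absent from corpus; skipped", m))
      next
    }
    sub <- restrictToMagnification(corpus, m)
    folds_m <- lapply(folds, restrictFold, corpus = sub, scope = "MSB",
                      magnification = m)
    has_test <- all(vapply(folds_m, function(f) length(testIds(f)) > 0,
                           logical(1)))
    if (!has_test) {
      warning(sprintf("magnification %dx has a fold with no test images; skipped", m))
      next
    }
    out_m <- if (is.null(outputDir)) NULL else file.path(outputDir, sprintf("mag%d", m))
    reports[[as.character(m)]] <- runFoldSet(
      sub, folds_m, cfg, ablation = FALSE, tag = sprintf("main MSB(%d)", m),
      k = cfg$k, outputDir = out_m)
  }
  if (!length(reports)) stop("no magnification could be evaluated")
  attr(reports, "summary") <- msbSummary(reports)
  if (!is.null(outputDir)) {
    data.table::fwrite(msbSummary(reports),
                       file.path(outputDir, "msb_summary.tsv"),
                       sep = "\t", quote = FALSE)
  }
  reports
}

#' Summary table for an MSB run
#'
#' One row per magnification: PLA and image-level metrics as mean and sd
#' over folds (the customary per-magnification reporting format).
#'
#' @param reports the list returned by [runMSB()] or [runAblation()] with
#'   MSB scope.
#' @return a `data.frame`.
#' @export
msbSummary <- function(reports) {
  do.call(rbind, lapply(names(reports), function(m) {
    s <- metricSummary(reports[[m]])
    data.frame(magnification = as.integer(m),
               pla_mean = s$mean[s$metric == "pla"],
               pla_sd = s$sd[s$metric == "pla"],
               accuracy_mean = s$mean[s$metric == "accuracy"],
               accuracy_sd = s$sd[s$metric == "accuracy"])
  }))
}

#' Run the ablation pipeline (no embedding layer)
#'
#' Identical to [runMIB()]/[runMSB()] except the embedding is the identity:
#' k-NN operates directly on the raw backbone features, with the ablation k
#' defaults (3 for MIB; 3/7/5/9 per magnification for MSB).  No embedding
#' model is produced or written.
#'
#' @inheritParams runMIB
#' @param scope `"MIB"` or `"MSB"`.
#' @return as [runMIB()] (scope `"MIB"`) or [runMSB()] (scope `"MSB"`),
#'   with reports tagged `"ablation"`.
#' @export
runAblation <- function(corpus, folds, cfg = runConfig("ablation_MIB"),
                        scope = c("MIB", "MSB"), outputDir = NULL) {
  scope <- match.arg(scope)
  if (scope == "MIB") {
    return(runFoldSet(corpus, folds, cfg, ablation = TRUE,
                      tag = "ablation MIB", k = cfg$kAblationMIB,
                      outputDir = outputDir))
  }
  mags <- sort(unique(magnifications(corpus)))
  reports <- list()
  for (m in MAGNIFICATIONS) {
    if (!m %in% mags) {
      warning(sprintf("magnification %dx absent from corpus; skipped", m))
      next
    }
    sub <- restrictToMagnification(corpus, m)
    folds_m <- lapply(folds, restrictFold, corpus = sub, scope = "MSB",
                      magnification = m)
    k_m <- cfg$kMapAblation[[as.character(m)]]
    if (is.null(k_m)) k_m <- cfg$kAblationMIB
    out_m <- if (is.null(outputDir)) NULL else file.path(outputDir, sprintf("mag%d", m))
    reports[[as.character(m)]] <- runFoldSet(
      sub, folds_m, cfg, ablation = TRUE,
      tag = sprintf("ablation MSB(%d)", m), k = k_m, outputDir = out_m)
  }
  if (!length(reports)) stop("no magnification could be evaluated")
  attr(reports, "summary") <- msbSummary(reports)
  reports
}
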