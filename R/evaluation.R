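# Patient-level evaluation: patient scores, PLA, confusion matrices,
# image-level metrics, fold aggregation and the patient x fold grid.
#
# PatientScore = Nrec / NP, with NP the number of test images of patient P
# and Nrec the COUNT of those classified correctly; PLA is the unweighted
# mean of patient scores over patients (never image-weighted).

#' Per-patient scores from a prediction set
#'
#' @param ps a [PredictionSet-class] whose predictions carry `patient_id`
#'   and `true_label`.
#' @return a `data.frame` with one row per patient: `patient_id`,
#'   `n_images`, `n_correct`, `patient_score` (= n_correct / n_images),
#'   `assigned_label` (majority of predicted labels; ties assign
#'   malignant, mirroring the k-NN tie policy), `true_label` and
#'   `fraction_malignant` (fraction of the patient's images predicted
#'   malignant).  Patients with mixed true labels are an error: in this
#'   protocol a patient is single-class.
#' @export
patientScores <- function(ps) {
  p <- as.data.frame(predictions(ps))
  if (!nrow(p)) stop("prediction set is empty")
  if (anyNA(p$true_label) || anyNA(p$patient_id)) {
    stop("predictions lack true labels or patient ids")
  }
  rows <- lapply(split(p, p$patient_id), function(s) {
    truth <- unique(s$true_label)
    if (length(truth) > 1L) {
      stop(sprintf("patient '%s' has mixed true labels", s$patient_id[1L]))
    }
    n <- nrow(s)
    n_correct <- sum(s$predicted_label == truth)
    n_malig <- sum(s$predicted_label == "malignant")
    n_benign <- n - n_malig
    data.frame(patient_id = s$patient_id[1L], n_images = n,
               n_correct = n_correct, patient_score = n_correct / n,
               assigned_label = if (n_benign > n_malig) "benign" else "malignant",
               true_label = truth, fraction_malignant = n_malig / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Patient-level accuracy
#'
#' The arithmetic mean of patient scores: every patient weighs equally,
#' regardless of how many test images they contribute.
#'
#' @param scores the `data.frame` from [patientScores()], or a bare numeric
#'   vector of patient scores.
#' @return a single number in \[0, 1\].
#' @examples
#' pla(c(1, 0.5))  # 0.75
#' @export
pla <- function(scores) {
  s <- if (is.data.frame(scores)) scores$patient_score else as.numeric(scores)
  if (!length(s)) stop("no patient scores")
  mean(s)
}

#' Rank-based (Mann-Whitney) AUC with midrank tie handling
#' @noRd
rankAUC <- function(score, truth) {
  pos <- truth == "benign"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(score)  # midranks
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' 2x2 confusion matrix (rows = truth, columns = prediction)
#'
#' @param ps a [PredictionSet-class] with true labels.
#' @return a 2x2 integer matrix with dimnames benign/malignant.
#' @export
confusionMatrix <- function(ps) {
  p <- as.data.frame(predictions(ps))
  m <- matrix(0L, 2L, 2L, dimnames = list(truth = CLASS_LEVELS,
                                          predicted = CLASS_LEVELS))
  for (tl in CLASS_LEVELS) for (pl in CLASS_LEVELS) {
    m[tl, pl] <- sum(p$true_label == tl & p$predicted_label == pl)
  }
  m
}

#' Image-level classification metrics
#'
#' Benign is the positive class.  AUC is computed from the positive-class
#' score by the rank (Mann-Whitney) statistic with midrank ties; with a
#' single-class truth set it is reported as `NA` with a warning.
#'
#' @param ps a [PredictionSet-class] with true labels and scores.
#' @return a `data.frame` row: `accuracy`, `precision`, `recall`, `f1`,
#'   `auc`, `n`.
#' @export
imageMetrics <- function(ps) {
  p <- as.data.frame(predictions(ps))
  if (!nrow(p)) stop("prediction set is empty")
  tp <- sum(p$true_label == "benign" & p$predicted_label == "benign")
  fp <- sum(p$true_label == "malignant" & p$predicted_label == "benign")
  fn <- sum(p$true_label == "benign" & p$predicted_label == "malignant")
  tn <- sum(p$true_label == "malignant" & p$predicted_label == "malignant")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  auc <- rankAUC(p$score, p$true_label)
  if (is.na(auc)) warning("single-class truth set: AUC is undefined")
  data.frame(accuracy = (tp + tn) / nrow(p), precision = precision,
             recall = recall, f1 = f1, auc = auc, n = nrow(p))
}

#' Evaluate one fold's predictions
#'
#' @param ps a [PredictionSet-class] for a test fold.
#' @param fold fold index recorded in the report.
#' @return a list (`fold`, `patients`, `pla`, `metrics`, `confusion`).
#' @export
evaluateFold <- function(ps, fold = 1L) {
  patients <- patientScores(ps)
  list(fold = as.integer(fold), patients = patients,
       pla = pla(patients), metrics = imageMetrics(ps),
       confusion = confusionMatrix(ps))
}

#' Aggregate per-fold reports into an EvaluationReport
#'
#' Confusion matrices are averaged element-wise; every scalar metric is
#' summarised as mean and sample (n-1) standard deviation over folds.
#'
#' @param foldReports a non-empty list of [evaluateFold()] results.
#' @param tag free-text tag stored on the report (e.g. `"main MIB"`).
#' @return an [EvaluationReport-class].
#' @export
foldAverage <- function(foldReports, tag = "main") {
  if (!length(foldReports)) stop("no fold reports to aggregate")
  fm <- do.call(rbind, lapply(foldReports, function(r) {
    cbind(data.frame(fold = r$fold, pla = r$pla,
                     n_patients = nrow(r$patients)), r$metrics)
  }))
  confs <- lapply(foldReports, `[[`, "confusion")
  dims_ok <- vapply(confs, function(m) identical(dimnames(m), dimnames(confs[[1L]])),
                    logical(1))
  if (!all(dims_ok)) stop("folds have mismatched confusion-matrix label sets")
  avg_conf <- Reduce(`+`, confs) / length(confs)
  pr <- do.call(rbind, lapply(foldReports, function(r) {
    cbind(data.frame(fold = r$fold), r$patients)
  }))
  metric_cols <- c("pla", "accuracy", "precision", "recall", "f1", "auc")
  summ <- do.call(rbind, lapply(metric_cols, function(mc) {
    v <- fm[[mc]]
    data.frame(metric = mc, mean = mean(v, na.rm = TRUE),
               sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else NA_real_)
  }))
  methods::new("EvaluationReport",
    patientResults = S4Vectors::DataFrame(pr),
    foldMetrics = fm,
    confusion = list(perFold = confs, average = avg_conf),
    summary = summ,
    grid = patientFoldGrid(foldReports),
    tag = tag)
}

#' Patient x fold grid
#'
#' One row per patient (benign block first), one column pair per fold:
#' the fraction of that patient's test images labelled malignant and the
#' assigned (majority) label; `NA` where the patient is not in that fold's
#' test set.  Patients whose assigned label flips across folds are visible
#' as differing `assigned_*` entries along their row.
#'
#' @param foldReports a list of [evaluateFold()] results.
#' @return a wide `data.frame`.
#' @export
patientFoldGrid <- function(foldReports) {
  all_pat <- unique(do.call(rbind, lapply(foldReports, function(r) {
    r$patients[, c("patient_id", "true_label")]
  })))
  all_pat <- all_pat[order(match(all_pat$true_label, CLASS_LEVELS),
                           all_pat$patient_id), , drop = FALSE]
  grid <- all_pat
  rownames(grid) <- NULL
  for (r in foldReports) {
    frac <- setNames(r$patients$fraction_malignant, r$patients$patient_id)
    assigned <- setNames(r$patients$assigned_label, r$patients$patient_id)
    grid[[sprintf("frac_malignant_f%d", r$fold)]] <-
      unname(frac[grid$patient_id])
    grid[[sprintf("assigned_f%d", r$fold)]] <-
      unname(assigned[grid$patient_id])
  }
  grid
}

#' Write an evaluation report as delimited text files
#'
#' Emits three round-trippable files under `dir`: `metrics.tsv` (per-fold
#' scalar metrics), `confusion.tsv` (per-fold and averaged matrices in long
#' form) and `patient_grid.tsv`.
#'
#' @param report an [EvaluationReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeEvaluationReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(foldMetrics(report), file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE)
  conf <- confusionMatrices(report)
  long <- do.call(rbind, c(
    lapply(seq_along(conf$perFold), function(i) {
      m <- conf$perFold[[i]]
      data.frame(fold = as.character(i),
                 truth = rep(rownames(m), times = 2),
                 predicted = rep(colnames(m), each = 2),
                 count = as.vector(m))
    }),
    list(data.frame(fold = "average",
                    truth = rep(rownames(conf$average), times = 2),
                    predicted = rep(colnames(conf$average), each = 2),
                    count = as.vector(conf$average)))))
  data.table::fwrite(long, file.path(dir, "confusion.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(patientGrid(report), file.path(dir, "patient_grid.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(metricSummary(report), file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(dir)
}
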