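# Patient-level evaluation: patient scores, PLA vs image accuracy,
# image-level metrics with the rank-AUC oracle, fold aggregation, the
# patient x fold grid.

test_that("patient scores count correct images and assign majority labels", {
  ps <- makePredSet(patient = rep("P1", 4), truth = rep("benign", 4),
                    predicted = c("benign", "benign", "benign", "malignant"))
  s <- patientScores(ps)
  expect_equal(s$n_images, 4L)
  expect_equal(s$n_correct, 3L)
  expect_equal(s$patient_score, 0.75)
  expect_equal(s$assigned_label, "benign")

  all_right <- makePredSet(rep("P", 3), rep("malignant", 3), rep("malignant", 3))
  expect_equal(patientScores(all_right)$patient_score, 1)
  none <- makePredSet(rep("P", 3), rep("malignant", 3), rep("benign", 3))
  expect_equal(patientScores(none)$patient_score, 0)

  # 2-2 prediction tie for a benign patient: assigned malignant, score 0.5
  tie <- makePredSet(rep("P", 4), rep("benign", 4),
                     c("benign", "benign", "malignant", "malignant"))
  st <- patientScores(tie)
  expect_equal(st$assigned_label, "malignant")
  expect_equal(st$patient_score, 0.5)
  expect_equal(st$fraction_malignant, 0.5)

  mixed <- makePredSet(rep("P", 2), c("benign", "malignant"),
                       c("benign", "benign"))
  expect_error(patientScores(mixed), "mixed true labels")
})

test_that("PLA weighs patients, not images", {
  expect_equal(pla(c(1.0, 0.5)), 0.75)
  expect_equal(pla(rep(0.83, 7)), 0.83)

  # patient A: 10/10 correct; patient B: 0/1 -> PLA 0.5, image accuracy 10/11
  ps <- makePredSet(patient = c(rep("A", 10), "B"),
                    truth = rep("benign", 11),
                    predicted = c(rep("benign", 10), "malignant"))
  s <- patientScores(ps)
  expect_equal(pla(s), 0.5)
  expect_equal(suppressWarnings(imageMetrics(ps))$accuracy, 10 / 11)

  # with uniform patient sizes PLA and image accuracy coincide exactly
  ps_u <- makePredSet(patient = rep(c("A", "B"), each = 4),
                      truth = rep(c("benign", "malignant"), each = 4),
                      predicted = c("benign", "benign", "benign", "malignant",
                                    "malignant", "malignant", "benign", "benign"))
  expect_equal(pla(patientScores(ps_u)), imageMetrics(ps_u)$accuracy)
  expect_error(pla(numeric(0)), "no patient scores")
})

test_that("image metrics match the printed 2x2 and the pairwise AUC oracle", {
  perfect <- makePredSet(rep("P", 4), rep(c("benign", "malignant"), 2),
                         rep(c("benign", "malignant"), 2),
                         score = c(1, 0, 1, 0))
  m <- suppressWarnings(imageMetrics(perfect))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # TP=3 FP=1 FN=1 TN=5 (benign positive)
  truth <- c(rep("benign", 4), rep("malignant", 6))
  predicted <- c("benign", "benign", "benign", "malignant",
                 "benign", rep("malignant", 5))
  ps <- makePredSet(patient = paste0("p", 1:10), truth = truth,
                    predicted = predicted)
  m2 <- imageMetrics(ps)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$recall, 0.75)
  expect_equal(m2$f1, 0.75)
  expect_equal(m2$accuracy, 0.8)
  cm <- confusionMatrix(ps)
  expect_equal(as.vector(cm), c(3L, 1L, 1L, 5L))
  expect_equal(sum(cm), 10L)

  set.seed(31)
  for (trial in 1:20) {
    n <- sample(5:100, 1)
    truth <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1] <- setdiff(c("benign", "malignant"), truth[2])
    score <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # ties abound
    ps <- makePredSet(paste0("p", seq_len(n)), truth,
                      ifelse(score > 0.5, "benign", "malignant"), score)
    expect_equal(imageMetrics(ps)$auc, oracleAUC(score, truth),
                 tolerance = 1e-12)
  }

  single <- makePredSet(c("p1", "p2"), rep("benign", 2), rep("benign", 2))
  expect_warning(ms <- imageMetrics(single), "AUC is undefined")
  expect_true(is.na(ms$auc))
})

test_that("fold averaging produces mean +/- sample sd and mean matrices", {
  mk <- function(truth, predicted, pat) {
    suppressWarnings(evaluateFold(makePredSet(pat, truth, predicted),
                                  fold = 1L))
  }
  f1 <- mk(rep(c("benign", "malignant"), each = 4),
           c("benign", "benign", "benign", "malignant",
             rep("malignant", 4)), rep(c("A", "B"), each = 4))
  f2 <- f1; f2$fold <- 2L

  # identical folds: averages equal the fold, sd exactly 0
  rep_id <- foldAverage(list(f1, f2))
  s <- metricSummary(rep_id)
  expect_equal(s$sd[s$metric == "pla"], 0)
  expect_equal(s$mean[s$metric == "pla"], f1$pla)
  expect_equal(confusionMatrices(rep_id)$average, f1$confusion,
               ignore_attr = TRUE)

  # PLA 0.8 and 1.0 -> mean 0.9, sample sd ~ 0.1414
  g1 <- mk(rep("benign", 5), c(rep("benign", 4), "malignant"), rep("A", 5))
  g1$patients$patient_score <- 0.8; g1$pla <- 0.8
  g2 <- mk(rep("benign", 5), rep("benign", 5), rep("A", 5))
  g2$fold <- 2L
  rep2 <- foldAverage(list(g1, g2))
  s2 <- metricSummary(rep2)
  expect_equal(s2$mean[s2$metric == "pla"], 0.9)
  expect_equal(s2$sd[s2$metric == "pla"], sd(c(0.8, 1.0)), tolerance = 1e-9)

  # averaged confusion entries sum to the mean test-set size
  expect_equal(sum(confusionMatrices(rep2)$average), 5)
  expect_error(foldAverage(list()), "no fold reports")
})

test_that("the patient x fold grid exposes per-fold fractions and flips", {
  fold1 <- evaluateFold(makePredSet(
    patient = rep(c("B1", "M1"), each = 2),
    truth = rep(c("benign", "malignant"), each = 2),
    predicted = c("benign", "benign", "malignant", "malignant")), 1L)
  fold2 <- suppressWarnings(evaluateFold(makePredSet(
    patient = rep("B1", 2), truth = rep("benign", 2),
    predicted = rep("malignant", 2)), 2L))
  grid <- patientFoldGrid(list(fold1, fold2))
  expect_equal(grid$patient_id, c("B1", "M1"))  # benign block first
  b1 <- grid[grid$patient_id == "B1", ]
  expect_equal(b1$frac_malignant_f1, 0)
  expect_equal(b1$frac_malignant_f2, 1)  # all images labelled malignant
  expect_equal(b1$assigned_f1, "benign")
  expect_equal(b1$assigned_f2, "malignant")  # unstable across folds
  m1 <- grid[grid$patient_id == "M1", ]
  expect_true(is.na(m1$frac_malignant_f2))  # absent from fold 2
})

test_that("metrics are invariant to prediction-row permutation", {
  set.seed(17)
  n <- 30
  truth <- sample(c("benign", "malignant"), n, replace = TRUE)
  truth[1:2] <- c("benign", "malignant")
  pat <- paste0("p", rep(1:6, each = 5))
  truth <- rep(sample(c("benign", "malignant"), 6, replace = TRUE), each = 5)
  truth[1:5] <- "benign"; truth[6:10] <- "malignant"
  predicted <- sample(c("benign", "malignant"), n, replace = TRUE)
  score <- runif(n)
  ps <- makePredSet(pat, truth, predicted, score)
  perm <- sample(n)
  ps_p <- makePredSet(pat[perm], truth[perm], predicted[perm], score[perm])
  expect_equal(imageMetrics(ps_p), imageMetrics(ps))
  a <- patientScores(ps); b <- patientScores(ps_p)
  expect_equal(b[order(b$patient_id), ], a[order(a$patient_id), ],
               ignore_attr = TRUE)
  expect_equal(pla(a), pla(b))
})

test_that("evaluation reports serialize to readable delimited files", {
  corpus <- makeTestCorpus(seed = 90, dim = 16, patients = 4, images = 6)
  folds <- makeDefaultFolds(corpus, k = 2, seed = 9)
  rep <- runAblation(corpus, folds, runConfig("ablation_MIB", seed = 1),
                     scope = "MIB")
  dir <- withr::local_tempdir()
  writeEvaluationReport(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("metrics.tsv", "confusion.tsv",
                                               "patient_grid.tsv",
                                               "summary.tsv")))))
  metrics <- read.delim(file.path(dir, "metrics.tsv"))
  expect_equal(nrow(metrics), 2L)
  expect_true(all(c("pla", "accuracy", "auc") %in% names(metrics)))
  conf <- read.delim(file.path(dir, "confusion.tsv"))
  expect_true("average" %in% conf$fold)
})
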