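# Independent brute-force oracles.  These deliberately share no code with
# the package internals: distances are computed pointwise, candidate sets by
# exhaustive enumeration.

oracleDist <- function(u, v, distance) {
  if (distance == "euclidean") {
    sqrt(sum((u - v)^2))
  } else {
    1 - sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  }
}

# Exhaustive enumeration of the semi-hard band d_ap < d_an < d_ap + m over
# all (anchor, positive, negative) triples, plus the closest-qualifying-
# negative selection rule (ties -> lowest row index).
oracleMine <- function(emb, labels, m, distance, rule = "semi_hard") {
  n <- nrow(emb)
  rows <- list()
  for (a in seq_len(n)) {
    for (p in seq_len(n)) {
      if (p == a || labels[p] != labels[a]) next
      d_ap <- oracleDist(emb[a, ], emb[p, ], distance)
      cand <- integer(0); cand_d <- numeric(0)
      for (nn in seq_len(n)) {
        if (labels[nn] == labels[a]) next
        d_an <- oracleDist(emb[a, ], emb[nn, ], distance)
        if (d_an > d_ap && d_an < d_ap + m) {
          cand <- c(cand, nn); cand_d <- c(cand_d, d_an)
        }
      }
      if (!length(cand)) next
      keep <- if (rule == "semi_hard") {
        which(cand_d == min(cand_d))[1L]  # lowest index among ties
      } else seq_along(cand)
      for (k in keep) {
        rows[[length(rows) + 1L]] <- data.frame(
          anchor = a, positive = p, negative = cand[k],
          d_ap = d_ap, d_an = cand_d[k])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(anchor = integer(0), positive = integer(0),
                      negative = integer(0), d_ap = numeric(0),
                      d_an = numeric(0)))
  }
  do.call(rbind, rows)
}

sortTriplets <- function(df) {
  df <- df[order(df$anchor, df$positive, df$negative), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Brute-force k-NN: pointwise distances, stable (distance, train index)
# ordering, benign-majority vote with ties predicted malignant.
oracleKnn <- function(train, trainLabels, test, k, distance) {
  n_tr <- nrow(train)
  pred <- character(nrow(test)); score <- numeric(nrow(test))
  for (i in seq_len(nrow(test))) {
    d <- vapply(seq_len(n_tr),
                function(j) oracleDist(test[i, ], train[j, ], distance),
                numeric(1))
    ord <- order(d, seq_len(n_tr))[seq_len(k)]
    nb <- sum(trainLabels[ord] == "benign")
    score[i] <- nb / k
    pred[i] <- if (nb > k - nb) "benign" else "malignant"
  }
  list(predicted = pred, score = score)
}

# Pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracleAUC <- function(score, truth) {
  pos <- score[truth == "benign"]
  neg <- score[truth == "malignant"]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# Small synthetic corpus used across tests (low feature dimension for speed).
makeTestCorpus <- function(seed = 1L, sep = 8, spread = 1, noise = 1,
                           dim = 32, patients = 6, images = 6,
                           mags = c(40L, 100L, 200L, 400L),
                           straddlers = 0) {
  syntheticCorpus(syntheticSpec(
    n_patients_benign = patients, n_patients_malignant = patients,
    images_per_patient = images, feature_dim = dim,
    class_separation = sep, patient_spread = spread, noise_sd = noise,
    magnifications = mags, n_straddlers = straddlers, seed = seed))
}

# Assemble a PredictionSet directly from vectors (for evaluation tests).
makePredSet <- function(patient, truth, predicted, score = NULL, k = 3L) {
  n <- length(truth)
  ids <- sprintf("img%03d", seq_len(n))
  if (is.null(score)) {
    score <- ifelse(predicted == "benign", 1, 0)
  }
  methods::new("PredictionSet",
    predictions = S4Vectors::DataFrame(image_id = ids, patient_id = patient,
                                       true_label = truth,
                                       predicted_label = predicted,
                                       score = score, row.names = ids),
    neighbors = S4Vectors::DataFrame(image_id = character(0),
                                     rank = integer(0),
                                     neighbor_id = character(0),
                                     distance = numeric(0),
                                     neighbor_label = character(0)),
    k = as.integer(k), distance = "euclidean")
}

# Mean inter-class / mean intra-class distance ratio in a representation.
separationRatio <- function(x, labels) {
  D <- as.matrix(dist(x))
  same <- outer(labels, labels, "==") & upper.tri(D)
  diff <- outer(labels, labels, "!=") & upper.tri(D)
  mean(D[diff]) / mean(D[same])
}
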