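# Synthetic feature corpora: hierarchical Gaussian generator emulating the
# statistical structure the pipeline assumes — class-level separation,
# patient-level clustering, magnification substructure, and optional
# "straddler" patients whose images cross the class boundary.

#' Specification for a synthetic feature corpus
#'
#' The generator draws, in feature space: a random unit direction `u`
#' separating the class means by `class_separation`; per-patient mean
#' offsets of length `patient_spread` in random directions; per-magnification
#' global offsets of length `magnification_shift`; and i.i.d. Gaussian
#' per-image noise with per-dimension standard deviation `noise_sd`.
#' Straddler patients (emulating patients whose images fall in both class
#' clusters) have a fraction of their images drawn around the OPPOSITE class
#' mean.
#'
#' @param n_patients_benign,n_patients_malignant patient counts (>= 1).
#' @param images_per_patient a count, or a length-2 range sampled uniformly
#'   per patient; images are spread round-robin over `magnifications`.
#' @param feature_dim feature dimensionality (default 2048, the backbone
#'   convention).
#' @param class_separation distance between the two class mean vectors.
#' @param patient_spread distance of each patient mean from its class mean.
#' @param noise_sd per-dimension within-patient standard deviation.
#' @param magnifications subset of `c(40, 100, 200, 400)`.
#' @param magnification_shift length of the global per-magnification offset.
#' @param n_straddlers number of straddler patients per class.
#' @param straddle_fraction fraction of a straddler's images drawn on the
#'   wrong side of the class boundary.
#' @param seed integer seed; the draw is fully deterministic given the spec.
#' @return a list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(n_patients_benign = 10, n_patients_malignant = 10,
                          images_per_patient = 8, feature_dim = 2048,
                          class_separation = 6, patient_spread = 2,
                          noise_sd = 1,
                          magnifications = c(40L, 100L, 200L, 400L),
                          magnification_shift = 0.5,
                          n_straddlers = 0, straddle_fraction = 0.4,
                          seed = 1L) {
  spec <- list(
    n_patients_benign = assertCount(n_patients_benign, "n_patients_benign"),
    n_patients_malignant = assertCount(n_patients_malignant, "n_patients_malignant"),
    images_per_patient = as.integer(images_per_patient),
    feature_dim = assertCount(feature_dim, "feature_dim", min = 2L),
    class_separation = assertPositive(class_separation, "class_separation", strict = FALSE),
    patient_spread = assertPositive(patient_spread, "patient_spread", strict = FALSE),
    noise_sd = assertPositive(noise_sd, "noise_sd"),
    magnifications = sort(as.integer(magnifications)),
    magnification_shift = assertPositive(magnification_shift, "magnification_shift", strict = FALSE),
    n_straddlers = assertCount(n_straddlers, "n_straddlers", min = 0L),
    straddle_fraction = assertPositive(straddle_fraction, "straddle_fraction", strict = FALSE),
    seed = as.integer(seed))
  if (!all(spec$magnifications %in% MAGNIFICATIONS)) {
    stop("magnifications must be a subset of 40, 100, 200, 400")
  }
  if (!length(spec$magnifications)) stop("need at least one magnification")
  if (!all(spec$images_per_patient >= 1)) {
    stop("images_per_patient must be >= 1")
  }
  class(spec) <- "SyntheticSpec"
  spec
}

randomUnit <- function(d) {
  v <- rnorm(d)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic feature corpus
#'
#' @param spec a [syntheticSpec()].
#' @return a [PatchCorpus-class] with a features assay; deterministic given
#'   `spec$seed` (same spec twice gives bit-identical output).
#' @examples
#' corpus <- syntheticCorpus(syntheticSpec(n_patients_benign = 2,
#'   n_patients_malignant = 2, images_per_patient = 5, feature_dim = 16,
#'   magnifications = 40))
#' corpus
#' @export
syntheticCorpus <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    d <- spec$feature_dim
    u <- randomUnit(d)
    class_means <- list(
      benign = -0.5 * spec$class_separation * u,
      malignant = 0.5 * spec$class_separation * u)
    mag_offsets <- lapply(seq_along(spec$magnifications), function(i) {
      spec$magnification_shift * randomUnit(d)
    })
    names(mag_offsets) <- as.character(spec$magnifications)

    n_b <- spec$n_patients_benign
    n_m <- spec$n_patients_malignant
    patients <- data.frame(
      patient_id = c(sprintf("B%02d", seq_len(n_b)), sprintf("M%02d", seq_len(n_m))),
      class_label = rep(CLASS_LEVELS, c(n_b, n_m)),
      stringsAsFactors = FALSE)
    # subclasses round-robin within class, mirroring the benchmark's 4+4 codes
    patients$subclass <- ifelse(
      patients$class_label == "benign",
      BENIGN_SUBCLASSES[(seq_len(nrow(patients)) - 1L) %% 4L + 1L],
      MALIGNANT_SUBCLASSES[(seq_len(nrow(patients)) - 1L) %% 4L + 1L])
    # last n_straddlers patients of each class straddle the boundary
    straddler <- logical(nrow(patients))
    if (spec$n_straddlers > 0) {
      for (cl in CLASS_LEVELS) {
        idx <- which(patients$class_label == cl)
        straddler[utils::tail(idx, spec$n_straddlers)] <- TRUE
      }
    }

    rows <- vector("list", nrow(patients))
    feats <- vector("list", nrow(patients))
    for (i in seq_len(nrow(patients))) {
      p <- patients[i, ]
      n_img <- if (length(spec$images_per_patient) > 1L) {
        sample(spec$images_per_patient[1L]:spec$images_per_patient[2L], 1L)
      } else spec$images_per_patient
      mags <- spec$magnifications[(seq_len(n_img) - 1L) %% length(spec$magnifications) + 1L]
      own_mean <- class_means[[p$class_label]] + spec$patient_spread * randomUnit(d)
      other <- setdiff(CLASS_LEVELS, p$class_label)
      cross_mean <- class_means[[other]] + spec$patient_spread * randomUnit(d)
      n_cross <- if (straddler[i]) round(spec$straddle_fraction * n_img) else 0L
      use_cross <- seq_len(n_img) <= n_cross  # first images straddle
      x <- matrix(rnorm(n_img * d, sd = spec$noise_sd), nrow = n_img)
      for (j in seq_len(n_img)) {
        base <- if (use_cross[j]) cross_mean else own_mean
        x[j, ] <- x[j, ] + base + mag_offsets[[as.character(mags[j])]]
      }
      rows[[i]] <- data.frame(
        image_id = sprintf("SYN_%s_%s-%d-%03d", p$patient_id, p$subclass,
                           mags, seq_len(n_img)),
        patient_id = p$patient_id, class_label = p$class_label,
        subclass = p$subclass, magnification = mags,
        source = "synthetic", stringsAsFactors = FALSE)
      feats[[i]] <- x
    }
    mf <- do.call(rbind, rows)
    x <- do.call(rbind, feats)
    rownames(x) <- mf$image_id
    PatchCorpus(mf, features = x,
                provenance = sprintf("synthetic seed=%d sep=%g spread=%g noise=%g dim=%d",
                                     spec$seed, spec$class_separation,
                                     spec$patient_spread, spec$noise_sd, d))
  })
}

#' Generate a corpus shaped like the BreakHis benchmark
#'
#' Patient counts per subclass and per-patient image counts follow the
#' benchmark's composition (24 benign / 58 malignant patients; ~2480 benign /
#' ~5429 malignant images at `scale = 1`), optionally scaled down; every
#' patient has images at all four magnifications.
#'
#' @param seed integer seed.
#' @param scale fraction in (0, 1]; patient and image counts are scaled
#'   proportionally (at least one patient per subclass that survives
#'   rounding, and it is an error when a whole class would vanish).
#' @param feature_dim,class_separation,patient_spread,noise_sd,magnification_shift,n_straddlers
#'   forwarded to the same hierarchical Gaussian draw as [syntheticCorpus()].
#' @return a [PatchCorpus-class] with features.
#' @export
breakhisShapedCorpus <- function(seed = 1L, scale = 1,
                                 feature_dim = 2048,
                                 class_separation = 6, patient_spread = 2,
                                 noise_sd = 1, magnification_shift = 0.5,
                                 n_straddlers = 0) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  # benchmark composition: subclass -> c(images, patients)
  comp <- list(
    benign = list(A = c(444, 4), F = c(1014, 10), TA = c(453, 7), PT = c(569, 3)),
    malignant = list(DC = c(3451, 38), LC = c(626, 5), MC = c(792, 9), PC = c(560, 6)))
  withSeed(deriveSeed(seed, 17L), {
    d <- assertCount(feature_dim, "feature_dim", min = 2L)
    u <- randomUnit(d)
    class_means <- list(benign = -0.5 * class_separation * u,
                        malignant = 0.5 * class_separation * u)
    mag_offsets <- lapply(MAGNIFICATIONS, function(m) magnification_shift * randomUnit(d))
    names(mag_offsets) <- as.character(MAGNIFICATIONS)

    rows <- list(); feats <- list(); k <- 0L
    for (cl in CLASS_LEVELS) {
      n_pat_class <- 0L
      for (sc in names(comp[[cl]])) {
        n_pat_class <- n_pat_class + round(scale * comp[[cl]][[sc]][2L])
      }
      if (n_pat_class < 1L) {
        stop(sprintf("scale %g leaves no %s patients", scale, cl))
      }
      straddle_left <- n_straddlers
      for (sc in names(comp[[cl]])) {
        n_img_total <- comp[[cl]][[sc]][1L]
        n_pat <- round(scale * comp[[cl]][[sc]][2L])
        if (n_pat < 1L) next
        imgs_per_pat <- max(4L, round(scale * n_img_total / comp[[cl]][[sc]][2L]))
        imgs_per_pat <- 4L * ceiling(imgs_per_pat / 4L)  # equal count per magnification
        for (p in seq_len(n_pat)) {
          k <- k + 1L
          pid <- sprintf("%s-%s%02d", if (cl == "benign") "B" else "M", sc, p)
          own_mean <- class_means[[cl]] + patient_spread * randomUnit(d)
          other <- setdiff(CLASS_LEVELS, cl)
          cross_mean <- class_means[[other]] + patient_spread * randomUnit(d)
          is_straddler <- straddle_left > 0L
          if (is_straddler) straddle_left <- straddle_left - 1L
          mags <- rep(MAGNIFICATIONS, imgs_per_pat / 4L)
          n_img <- length(mags)
          n_cross <- if (is_straddler) round(0.4 * n_img) else 0L
          x <- matrix(rnorm(n_img * d, sd = noise_sd), nrow = n_img)
          for (j in seq_len(n_img)) {
            base <- if (j <= n_cross) cross_mean else own_mean
            x[j, ] <- x[j, ] + base + mag_offsets[[as.character(mags[j])]]
          }
          rows[[k]] <- data.frame(
            image_id = sprintf("SYN_%s-%d-%03d", pid, mags, seq_len(n_img)),
            patient_id = pid, class_label = cl, subclass = sc,
            magnification = mags, source = "synthetic",
            stringsAsFactors = FALSE)
          feats[[k]] <- x
        }
      }
    }
    mf <- do.call(rbind, rows)
    x <- do.call(rbind, feats)
    rownames(x) <- mf$image_id
    PatchCorpus(mf, features = x,
                provenance = sprintf("synthetic benchmark-shaped seed=%d scale=%g dim=%d",
                                     seed, scale, d))
  })
}

#' Generate patient-disjoint default folds
#'
#' Emulates the benchmark's released protocol: `k` independent 70-30
#' patient-level train/test splits, stratified by class.  Every returned
#' split passes [validateFold()] by construction.
#'
#' @param corpus a [PatchCorpus-class].
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param trainFraction fraction of each class's patients put in train.
#' @return a list of `k` [FoldSplit-class] objects.
#' @export
makeDefaultFolds <- function(corpus, k = 5L, seed = 1L, trainFraction = 0.7) {
  k <- assertCount(k, "k")
  mf <- manifest(corpus)
  by_class <- split(unique(mf[, c("patient_id", "class_label")])$patient_id,
                    unique(mf[, c("patient_id", "class_label")])$class_label)
  if (length(by_class) < 2L || any(vapply(by_class, length, 1L) < 2L)) {
    stop("need at least 2 patients per class to build patient-disjoint folds")
  }
  withSeed(deriveSeed(seed, 29L), {
    lapply(seq_len(k), function(f) {
      train_pat <- unlist(lapply(by_class, function(pats) {
        n_train <- max(1L, min(length(pats) - 1L,
                               round(trainFraction * length(pats))))
        sample(pats, n_train)
      }), use.names = FALSE)
      FoldSplit(f,
                trainIds = mf$image_id[mf$patient_id %in% train_pat],
                testIds = mf$image_id[!mf$patient_id %in% train_pat],
                scope = "MIB")
    })
  })
}
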