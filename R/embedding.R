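# Metric learning core: triplet margin loss, online semi-hard mining, and
# training of the linear embedding layer with Adam.
#
# Conceptually the trainer is a triplet network: three weight-sharing copies
# of the embedding layer receive anchor / positive / negative inputs.  As is
# standard, the implementation routes the whole mini-batch through the single
# shared layer once and assembles triplets from the batch ("online" mining).

#' Training configuration for the embedding layer
#'
#' Defaults follow the published training protocol for this architecture:
#' 20 epochs, mini-batch 32, Adam with learning rate 1e-5 and weight decay
#' 1e-4.  Note the learning rate is calibrated to backbone activation
#' scales; synthetic unit-variance corpora train better at a larger rate
#' (see the methods vignette).
#'
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled weight-decay factor (AdamW-style).
#' @param optimizer only `"adam"` is implemented.
#' @param seed integer seed controlling initial weights and batch shuffles.
#' @param miner `"semi_hard"` (default) or `"all_valid"` (every
#'   in-margin violating triplet, no negative selection).
#' @return a list of class `"TrainConfig"`.
#' @export
trainConfig <- function(epochs = 20L, batch_size = 32L, learning_rate = 1e-5,
                        weight_decay = 1e-4, optimizer = "adam", seed = 1L,
                        miner = c("semi_hard", "all_valid")) {
  miner <- match.arg(miner)
  if (optimizer != "adam") stop("only the 'adam' optimizer is implemented")
  cfg <- list(epochs = assertCount(epochs, "epochs", min = 0L),
              batch_size = assertCount(batch_size, "batch_size", min = 2L),
              learning_rate = assertPositive(learning_rate, "learning_rate"),
              weight_decay = assertPositive(weight_decay, "weight_decay", strict = FALSE),
              optimizer = optimizer, seed = as.integer(seed), miner = miner)
  class(cfg) <- "TrainConfig"
  cfg
}

#' Construct an (untrained) embedding model
#'
#' The layer is a pure bias-free linear projection.  Weights are initialised
#' to a seeded Gaussian matrix scaled by `1/sqrt(inputDim)`, whose rows have
#' expected unit norm and are nearly orthogonal, so the initial map behaves
#' like an isometry onto a random `embeddingDim`-dimensional subspace.
#'
#' @param inputDim backbone feature dimensionality (2048 by convention).
#' @param embeddingDim embedding dimensionality (default 512); must be
#'   strictly smaller than `inputDim`.
#' @param distance `"euclidean"` (default) or `"cosine"`.
#' @param margin triplet margin `m` (> 0; default 0.2).
#' @param normalized L2-normalize embeddings after projection.
#' @param seed seed for the weight initialisation.
#' @return an [EmbeddingModel-class].
#' @export
embeddingModel <- function(inputDim, embeddingDim = 512L,
                           distance = c("euclidean", "cosine"),
                           margin = 0.2, normalized = FALSE, seed = 1L) {
  distance <- match.arg(distance)
  inputDim <- assertCount(inputDim, "inputDim", min = 2L)
  embeddingDim <- assertCount(embeddingDim, "embeddingDim")
  if (embeddingDim >= inputDim) {
    stop("embeddingDim must be smaller than inputDim")
  }
  # scaled Gaussian init: rows have expected unit norm and are near-
  # orthogonal at these dimensions, so the initial map is close to an
  # isometry onto a random subspace
  w <- withSeed(deriveSeed(seed, 3L), {
    matrix(rnorm(inputDim * embeddingDim, sd = 1 / sqrt(inputDim)),
           nrow = embeddingDim)
  })
  methods::new("EmbeddingModel", weights = w, distance = distance,
               margin = assertPositive(margin, "margin"),
               normalized = normalized, config = list(),
               lossHistory = numeric(0))
}

#' Triplet margin loss
#'
#' `max(0, d_ap - d_an + m)`: the hinge that pulls an anchor towards its
#' positive and pushes it at least `m` further from its negative.
#' Vectorized over `d_ap`/`d_an`.
#'
#' @param d_ap anchor-positive distance(s), non-negative.
#' @param d_an anchor-negative distance(s), non-negative.
#' @param m positive margin.
#' @return non-negative loss value(s).
#' @examples
#' tripletLoss(2, 1, 0.5)  # 1.5
#' @export
tripletLoss <- function(d_ap, d_an, m) {
  m <- assertPositive(m, "m")
  if (any(!is.finite(d_ap)) || any(!is.finite(d_an))) {
    stop("distances must be finite")
  }
  if (any(d_ap < 0) || any(d_an < 0)) stop("distances must be non-negative")
  pmax(0, d_ap - d_an + m)
}

#' Semi-hard triplet mining within a mini-batch
#'
#' For every ordered anchor-positive pair (same label, distinct rows) the
#' admissible negatives are those strictly farther from the anchor than the
#' positive but still within the margin band:
#' `d(a,p) < d(a,n) < d(a,p) + m`.  Under the default `"semi_hard"` rule the
#' single admissible negative closest to the anchor is selected (ties broken
#' by the lowest row index); `"all_valid"` keeps every admissible negative.
#' A direct consequence of the band is that every mined triplet's loss lies
#' in `(0, m)`.
#'
#' @param embeddings numeric matrix, batch rows x embedding dimension.
#' @param labels class label per row.
#' @param m positive margin.
#' @param distance `"euclidean"` or `"cosine"`.
#' @param rule `"semi_hard"` or `"all_valid"`.
#' @return a `data.frame` with columns `anchor`, `positive`, `negative`
#'   (row indices), `d_ap`, `d_an`; zero rows when no triplet qualifies.
#'   A single-class batch yields zero rows with a warning.
#' @export
mineSemiHard <- function(embeddings, labels, m,
                         distance = c("euclidean", "cosine"),
                         rule = c("semi_hard", "all_valid")) {
  distance <- match.arg(distance)
  rule <- match.arg(rule)
  m <- assertPositive(m, "m")
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  stopifnot(length(labels) == n)
  empty <- data.frame(anchor = integer(0), positive = integer(0),
                      negative = integer(0), d_ap = numeric(0),
                      d_an = numeric(0))
  if (length(unique(labels)) < 2L) {
    warning("single-class batch: no triplets can be mined")
    return(empty)
  }
  D <- pairwiseDistances(embeddings, embeddings, distance)
  mineFromDistances(D, labels, m, rule)
}

# Core of the miner, shared with the training loop: works from a
# precomputed within-batch distance matrix and avoids per-pair data.frame
# construction.
mineFromDistances <- function(D, labels, m, rule) {
  n <- nrow(D)
  anchors <- integer(0); positives <- integer(0); negatives <- integer(0)
  d_aps <- numeric(0); d_ans <- numeric(0)
  for (a in seq_len(n)) {
    pos <- which(labels == labels[a])
    pos <- pos[pos != a]
    neg <- which(labels != labels[a])
    if (!length(pos) || !length(neg)) next
    d_neg <- D[a, neg]
    for (p in pos) {
      d_ap <- D[a, p]
      ok <- d_neg > d_ap & d_neg < d_ap + m
      if (!any(ok)) next
      cand <- if (rule == "semi_hard") {
        # which.min is tie-stable: the lowest qualifying row index wins
        neg[ok][which.min(d_neg[ok])]
      } else neg[ok]
      nc <- length(cand)
      anchors <- c(anchors, rep.int(a, nc))
      positives <- c(positives, rep.int(p, nc))
      negatives <- c(negatives, cand)
      d_aps <- c(d_aps, rep.int(d_ap, nc))
      d_ans <- c(d_ans, D[a, cand])
    }
  }
  data.frame(anchor = anchors, positive = positives, negative = negatives,
             d_ap = d_aps, d_an = d_ans)
}

# Gradient of d(e_a, e_b) with respect to e_a and e_b, one pair per row of
# ea/eb.  Returns list(ga, gb) with matching shapes.
distanceGradients <- function(ea, eb, d, distance) {
  if (distance == "euclidean") {
    dd <- pmax(d, 1e-12)
    ga <- (ea - eb) / dd
    list(ga = ga, gb = -ga)
  } else {
    na <- pmax(sqrt(rowSums(ea^2)), 1e-12)
    nb <- pmax(sqrt(rowSums(eb^2)), 1e-12)
    s <- rowSums(ea * eb) / (na * nb)
    # d = 1 - s; grad_a = s * a / |a|^2 - b / (|a||b|)
    ga <- ea * (s / na^2) - eb / (na * nb)
    gb <- eb * (s / nb^2) - ea / (na * nb)
    list(ga = ga, gb = gb)
  }
}

#' Train the embedding layer with triplet margin loss
#'
#' Runs mini-batch gradient training of the linear embedding: each step
#' projects the batch through the shared layer, mines triplets online
#' (semi-hard by default), and updates the weights with Adam on the mean
#' triplet margin loss (decoupled weight decay).  Deterministic given
#' `cfg$seed`.
#'
#' @param features numeric matrix, images x input dimension, or a
#'   [PatchCorpus-class] with features.
#' @param labels class label per row (ignored with a corpus, whose
#'   `class_label` column is used).
#' @param cfg a [trainConfig()].
#' @param model an [embeddingModel()] providing the initialisation, the
#'   distance, the margin and the normalization flag.
#' @return the trained [EmbeddingModel-class]; `lossHistory(model)` holds
#'   the per-epoch mean mined-triplet loss (0 for epochs where the margin
#'   band was empty) and `model@config$epochStats` a per-epoch data frame
#'   with triplet counts and min/max mined losses.
#' @export
trainEmbedding <- function(features, labels = NULL, cfg = trainConfig(),
                           model) {
  if (methods::is(features, "PatchCorpus")) {
    labels <- classLabels(features)
    features <- featureMatrix(features)
  }
  x <- as.matrix(features)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L) {
    stop("training requires at least two classes")
  }
  if (ncol(x) != inputDim(model)) {
    stop(sprintf("feature dimension %d does not match model input %d",
                 ncol(x), inputDim(model)))
  }
  # weights kept transposed (inputDim x embeddingDim) inside the loop so
  # forward and backward passes are plain matrix products with no t() calls
  w_t <- t(model@weights)
  m_adam <- matrix(0, nrow(w_t), ncol(w_t))
  v_adam <- matrix(0, nrow(w_t), ncol(w_t))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  margin <- model@margin
  distance <- model@distance
  history <- numeric(cfg$epochs)
  stats <- data.frame(epoch = seq_len(cfg$epochs),
                      n_triplets = rep(0L, cfg$epochs),
                      mean_loss = rep(0, cfg$epochs),
                      min_loss = rep(NA_real_, cfg$epochs),
                      max_loss = rep(NA_real_, cfg$epochs))

  withSeed(deriveSeed(cfg$seed, 7L), {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_losses <- numeric(0)
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        if (length(idx) < 2L) next
        xb <- x[idx, , drop = FALSE]
        lb <- labels[idx]
        if (length(unique(lb)) < 2L) next  # nothing minable in this batch
        e_raw <- xb %*% w_t
        if (model@normalized) {
          norms <- pmax(sqrt(rowSums(e_raw^2)), 1e-12)
          e <- e_raw / norms
        } else {
          e <- e_raw
        }
        trip <- mineFromDistances(pairwiseDistances(e, e, distance), lb,
                                  margin, cfg$miner)
        if (!nrow(trip)) next
        losses <- trip$d_ap - trip$d_an + margin  # all mined triplets are active
        if (any(!is.finite(losses))) {
          stop(sprintf("non-finite triplet loss at epoch %d", epoch))
        }
        ep_losses <- c(ep_losses, losses)
        nt <- nrow(trip)
        gap <- distanceGradients(e[trip$anchor, , drop = FALSE],
                                 e[trip$positive, , drop = FALSE],
                                 trip$d_ap, distance)
        gan <- distanceGradients(e[trip$anchor, , drop = FALSE],
                                 e[trip$negative, , drop = FALSE],
                                 trip$d_an, distance)
        # dL/dE, scattered over batch rows (mean over triplets)
        g_e <- matrix(0, nrow(e), ncol(e))
        contrib <- rowsum(rbind((gap$ga - gan$ga) / nt, gap$gb / nt,
                                -gan$gb / nt),
                          group = c(trip$anchor, trip$positive, trip$negative))
        g_e[as.integer(rownames(contrib)), ] <- contrib
        if (model@normalized) {
          # back through row-normalization: (g - (g.ehat) ehat) / |e_raw|
          proj <- rowSums(g_e * e)
          g_e <- (g_e - e * proj) / norms
        }
        grad_wt <- crossprod(xb, g_e)  # (inputDim x embeddingDim)
        t_step <- t_step + 1L
        .adamStep(w_t, m_adam, v_adam, grad_wt, cfg$learning_rate,
                  cfg$weight_decay, beta1, beta2, eps, t_step)
      }
      history[epoch] <- if (length(ep_losses)) mean(ep_losses) else 0
      stats$n_triplets[epoch] <- length(ep_losses)
      stats$mean_loss[epoch] <- history[epoch]
      if (length(ep_losses)) {
        stats$min_loss[epoch] <- min(ep_losses)
        stats$max_loss[epoch] <- max(ep_losses)
      }
    }
  })
  methods::new("EmbeddingModel", weights = t(w_t), distance = distance,
               margin = margin, normalized = model@normalized,
               config = c(unclass(cfg), list(epochStats = stats)),
               lossHistory = history)
}

#' @rdname embedFeatures
#' @export
setMethod("embedFeatures", signature(model = "EmbeddingModel", x = "matrix"),
  function(model, x) {
    if (ncol(x) != inputDim(model)) {
      stop(sprintf("input has %d columns; model expects %d",
                   ncol(x), inputDim(model)))
    }
    e <- x %*% t(model@weights)
    if (model@normalized) e <- rowL2Normalize(e)
    rownames(e) <- rownames(x)
    e
  })

#' @rdname embedFeatures
#' @export
setMethod("embedFeatures", signature(model = "EmbeddingModel", x = "PatchCorpus"),
  function(model, x) embedFeatures(model, featureMatrix(x)))

# ---- model serialization ---------------------------------------------------

#' Write and read embedding models
#'
#' Plain-text container: a versioned key-value header (dimensions, distance,
#' margin, normalization flag, training config) followed by the weight
#' matrix at full double precision; the round trip restores weights exactly.
#'
#' @param model an [EmbeddingModel-class].
#' @param path file path.
#' @return `writeEmbeddingModel` returns `path` invisibly;
#'   `readEmbeddingModel` the restored model.
#' @export
writeEmbeddingModel <- function(model, path) {
  header <- c(
    "#tripletKNN-embedding-model v1",
    sprintf("embedding_dim\t%d", embeddingDim(model)),
    sprintf("input_dim\t%d", inputDim(model)),
    sprintf("distance\t%s", model@distance),
    sprintf("margin\t%.17g", model@margin),
    sprintf("normalized\t%s", model@normalized),
    sprintf("loss_history\t%s", paste(sprintf("%.17g", model@lossHistory),
                                      collapse = ",")),
    "weights")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(model@weights, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname writeEmbeddingModel
#' @export
readEmbeddingModel <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#tripletKNN-embedding-model")) {
    stop(sprintf("'%s' is not a tripletKNN model file", path))
  }
  kv <- strsplit(lines[2:7], "\t")
  vals <- setNames(vapply(kv, function(x) if (length(x) > 1) x[2] else "",
                          character(1)),
                   vapply(kv, `[`, character(1), 1))
  wstart <- which(lines == "weights")[1L] + 1L
  w <- as.matrix(utils::read.table(text = lines[wstart:length(lines)],
                                   sep = "\t"))
  dimnames(w) <- NULL
  lh <- if (nzchar(vals[["loss_history"]])) {
    as.numeric(strsplit(vals[["loss_history"]], ",")[[1L]])
  } else numeric(0)
  methods::new("EmbeddingModel", weights = w,
               distance = vals[["distance"]],
               margin = as.numeric(vals[["margin"]]),
               normalized = as.logical(vals[["normalized"]]),
               config = list(), lossHistory = lh)
}
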