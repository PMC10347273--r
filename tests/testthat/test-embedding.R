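# Metric-learning core: triplet loss, semi-hard mining vs the exhaustive
# oracle, gradient correctness, training behaviour, model IO.

test_that("triplet margin loss is the hinge max(0, d_ap - d_an + m)", {
  expect_equal(tripletLoss(0, 0.5, 0.5), 0)      # boundary of the hinge
  expect_equal(tripletLoss(2.0, 1.0, 0.5), 1.5)  # direct substitution
  # hinge inactive whenever d_an >= d_ap + m
  for (d_ap in c(0, 0.3, 2)) {
    expect_equal(tripletLoss(d_ap, d_ap + 0.2, 0.2), 0)
    expect_equal(tripletLoss(d_ap, d_ap + 5, 0.2), 0)
  }
  expect_equal(tripletLoss(c(2, 0), c(1, 1), 0.5), c(1.5, 0))  # vectorized
  expect_error(tripletLoss(-0.1, 1, 0.5), "non-negative")
  expect_error(tripletLoss(Inf, 1, 0.5), "finite")
  expect_error(tripletLoss(1, 1, 0), "'m'")
})

test_that("semi-hard mining matches hand-worked 1-D geometry", {
  # class 0 at {0.0, 0.1}; class 1 at {0.15, 5.0}; m = 0.5, euclidean.
  # For anchor 0.0 / positive 0.1: d_ap = 0.1, band is (0.1, 0.6);
  # the negative 0.15 qualifies (d = 0.15), 5.0 does not.
  emb <- matrix(c(0.0, 0.1, 0.15, 5.0), ncol = 1)
  labels <- c("a", "a", "b", "b")
  got <- mineSemiHard(emb, labels, m = 0.5, distance = "euclidean")
  row1 <- got[got$anchor == 1 & got$positive == 2, ]
  expect_equal(nrow(row1), 1L)
  expect_equal(row1$negative, 3L)
  expect_equal(row1$d_ap, 0.1)
  expect_equal(row1$d_an, 0.15)
  expect_false(any(got$negative == 4L & got$anchor == 1))
  # full agreement with the exhaustive oracle on this fixture
  expect_equal(sortTriplets(got),
               sortTriplets(oracleMine(emb, labels, 0.5, "euclidean")),
               tolerance = 1e-12)

  # every negative beyond d_ap + m: the band is empty
  far <- matrix(c(0, 0.01, 10, 11), ncol = 1)
  expect_equal(nrow(mineSemiHard(far, labels, m = 0.5)), 0L)

  expect_warning(none <- mineSemiHard(matrix(rnorm(6), 3), rep("a", 3), 0.2),
                 "single-class")
  expect_equal(nrow(none), 0L)
})

test_that("mining equals the brute-force band enumeration on random batches", {
  set.seed(42)
  for (trial in 1:25) {
    n <- sample(4:16, 1)
    emb <- matrix(rnorm(n * 3), n)
    labels <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- setdiff(c("benign", "malignant"), labels[2])
    for (distance in c("euclidean", "cosine")) {
      m <- sample(c(0.1, 0.2, 0.5), 1)
      got <- sortTriplets(mineSemiHard(emb, labels, m, distance))
      want <- sortTriplets(oracleMine(emb, labels, m, distance))
      expect_equal(got, want, tolerance = 1e-9)
      # mined losses always fall strictly inside (0, m)
      if (nrow(got)) {
        loss <- tripletLoss(got$d_ap, got$d_an, m)
        expect_true(all(loss > 0 & loss < m + 1e-12))
      }
      # all_valid keeps the whole band
      gotall <- sortTriplets(mineSemiHard(emb, labels, m, distance,
                                          rule = "all_valid"))
      wantall <- sortTriplets(oracleMine(emb, labels, m, distance,
                                         rule = "all_valid"))
      expect_equal(gotall, wantall, tolerance = 1e-9)
    }
  }
})

test_that("analytic distance gradients match finite differences", {
  gradCheck <- function(distance) {
    set.seed(7)
    a <- rnorm(5); b <- rnorm(5)
    d0 <- oracleDist(a, b, distance)
    g <- tripletKNN:::distanceGradients(matrix(a, 1), matrix(b, 1), d0,
                                        distance)
    eps <- 1e-6
    num_a <- vapply(1:5, function(i) {
      ap <- a; ap[i] <- ap[i] + eps
      am <- a; am[i] <- am[i] - eps
      (oracleDist(ap, b, distance) - oracleDist(am, b, distance)) / (2 * eps)
    }, numeric(1))
    num_b <- vapply(1:5, function(i) {
      bp <- b; bp[i] <- bp[i] + eps
      bm <- b; bm[i] <- bm[i] - eps
      (oracleDist(a, bp, distance) - oracleDist(a, bm, distance)) / (2 * eps)
    }, numeric(1))
    expect_equal(as.numeric(g$ga), num_a, tolerance = 1e-5)
    expect_equal(as.numeric(g$gb), num_b, tolerance = 1e-5)
  }
  gradCheck("euclidean")
  gradCheck("cosine")
})

test_that("training reduces the mined loss on separable corpora", {
  for (s in 1:3) {
    corpus <- makeTestCorpus(seed = 40 + s, sep = 10, noise = 1, dim = 48,
                             patients = 5, images = 6)
    model <- trainEmbedding(corpus, cfg = trainConfig(epochs = 12,
                                                      learning_rate = 1e-2,
                                                      seed = s),
                            model = embeddingModel(48, 8, seed = s))
    h <- lossHistory(model)
    expect_length(h, 12L)
    expect_lt(h[12], h[1])
    # margin bound: every mined triplet in every epoch has loss in (0, m]
    st <- model@config$epochStats
    mined <- st[st$n_triplets > 0, ]
    expect_true(all(mined$min_loss > 0))
    expect_true(all(mined$max_loss <= modelMargin(model) + 1e-12))
  }
})

test_that("training is seed-deterministic and honours degenerate configs", {
  corpus <- makeTestCorpus(seed = 50, dim = 24, patients = 4, images = 5)
  x <- featureMatrix(corpus); lab <- classLabels(corpus)
  init <- embeddingModel(24, 6, seed = 2)

  m1 <- trainEmbedding(x, lab, trainConfig(epochs = 4, learning_rate = 1e-2,
                                           seed = 3), init)
  m2 <- trainEmbedding(x, lab, trainConfig(epochs = 4, learning_rate = 1e-2,
                                           seed = 3), init)
  expect_identical(modelWeights(m1), modelWeights(m2))
  expect_identical(lossHistory(m1), lossHistory(m2))

  # zero epochs: the returned model is the initialisation
  m0 <- trainEmbedding(x, lab, trainConfig(epochs = 0, seed = 3), init)
  expect_equal(modelWeights(m0), modelWeights(init))
  expect_length(lossHistory(m0), 0L)

  expect_error(trainEmbedding(x, rep("benign", nrow(x)),
                              trainConfig(seed = 1), init), "two classes")
  expect_error(trainEmbedding(x[, 1:10], lab, trainConfig(seed = 1), init),
               "dimension")
})

test_that("training improves the inter/intra separation ratio", {
  # class_separation >= 5 * noise_sd: the learned map should sharpen class
  # structure relative to the random initial projection in >= 8/10 seeds
  wins <- 0L
  for (s in 1:10) {
    corpus <- makeTestCorpus(seed = 60 + s, sep = 5, noise = 1, dim = 64,
                             patients = 4, images = 6, mags = 40L)
    x <- featureMatrix(corpus); lab <- classLabels(corpus)
    init <- embeddingModel(64, 16, seed = s)
    trained <- trainEmbedding(x, lab,
                              trainConfig(epochs = 10, learning_rate = 1e-2,
                                          seed = s), init)
    before <- separationRatio(embedFeatures(init, x), lab)
    after <- separationRatio(embedFeatures(trained, x), lab)
    if (after >= before) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("embedding application is a plain linear map with declared shape", {
  w <- diag(3)
  model <- methods::new("EmbeddingModel", weights = w, distance = "euclidean",
                        margin = 0.2, normalized = FALSE, config = list(),
                        lossHistory = numeric(0))
  x <- matrix(rnorm(12), 4)
  expect_equal(embedFeatures(model, x), x)            # identity weights
  expect_equal(embedFeatures(model, 3 * x), 3 * embedFeatures(model, x))
  e0 <- embedFeatures(model, x[0, , drop = FALSE])    # zero rows
  expect_equal(dim(e0), c(0L, 3L))
  expect_error(embedFeatures(model, matrix(0, 2, 5)), "expects")

  mn <- methods::new("EmbeddingModel", weights = w, distance = "euclidean",
                     margin = 0.2, normalized = TRUE, config = list(),
                     lossHistory = numeric(0))
  en <- embedFeatures(mn, x)
  expect_equal(unname(rowSums(en^2)), rep(1, 4))
})

test_that("model files round-trip weights and metadata exactly", {
  corpus <- makeTestCorpus(seed = 70, dim = 16, patients = 3, images = 4)
  model <- trainEmbedding(corpus,
                          cfg = trainConfig(epochs = 3, learning_rate = 1e-2,
                                            seed = 1),
                          model = embeddingModel(16, 4, distance = "cosine",
                                                 margin = 0.35,
                                                 normalized = TRUE, seed = 1))
  path <- withr::local_tempfile(fileext = ".txt")
  writeEmbeddingModel(model, path)
  back <- readEmbeddingModel(path)
  expect_identical(modelWeights(back), modelWeights(model))
  expect_identical(modelDistance(back), "cosine")
  expect_identical(modelMargin(back), 0.35)
  expect_true(back@normalized)
  expect_equal(lossHistory(back), lossHistory(model))
  expect_error(readEmbeddingModel(withr::local_tempfile(lines = "nope")),
               "not a tripletKNN model")
})

test_that("embeddingModel validates its geometry", {
  expect_error(embeddingModel(8, 8), "smaller")
  expect_error(embeddingModel(8, 4, margin = -1), "margin")
  m <- embeddingModel(8, 4, seed = 1)
  expect_equal(embeddingDim(m), 4L)
  expect_equal(inputDim(m), 8L)
  expect_identical(modelWeights(embeddingModel(8, 4, seed = 1)),
                   modelWeights(m))
})
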