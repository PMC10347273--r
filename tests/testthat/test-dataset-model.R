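# Dataset model: filename decoding, manifest container, magnification
# restriction, fold validation, file round trips.

test_that("BreakHis filenames decode per the token grammar", {
  # hand-decoded reference cases
  r <- decodeBreakhisFilename("SOB_B_TA-14-4659-40-001.png")
  expect_equal(r$class_label, "benign")
  expect_equal(r$subclass, "TA")
  expect_equal(r$patient_id, "14-4659")
  expect_equal(r$magnification, 40L)
  expect_equal(r$image_id, "SOB_B_TA-14-4659-40-001")

  r2 <- decodeBreakhisFilename("SOB_M_DC-14-10926-400-012.png")
  expect_equal(r2$class_label, "malignant")
  expect_equal(r2$subclass, "DC")
  expect_equal(r2$magnification, 400L)

  r3 <- decodeBreakhisFilename("SOB_B_F-14-9133-100-003.png")
  expect_equal(r3$subclass, "F")
  expect_equal(r3$patient_id, "14-9133")
  expect_equal(r3$magnification, 100L)

  # slide ids may carry section letters
  r4 <- decodeBreakhisFilename("SOB_M_LC-14-15687B-200-002.png")
  expect_equal(r4$patient_id, "14-15687B")

  # class/subclass token contradiction and free-form names do not decode
  expect_null(decodeBreakhisFilename("SOB_B_DC-14-10926-400-012.png"))
  expect_null(decodeBreakhisFilename("notes.png"))
  expect_null(decodeBreakhisFilename("SOB_B_TA-14-4659-50-001.png"))
})

test_that("parseBreakhisTree scans a tree, reports unparsable files", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "benign"), showWarnings = FALSE)
  good <- c("SOB_B_TA-14-4659-40-001.png", "SOB_B_TA-14-4659-100-001.png",
            "SOB_M_DC-14-10926-400-012.png")
  for (f in good) file.create(file.path(root, "benign", f))
  file.create(file.path(root, "stray_image.png"))

  expect_warning(corpus <- parseBreakhisTree(root), "did not match")
  expect_s4_class(corpus, "PatchCorpus")
  expect_equal(ncol(corpus), 3L)
  expect_equal(S4Vectors::metadata(corpus)$n_unparsed, 1L)
  expect_match(S4Vectors::metadata(corpus)$unparsed, "stray_image")
  expect_setequal(patientIds(corpus), c("14-4659", "14-10926"))

  empty <- withr::local_tempdir()
  expect_error(parseBreakhisTree(empty), "no files matching")
  expect_error(parseBreakhisTree(file.path(root, "nope")), "does not exist")
})

test_that("PatchCorpus enforces the subclass/class mapping and unique ids", {
  mf <- data.frame(image_id = c("a", "b"), patient_id = c("p", "q"),
                   class_label = c("benign", "malignant"),
                   subclass = c("TA", "DC"), magnification = c(40L, 40L))
  expect_s4_class(PatchCorpus(mf), "PatchCorpus")

  bad <- mf; bad$subclass <- c("DC", "DC")  # DC is malignant-only
  expect_error(PatchCorpus(bad), "mismatch")

  dup <- mf; dup$image_id <- c("a", "a")
  expect_error(PatchCorpus(dup), "unique")

  badmag <- mf; badmag$magnification <- c(40L, 50L)
  expect_error(PatchCorpus(badmag), "magnification")
})

test_that("magnification restrictions partition the corpus and are idempotent", {
  corpus <- makeTestCorpus(seed = 3, patients = 3, images = 8)
  sizes <- vapply(c(40L, 100L, 200L, 400L),
                  function(m) ncol(restrictToMagnification(corpus, m)), 1L)
  expect_equal(sum(sizes), ncol(corpus))

  r40 <- restrictToMagnification(corpus, 40)
  expect_true(all(magnifications(r40) == 40L))
  expect_equal(ncol(restrictToMagnification(r40, 40)), ncol(r40))
  expect_error(restrictToMagnification(corpus, 60), "magnification")
})

test_that("fold validation catches patient leakage and scope violations", {
  corpus <- makeTestCorpus(seed = 4, patients = 4, images = 4)
  mf <- manifest(corpus)
  pat <- split(mf$image_id, mf$patient_id)

  good <- FoldSplit(1, trainIds = unlist(pat[1:5]), testIds = unlist(pat[6:8]))
  expect_true(validateFold(good, corpus)$pass)

  # put one image of a training patient into test: leakage must be caught
  leaky_pat <- names(pat)[1L]
  leak <- FoldSplit(1, trainIds = setdiff(unlist(pat[1:5]), pat[[1L]][1L]),
                    testIds = c(unlist(pat[6:8]), pat[[1L]][1L]))
  v <- validateFold(leak, corpus)
  expect_false(v$pass)
  expect_true(leaky_pat %in% v$shared_patients)

  # MSB fold holding a 40x record under a 100x scope
  msb <- FoldSplit(1, trainIds = mf$image_id[mf$magnification == 100][1:4],
                   testIds = mf$image_id[mf$magnification == 40][1:2],
                   scope = "MSB", magnification = 100L)
  v2 <- validateFold(msb, corpus)
  expect_false(v2$pass)
  expect_true(length(v2$scope_violations) > 0)

  expect_error(validateFold(FoldSplit(1, "ghost", mf$image_id[1]), corpus),
               "ghost")
})

test_that("manifest, feature-table and fold files round-trip losslessly", {
  corpus <- makeTestCorpus(seed = 5, patients = 3, images = 4, dim = 8)
  tmp <- withr::local_tempdir()

  mp <- file.path(tmp, "manifest.tsv")
  writeManifest(corpus, mp)
  back <- readManifest(mp)
  expect_equal(manifest(back), manifest(corpus))

  fp <- file.path(tmp, "features.tsv")
  writeFeatureTable(corpus, fp)
  x <- readFeatureTable(fp)
  expect_equal(x, featureMatrix(corpus), tolerance = 1e-12,
               ignore_attr = FALSE)

  full <- readCorpus(mp, fp)
  expect_equal(featureMatrix(full), featureMatrix(corpus), tolerance = 1e-12)
  expect_equal(manifest(full), manifest(corpus))

  folds <- makeDefaultFolds(corpus, k = 3, seed = 5)
  fol <- file.path(tmp, "folds.tsv")
  writeFolds(folds, fol)
  folds2 <- readFolds(fol)
  expect_equal(length(folds2), 3L)
  for (i in 1:3) {
    expect_equal(trainIds(folds2[[i]]), trainIds(folds[[i]]))
    expect_equal(testIds(folds2[[i]]), testIds(folds[[i]]))
  }

  # per-fold list-file ingestion (paths; ids = basename sans extension)
  tr <- file.path(tmp, "f1_train.txt"); te <- file.path(tmp, "f1_test.txt")
  writeLines(file.path("some/dir", paste0(trainIds(folds[[1]]), ".png")), tr)
  writeLines(paste0(testIds(folds[[1]]), ".png"), te)
  f1 <- foldFromFiles(tr, te, foldIndex = 1)
  expect_equal(trainIds(f1), trainIds(folds[[1]]))
  expect_equal(testIds(f1), testIds(folds[[1]]))
})

test_that("feature-less corpora refuse feature access but keep the manifest", {
  mf <- data.frame(image_id = "a", patient_id = "p", class_label = "benign",
                   subclass = "A", magnification = 40L)
  m <- PatchCorpus(mf)
  expect_error(featureMatrix(m), "no features")
  expect_equal(imageIds(m), "a")
})
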