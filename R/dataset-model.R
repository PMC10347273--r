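# Dataset model: BreakHis-style directory ingestion, manifest and feature
# table IO, fold ingestion and patient-disjointness validation.

# BreakHis filename grammar (the dataset's published token convention):
#   <PROCEDURE>_<B|M>_<SUBCLASS>-<YEAR>-<SLIDE>-<MAGNIFICATION>-<SEQ>.png
# e.g. SOB_B_TA-14-4659-40-001.png.  The patient surrogate is the compound
# "<YEAR>-<SLIDE>" token, the only per-patient key the filenames carry.
BREAKHIS_RE <- "^([A-Za-z]+)_(B|M)_([A-Z]+)-([0-9]+)-([0-9A-Za-z.]+)-(40|100|200|400)-([0-9]+)\\.(png|PNG)$"

#' Decode one BreakHis-convention filename
#'
#' @param filename a file name (directory part ignored).
#' @return a one-row `data.frame` with `image_id`, `patient_id`,
#'   `class_label`, `subclass`, `magnification`, or `NULL` when the name does
#'   not follow the convention.
#' @examples
#' decodeBreakhisFilename("SOB_B_TA-14-4659-40-001.png")
#' @export
decodeBreakhisFilename <- function(filename) {
  base <- basename(filename)
  m <- regmatches(base, regexec(BREAKHIS_RE, base))[[1L]]
  if (!length(m)) return(NULL)
  subclass <- m[4L]
  class_label <- if (m[3L] == "B") "benign" else "malignant"
  if (subclassClass(subclass) != class_label) return(NULL)
  data.frame(
    image_id = sub("\\.(png|PNG)$", "", base),
    patient_id = paste(m[5L], m[6L], sep = "-"),
    class_label = class_label,
    subclass = subclass,
    magnification = as.integer(m[7L]),
    stringsAsFactors = FALSE)
}

#' Scan a BreakHis-style directory tree into a manifest
#'
#' Walks `root` recursively, decodes every PNG filename following the
#' BreakHis token convention and returns a manifest-only [PatchCorpus-class]
#' (`source` = file path).  Files that do not parse are not silently
#' dropped: their paths are collected in `metadata(x)$unparsed` and a warning
#' reports their count.
#'
#' @param root directory to scan.
#' @return a [PatchCorpus-class] manifest.
#' @export
parseBreakhisTree <- function(root) {
  if (!dir.exists(root)) stop(sprintf("directory '%s' does not exist", root))
  files <- list.files(root, pattern = "\\.(png|PNG)$", recursive = TRUE,
                      full.names = TRUE)
  decoded <- lapply(files, decodeBreakhisFilename)
  ok <- !vapply(decoded, is.null, logical(1))
  if (!any(ok)) {
    stop(sprintf("no files matching the BreakHis naming convention under '%s'",
                 root))
  }
  mf <- do.call(rbind, decoded[ok])
  mf$source <- files[ok]
  unparsed <- files[!ok]
  if (length(unparsed)) {
    warning(sprintf("%d file(s) did not match the BreakHis convention; see metadata(x)$unparsed",
                    length(unparsed)))
  }
  corpus <- PatchCorpus(mf, provenance = sprintf("scanned: %s", root))
  S4Vectors::metadata(corpus)$unparsed <- unparsed
  S4Vectors::metadata(corpus)$n_unparsed <- length(unparsed)
  corpus
}

#' Restrict a corpus to a single magnification
#'
#' The four restrictions (40, 100, 200, 400) partition any corpus.
#'
#' @param corpus a [PatchCorpus-class].
#' @param m one of 40, 100, 200, 400.
#' @return the sub-corpus at magnification `m` (possibly with 0 images).
#' @export
restrictToMagnification <- function(corpus, m) {
  m <- as.integer(m)
  if (!m %in% MAGNIFICATIONS) {
    stop("magnification must be one of 40, 100, 200, 400")
  }
  corpus[, magnifications(corpus) == m]
}

#' Validate a fold against a manifest
#'
#' Checks (a) that every id in the split exists in the manifest, (b) that no
#' patient has images on both sides (the fold discipline the patient-level
#' protocol relies on), (c) the train/test sets are disjoint, and (d) for
#' MSB folds, that every image is at the fold's magnification.
#'
#' @param split a [FoldSplit-class].
#' @param corpus a [PatchCorpus-class] (manifest is sufficient).
#' @return a list with `pass` (logical), `shared_patients` (patients seen on
#'   both sides), `scope_violations` (image ids at the wrong magnification)
#'   and `messages`.  Unknown image ids are an error naming the first one.
#' @export
validateFold <- function(split, corpus) {
  ids <- imageIds(corpus)
  all_split <- c(trainIds(split), testIds(split))
  unknown <- setdiff(all_split, ids)
  if (length(unknown)) {
    stop(sprintf("image id '%s' in fold %d is not in the manifest",
                 unknown[1L], foldIndex(split)))
  }
  pat <- setNames(patientIds(corpus), ids)
  shared <- intersect(unique(pat[trainIds(split)]),
                      unique(pat[testIds(split)]))
  overlap <- intersect(trainIds(split), testIds(split))
  scope_viol <- character(0)
  if (split@scope == "MSB") {
    mag <- setNames(magnifications(corpus), ids)
    scope_viol <- all_split[mag[all_split] != split@magnification]
  }
  msgs <- character(0)
  if (length(shared)) {
    msgs <- c(msgs, sprintf("patients on both sides: %s",
                            paste(shared, collapse = ", ")))
  }
  if (length(overlap)) {
    msgs <- c(msgs, sprintf("%d image(s) in both train and test", length(overlap)))
  }
  if (length(scope_viol)) {
    msgs <- c(msgs, sprintf("%d image(s) violate the MSB(%d) scope",
                            length(scope_viol), split@magnification))
  }
  list(pass = !length(shared) && !length(overlap) && !length(scope_viol),
       shared_patients = shared, scope_violations = scope_viol,
       messages = msgs)
}

# ---- manifest / feature-table / fold IO (delimited text) -------------------

#' Write and read manifests
#'
#' Manifests are tab-delimited UTF-8 text with a header row and columns
#' `image_id`, `patient_id`, `class_label`, `subclass`, `magnification`,
#' `source`; the round trip is lossless.
#'
#' @param corpus a [PatchCorpus-class] (features, if any, are not written;
#'   see [writeFeatureTable()]).
#' @param path file path.
#' @return `writeManifest` returns `path` invisibly; `readManifest` returns
#'   a manifest-only [PatchCorpus-class].
#' @export
writeManifest <- function(corpus, path) {
  data.table::fwrite(manifest(corpus), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest '%s' not found", path))
  mf <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "image_id"),
                          data.table = FALSE)
  PatchCorpus(mf, provenance = sprintf("manifest: %s", path))
}

#' Write and read feature tables
#'
#' Feature tables are tab-delimited text: an `image_id` column followed by
#' `f1 ... fd` numeric columns, one row per image.
#'
#' @param corpus a [PatchCorpus-class] carrying features.
#' @param path file path.
#' @return `writeFeatureTable` returns `path` invisibly; `readFeatureTable`
#'   returns an images x features matrix with image ids as row names.
#' @export
writeFeatureTable <- function(corpus, path) {
  x <- featureMatrix(corpus)
  dt <- data.table::data.table(image_id = rownames(x))
  fd <- data.table::as.data.table(x)
  data.table::setnames(fd, paste0("f", seq_len(ncol(x))))
  data.table::fwrite(cbind(dt, fd), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature table '%s' not found", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- as.character(dt$image_id)
  x <- as.matrix(dt[, -1L, drop = FALSE])
  dimnames(x) <- list(ids, NULL)
  x
}

#' Assemble a corpus from a manifest file and a feature-table file
#'
#' @param manifestPath,featuresPath file paths written by [writeManifest()]
#'   and [writeFeatureTable()] (feature rows are matched to the manifest by
#'   `image_id`, so row order need not agree).
#' @return a [PatchCorpus-class] with features.
#' @export
readCorpus <- function(manifestPath, featuresPath) {
  corpus <- readManifest(manifestPath)
  x <- readFeatureTable(featuresPath)
  missing_ids <- setdiff(imageIds(corpus), rownames(x))
  if (length(missing_ids)) {
    stop(sprintf("feature table lacks %d manifest image(s), e.g. '%s'",
                 length(missing_ids), missing_ids[1L]))
  }
  PatchCorpus(manifest(corpus), features = x[imageIds(corpus), , drop = FALSE],
              provenance = sprintf("manifest: %s + features: %s",
                                   manifestPath, featuresPath))
}

#' Write and read fold definitions
#'
#' The single-table format has columns `fold`, `scope`, `magnification`,
#' `role` (`train`/`test`) and `image_id`.
#'
#' @param folds a list of [FoldSplit-class].
#' @param path file path.
#' @return `writeFolds` returns `path` invisibly; `readFolds` a list of
#'   [FoldSplit-class].
#' @export
writeFolds <- function(folds, path) {
  rows <- lapply(folds, function(f) {
    data.frame(fold = foldIndex(f), scope = f@scope,
               magnification = f@magnification,
               role = rep(c("train", "test"),
                          c(length(trainIds(f)), length(testIds(f)))),
               image_id = c(trainIds(f), testIds(f)),
               stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname writeFolds
#' @export
readFolds <- function(path) {
  if (!file.exists(path)) stop(sprintf("fold table '%s' not found", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  lapply(sort(unique(dt$fold)), function(i) {
    sub <- dt[dt$fold == i, , drop = FALSE]
    FoldSplit(i, trainIds = sub$image_id[sub$role == "train"],
              testIds = sub$image_id[sub$role == "test"],
              scope = sub$scope[1L],
              magnification = sub$magnification[1L])
  })
}

#' Build a fold from per-fold train/test list files
#'
#' Consumes the released per-fold text-file format: one image path or image
#' id per line; ids are taken as the base file name without extension.
#'
#' @param trainFile,testFile paths to the two list files.
#' @param foldIndex fold number.
#' @param scope `"MIB"` or `"MSB"`.
#' @param magnification required when `scope = "MSB"`.
#' @return a [FoldSplit-class].
#' @export
foldFromFiles <- function(trainFile, testFile, foldIndex, scope = "MIB",
                          magnification = NA_integer_) {
  readIds <- function(p) {
    if (!file.exists(p)) stop(sprintf("fold list '%s' not found", p))
    lines <- trimws(readLines(p, warn = FALSE))
    lines <- lines[nzchar(lines)]
    sub("\\.[A-Za-z]+$", "", basename(lines))
  }
  FoldSplit(foldIndex, trainIds = readIds(trainFile),
            testIds = readIds(testFile), scope = scope,
            magnification = magnification)
}

#' Restrict a fold to the images present in a (sub-)corpus
#'
#' Used to derive magnification-specific folds from global ones: the global
#' fold's train/test ids are intersected with the corpus image set.
#'
#' @param split a [FoldSplit-class].
#' @param corpus the (typically magnification-restricted) corpus.
#' @param scope,magnification scope tags for the derived fold.
#' @return a [FoldSplit-class].
#' @export
restrictFold <- function(split, corpus, scope = split@scope,
                         magnification = split@magnification) {
  ids <- imageIds(corpus)
  FoldSplit(foldIndex(split),
            trainIds = intersect(trainIds(split), ids),
            testIds = intersect(testIds(split), ids),
            scope = scope, magnification = magnification)
}
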