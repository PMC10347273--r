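# Backbone contract: image -> fixed-length feature vector from a FROZEN
# extractor.  The pipeline's published contract is "feature table in,
# everything downstream identical", so any extractor satisfying the
# determinism contract can stand in front; a deterministic stub extractor
# lets end-to-end image paths run without a deep-learning runtime.

#' FeatureExtractor: the frozen image-to-features contract
#'
#' @slot name extractor name.
#' @slot outputDim fixed output dimensionality (2048 for the conventional
#'   pretrained backbone).
#' @slot resize target size (height, width) applied before extraction; the
#'   canonical preprocessing resizes every patch to 224 x 224.
#' @slot fun function mapping a numeric pixel array (values in \[0, 1\],
#'   already resized) to a length-`outputDim` numeric vector.
#' @seealso [stubExtractor()], [extractFeatures()]
#' @export
setClass("FeatureExtractor",
  representation(name = "character", outputDim = "integer",
                 resize = "integer", fun = "function"))

setMethod("show", "FeatureExtractor", function(object) {
  cat(sprintf("FeatureExtractor '%s': -> %d features (resize %dx%d)\n",
              object@name, object@outputDim, object@resize[1L], object@resize[2L]))
  invisible(NULL)
})

#' Deterministic stub feature extractor
#'
#' Maps an image to a reproducible pseudo-random feature vector keyed on a
#' hash of its (resized) pixel content and `seed`: identical images always
#' produce identical vectors (the frozen-extractor property) and different
#' seeds produce unrelated tables.  It exists so that image-mode paths are
#' testable without a deep-learning runtime; it carries no visual semantics.
#'
#' @param seed integer seed baked into the extractor.
#' @param dim output dimensionality (>= 2; default 2048 to match the
#'   backbone convention).
#' @param resize target (height, width); default `c(224, 224)`.
#' @return a [FeatureExtractor-class].
#' @export
stubExtractor <- function(seed = 1L, dim = 2048L, resize = c(224L, 224L)) {
  dim <- assertCount(dim, "dim", min = 2L)
  seed <- as.integer(seed)
  fun <- function(px) {
    q <- as.integer(round(as.numeric(px) * 255))
    # cheap deterministic content hash (no cryptographic intent)
    h <- sum(q * ((seq_along(q) %% 9973L) + 1L)) %% 2147480009
    withSeed((h + seed * 7919L) %% 2147480009, rnorm(dim))
  }
  methods::new("FeatureExtractor", name = sprintf("stub(seed=%d)", seed),
               outputDim = dim, resize = as.integer(resize), fun = fun)
}

#' Read a PNG/JPEG image as a numeric array
#' @noRd
readImageArray <- function(path) {
  if (!file.exists(path)) stop(sprintf("image '%s' not readable", path))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG images requires the 'png' package")
  }
  png::readPNG(path)
}

#' Resize a pixel array to the extractor's target
#' @noRd
resizeImage <- function(px, target) {
  dims <- dim(px)
  if (dims[1L] == target[1L] && dims[2L] == target[2L]) return(px)
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("resizing images requires the 'EBImage' package")
  }
  out <- EBImage::resize(EBImage::Image(px,
                                        colormode = if (length(dims) == 3L) "Color" else "Grayscale"),
                         w = target[1L], h = target[2L])
  EBImage::imageData(out)
}

#' Extract features for a corpus of images
#'
#' Applies the frozen extractor to every image in `corpus` (read from the
#' `source` column), after resizing to the extractor's target (224 x 224 by
#' convention).  Output order matches the corpus; repeated extraction gives
#' identical tables.
#'
#' @param extractor a [FeatureExtractor-class].
#' @param corpus a manifest [PatchCorpus-class] whose `source` column holds
#'   readable image paths (an empty corpus yields a features assay with the
#'   declared dimension and zero images).
#' @return the corpus with a populated `features` assay.
#' @export
extractFeatures <- function(extractor, corpus) {
  stopifnot(methods::is(extractor, "FeatureExtractor"))
  mf <- manifest(corpus)
  if (nrow(mf) == 0L) {
    return(PatchCorpus(mf,
                       features = matrix(numeric(0), nrow = 0L,
                                         ncol = extractor@outputDim),
                       provenance = provenance(corpus)))
  }
  feats <- matrix(NA_real_, nrow = nrow(mf), ncol = extractor@outputDim,
                  dimnames = list(mf$image_id, NULL))
  for (i in seq_len(nrow(mf))) {
    px <- readImageArray(mf$source[i])
    px <- resizeImage(px, extractor@resize)
    v <- extractor@fun(px)
    if (length(v) != extractor@outputDim) {
      stop(sprintf("extractor returned %d values for image '%s' (expected %d)",
                   length(v), mf$image_id[i], extractor@outputDim))
    }
    feats[i, ] <- v
  }
  PatchCorpus(mf, features = feats,
              provenance = sprintf("%s | features: %s",
                                   provenance(corpus), extractor@name))
}
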