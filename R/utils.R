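# Internal utilities: scoped RNG, pairwise distances, argument checking.

BENIGN_SUBCLASSES <- c("A", "F", "TA", "PT")
MALIGNANT_SUBCLASSES <- c("DC", "LC", "MC", "PC")
MAGNIFICATIONS <- c(40L, 100L, 200L, 400L)
CLASS_LEVELS <- c("benign", "malignant")

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded internals do
#' not perturb the caller's RNG stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

subclassClass <- function(subclass) {
  ifelse(subclass %in% BENIGN_SUBCLASSES, "benign", "malignant")
}

#' Pairwise distances between the rows of two matrices
#'
#' @param a,b numeric matrices with matching column count.
#' @param distance `"euclidean"` or `"cosine"` (1 minus cosine similarity).
#' @return an `nrow(a)` x `nrow(b)` matrix of distances.
#' @noRd
pairwiseDistances <- function(a, b, distance = c("euclidean", "cosine")) {
  distance <- match.arg(distance)
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b))
  if (distance == "euclidean") {
    # ||x - y||^2 = ||x||^2 + ||y||^2 - 2 x.y, clamped against roundoff
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else {
    na <- sqrt(rowSums(a^2))
    nb <- sqrt(rowSums(b^2))
    na[na == 0] <- 1e-300
    nb[nb == 0] <- 1e-300
    sim <- tcrossprod(a / na, b / nb)
    sim[sim > 1] <- 1
    sim[sim < -1] <- -1
    1 - sim
  }
}

rowL2Normalize <- function(x) {
  n <- sqrt(rowSums(x^2))
  n[n == 0] <- 1
  x / n
}

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

assertPositive <- function(x, name, strict = TRUE) {
  ok <- length(x) == 1L && is.finite(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("'%s' must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  as.numeric(x)
}

#' Derive a stream-specific 32-bit sub-seed from a base seed
#' @noRd
deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(offset) %% 2011L
}
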