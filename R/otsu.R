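# Multi-level Otsu thresholding (three thresholds, four classes) by
# exhaustive scan of all ordered triples over the 256-bin histogram.

# cached triple enumeration (t1 < t2 < t3, lexicographic order)
.otsu_env <- new.env(parent = emptyenv())

.otsu_triples <- function() {
  if (is.null(.otsu_env$t1)) {
    t1 <- rep.int(1:253, choose(255L - 1:253, 2L))
    t2 <- unlist(lapply(1:253, function(k) {
      v <- (k + 1L):254L
      rep.int(v, 255L - v)
    }), use.names = FALSE)
    t2_pairs <- unlist(lapply(1:253, function(k) (k + 1L):254L),
                       use.names = FALSE)
    t3 <- unlist(lapply(t2_pairs, function(j) (j + 1L):255L),
                 use.names = FALSE)
    .otsu_env$t1 <- t1; .otsu_env$t2 <- t2; .otsu_env$t3 <- t3
  }
  .otsu_env
}

#' Three-level Otsu thresholds
#'
#' Finds the threshold triple \code{t1 < t2 < t3} (integers in
#' \code{[1, 255]}) maximizing the between-class variance of the four classes
#' \code{[0, t1)}, \code{[t1, t2)}, \code{[t2, t3)}, \code{[t3, 255]} over
#' the 256-bin histogram of an 8-bit image. All ~2.7 million ordered triples
#' are scanned; ties are broken by the lexicographically smallest triple, so
#' the result is fully deterministic.
#'
#' @param img integer matrix with values in \code{[0, 255]}, or a vector of
#'   such values (e.g. a restricted histogram sample).
#' @return Integer vector \code{c(t1, t2, t3)}.
#' @export
otsu3_thresholds <- function(img) {
  v <- as.integer(img)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty image")
  if (any(v < 0L | v > 255L)) stop("values must be in [0, 255]")
  if (length(unique(v)) < 4L)
    stop("degenerate histogram: fewer than 4 distinct values")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  S0 <- c(0, cumsum(p))                       # S0[k+1] = P(value <= k-1)
  S1 <- c(0, cumsum(p * (0:255)))
  tr <- .otsu_triples()
  # class (lo..hi) weight and mean-sum via cumulative lookups
  csum <- function(S, lo, hi) S[hi + 2L] - S[lo + 1L]
  obj_term <- function(lo, hi) {
    w <- csum(S0, lo, hi)
    m <- csum(S1, lo, hi)
    out <- numeric(length(w))
    nz <- w > 0
    out[nz] <- m[nz]^2 / w[nz]
    out
  }
  obj <- obj_term(rep(0L, length(tr$t1)), tr$t1 - 1L) +
    obj_term(tr$t1, tr$t2 - 1L) +
    obj_term(tr$t2, tr$t3 - 1L) +
    obj_term(tr$t3, rep(255L, length(tr$t1)))
  i <- which.max(obj)
  c(t1 = tr$t1[i], t2 = tr$t2[i], t3 = tr$t3[i])
}

#' Binarize an image below a threshold
#'
#' @param img integer matrix with values in \code{[0, 255]}.
#' @param t integer threshold in \code{[1, 255]}.
#' @return Integer matrix with 255 where \code{img < t}, else 0.
#' @export
threshold_below <- function(img, t) {
  t <- as.integer(t)
  if (length(t) != 1L || is.na(t) || t < 1L || t > 255L)
    stop("threshold must be an integer in [1, 255]")
  out <- matrix(0L, nrow(img), ncol(img))
  out[img < t] <- 255L
  out
}
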