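#' Seeded 4-cluster k-means on Lab pixels
#'
#' Batch k-means (k = 4, squared Euclidean distance in the 8-bit Lab space)
#' whose initial centroids are derived from a binary seed image: centroid 0
#' is the mean Lab colour of pixels that are black in the seed, centroid 1
#' the mean of pixels that are white (the strongly stained extreme), and
#' centroids 2 and 3 interpolate at 1/3 and 2/3 between them. The procedure
#' is fully deterministic: batch updates, convergence when every centroid
#' moves by less than 1 Lab unit, at most \code{max_iter} iterations, empty
#' clusters keep their previous centroid.
#'
#' After convergence cluster indices are re-anchored to the seeds: index 1 is
#' the converged centroid nearest the white seed, index 0 the one nearest the
#' black seed, and of the remaining two the one nearer centroid 1 gets index
#' 2, the other index 3. Index 1 therefore tracks the strongly stained
#' cluster and indices 2/3 the intermediate (low / unstained) colours.
#'
#' @param lab a \code{lab_image}.
#' @param bin binary seed matrix (values 0/255) of the same dimensions.
#' @param max_iter iteration cap (default 20).
#' @param tol centroid-shift convergence tolerance in Lab units (default 1).
#' @return Integer matrix of cluster labels in \code{{0, 1, 2, 3}}.
#' @export
seeded_kmeans4 <- function(lab, bin, max_iter = 20L, tol = 1.0) {
  stopifnot(inherits(lab, "lab_image"))
  white <- bin == 255L
  n_white <- sum(white)
  if (n_white == 0L || n_white == length(bin))
    stop("seed image must contain both white and black pixels")
  X <- cbind(as.numeric(lab$L), as.numeric(lab$a), as.numeric(lab$b))
  w <- as.vector(white)
  c0 <- colMeans(X[!w, , drop = FALSE])
  c1 <- colMeans(X[w, , drop = FALSE])
  cen <- rbind(c0, c1, c0 + (c1 - c0) / 3, c0 + 2 * (c1 - c0) / 3)
  for (it in seq_len(max_iter)) {
    d <- .dist2_to_centroids(X, cen)
    assign <- max.col(-d, ties.method = "first")
    new_cen <- cen
    for (k in 1:4) {
      sel <- assign == k
      if (any(sel)) new_cen[k, ] <- colMeans(X[sel, , drop = FALSE])
    }
    shift <- sqrt(rowSums((new_cen - cen)^2))
    cen <- new_cen
    if (max(shift) < tol) break
  }
  d <- .dist2_to_centroids(X, cen)
  assign <- max.col(-d, ties.method = "first")
  # anchor converged centroids back to the seed extremes
  seed1 <- which.min(colSums((t(cen) - c1)^2))
  d0 <- colSums((t(cen) - c0)^2); d0[seed1] <- Inf
  seed0 <- which.min(d0)
  rest <- setdiff(1:4, c(seed0, seed1))
  d_to1 <- colSums((t(cen[rest, , drop = FALSE]) - cen[seed1, ])^2)
  ord <- rest[order(d_to1)]
  relabel <- integer(4L)
  relabel[c(seed0, seed1, ord[1], ord[2])] <- 0:3
  matrix(relabel[assign], nrow(lab$L), ncol(lab$L))
}

.dist2_to_centroids <- function(X, cen) {
  # squared distances, n x k
  cross <- X %*% t(cen)
  sweep(-2 * cross, 2, rowSums(cen^2), `+`) + rowSums(X^2)
}

#' Binary mask of one k-means cluster
#'
#' @param labels integer matrix of cluster labels.
#' @param k cluster index in \code{{1, 2, 3}}.
#' @param close apply a morphological closing with a 3x3 square structuring
#'   element (used for the low/unstained clusters to fill small holes).
#' @return Binary matrix (0/255).
#' @export
cluster_mask <- function(labels, k, close = FALSE) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  m <- matrix(0L, nrow(labels), ncol(labels))
  m[labels == k] <- 255L
  if (close) {
    img <- EBImage::closing(EBImage::Image(m / 255),
                            EBImage::makeBrush(3L, shape = "box"))
    m <- matrix(as.integer(img@.Data > 0.5) * 255L, nrow(m), ncol(m))
  }
  m
}
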