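#' Gaussian kernel between two vectors
#'
#' `K(x, y) = exp(-||x - y||^2 / (2 sigma^2))`, the radial basis function
#' kernel whose bandwidth `sigma` controls the geometry of the induced
#' feature space.
#'
#' @param x,y Numeric vectors of equal length.
#' @param sigma Positive bandwidth.
#' @return Kernel value in (0, 1].
#' @export
#' @examples
#' gaussian_kernel(c(0, 0), c(3, 4), sigma = 5) # exp(-0.5)
gaussian_kernel <- function(x, y, sigma) {
  check_sigma(sigma)
  if (length(x) != length(y)) stop_user("`x` and `y` must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_user("inputs must be finite")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop_user("`sigma` must be a single finite positive number")
  }
  invisible(sigma)
}

#' Gaussian Gram matrix of a sample
#'
#' @param x Numeric N x D matrix (or feature tibble; see
#'   [as_feature_matrix()] conventions).
#' @param sigma Positive bandwidth.
#' @return Symmetric N x N matrix with unit diagonal, positive
#'   semidefinite up to numerical round-off.
#' @export
kernel_matrix <- function(x, sigma) {
  check_sigma(sigma)
  x <- as_feature_matrix(x)$x
  if (nrow(x) < 2L) stop_user("kernel_matrix needs N >= 2 samples")
  d2 <- as.matrix(dist(x))^2
  k <- exp(-d2 / (2 * sigma^2))
  k <- (k + t(k)) / 2
  diag(k) <- 1
  k
}

# cross Gram matrix between new points (rows of a) and training points
# (rows of b): M x N
kernel_cross <- function(a, b, sigma) {
  check_sigma(sigma)
  if (ncol(a) != ncol(b)) {
    stop_user(sprintf("feature dimension mismatch: %d vs %d", ncol(a), ncol(b)))
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Median pairwise distance heuristic
#'
#' Median of the Euclidean pairwise distances between rows; a standard
#' reference scale for Gaussian bandwidths.
#'
#' @param x Feature matrix or tibble.
#' @return Positive scalar.
#' @export
median_pairwise_distance <- function(x) {
  x <- as_feature_matrix(x)$x
  d <- as.numeric(dist(x))
  d <- d[d > 0]
  if (length(d) == 0L) stop_user("all points coincide; no pairwise distance scale")
  stats::median(d)
}
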