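#' Within-class dispersion of projected samples
#'
#' `D_W = sum_i sum_m ||r_m^i - a_i||^2`: total squared Euclidean deviation
#' of each sample from its class mean.
#'
#' @param r Numeric N x d matrix of (projected) samples, or a feature
#'   tibble.
#' @param labels Length-N class labels (taken from the tibble's `label`
#'   column when omitted).
#' @return Nonnegative scalar.
#' @export
within_dispersion <- function(r, labels = NULL) {
  fm <- as_feature_matrix(r, labels)
  x <- fm$x
  labels <- fm$labels
  check_labels(labels, nrow(x))
  centered <- x - class_means(x, labels)[labels, , drop = FALSE]
  sum(centered^2)
}

#' Between-class dispersion of projected samples
#'
#' `D_B = sum_i ||a_i - a||^2`: squared distance of each class mean from the
#' global sample mean, summed over classes. The sum is unweighted by class
#' size (each class counts once); set `weighted = TRUE` for the
#' class-size-weighted variant.
#'
#' @inheritParams within_dispersion
#' @param weighted Weight each class term by its size N_i (default `FALSE`).
#' @return Nonnegative scalar.
#' @export
between_dispersion <- function(r, labels = NULL, weighted = FALSE) {
  fm <- as_feature_matrix(r, labels)
  x <- fm$x
  labels <- fm$labels
  check_labels(labels, nrow(x))
  a <- colMeans(x)
  mu <- class_means(x, labels)
  sq <- rowSums((mu - matrix(a, nrow(mu), ncol(mu), byrow = TRUE))^2)
  if (weighted) {
    n_i <- as.integer(table(factor(labels, levels = rownames(mu))))
    sum(n_i * sq)
  } else {
    sum(sq)
  }
}

#' Dispersion ratio criterion for reduced data
#'
#' The class separability score maximized when selecting the kernel
#' bandwidth: `D_B / D_W`, the between-class over within-class dispersion of
#' the projected samples. Larger is better. When all within-class spread
#' vanishes but classes sit at distinct means the ratio is `+Inf` (a
#' sentinel that compares greater than any finite fitness); when both
#' dispersions are zero the ratio is 0 by convention.
#'
#' @inheritParams within_dispersion
#' @param weighted Use the class-size-weighted between-class dispersion.
#' @return A list of class `dispersion_criterion` with elements `d_w`,
#'   `d_b`, `ratio`.
#' @export
dispersion_criterion <- function(r, labels = NULL, weighted = FALSE) {
  fm <- as_feature_matrix(r, labels)
  labels <- fm$labels
  check_labels(labels, nrow(fm$x))
  if (length(unique(labels)) < 2L) {
    stop_user("dispersion criterion requires at least 2 classes")
  }
  d_w <- within_dispersion(fm$x, labels)
  d_b <- between_dispersion(fm$x, labels, weighted = weighted)
  ratio <- if (d_w == 0 && d_b == 0) {
    0
  } else if (d_w == 0) {
    Inf
  } else {
    d_b / d_w
  }
  structure(list(d_w = d_w, d_b = d_b, ratio = ratio),
            class = "dispersion_criterion")
}

#' @export
print.dispersion_criterion <- function(x, ...) {
  cat(sprintf("<dispersion_criterion> D_B = %.6g, D_W = %.6g, ratio = %.6g\n",
              x$d_b, x$d_w, x$ratio))
  invisible(x)
}

class_means <- function(x, labels) {
  g <- factor(labels)
  mu <- rowsum(x, g) / as.vector(table(g))
  rownames(mu) <- levels(g)
  mu
}

check_labels <- function(labels, n) {
  if (is.null(labels)) stop_user("class labels are required (supply `labels` or a `label` column)")
  if (length(labels) != n) {
    stop_user(sprintf("%d labels for %d samples", length(labels), n))
  }
  if (anyNA(labels)) stop_user("labels must be non-missing")
  invisible(labels)
}
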