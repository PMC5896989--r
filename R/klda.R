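#' Fit kernel linear discriminant analysis (generalized discriminant analysis)
#'
#' Performs Fisher discriminant analysis in the feature space induced by a
#' Gaussian kernel, entirely in dual form: the N x N Gram matrix is
#' double-centered, the between-class dual scatter is built from the class
#' indicator structure, the within-class dual scatter is regularized by
#' adding `epsilon * I` with `epsilon = 1e-8 * trace / N` (the Gram matrix
#' is singular whenever N exceeds the effective rank), and the generalized
#' eigenproblem is solved by symmetric whitening. Discriminant directions
#' are returned as dual coefficients over the training points, ordered by
#' non-increasing eigenvalue, with the sign convention that each direction's
#' largest-magnitude coefficient is positive.
#'
#' At most `K - 1` discriminants have nonzero eigenvalues for `K` classes;
#' the conventional reduced dimension is nevertheless `d = K` (the trailing
#' direction has a near-zero eigenvalue), so the default keeps `d = K` and
#' reports the numerically effective count in `d_effective` with a warning
#' when it falls short. Requests of `d > K` are capped at `K`.
#'
#' @param data Feature tibble (columns `protein_id`, `label`, features) or
#'   numeric N x D matrix.
#' @param labels Class labels (taken from `data$label` when omitted).
#' @param sigma Positive Gaussian bandwidth.
#' @param d Reduced dimension; default: number of classes.
#' @return An object of class `klda` with elements `x_train`, `labels`,
#'   `sigma`, `alpha` (N x d dual coefficients), `eigenvalues`, `d`,
#'   `d_effective`, `projections` (N x d training projections) and the
#'   centering statistics needed by [klda_transform()].
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' fit <- klda_fit(x, rep(c("a", "b"), each = 20), sigma = 2, d = 2)
#' fit$d_effective
klda_fit <- function(data, labels = NULL, sigma, d = NULL) {
  fm <- as_feature_matrix(data, labels)
  x <- fm$x
  labels <- fm$labels
  check_labels(labels, nrow(x))
  check_sigma(sigma)
  g <- factor(labels)
  k_classes <- nlevels(g)
  n <- nrow(x)
  if (k_classes < 2L) stop_user("KLDA needs at least 2 classes")
  if (any(table(g) < 1L)) stop_user("every class needs at least one member")
  if (n < k_classes) stop_user("need at least as many samples as classes")
  if (is.null(d)) d <- k_classes
  if (d < 1L) stop_user("`d` must be a positive integer")
  if (d > k_classes) {
    warn(sprintf(
      "requested d = %d exceeds the number of classes (%d); capping at %d",
      d, k_classes, k_classes
    ))
    d <- k_classes
  }

  km <- kernel_matrix(x, sigma)
  col_means <- colMeans(km)
  grand_mean <- mean(km)
  kc <- center_gram(km, col_means, grand_mean)

  # dual scatters: class-mean kernel columns m_i = (1/N_i) Kc 1_{class i};
  # after double-centering the global mean column is 0, so
  # S_B = sum_i N_i m_i m_i', S_W = Kc Kc' - S_B
  idx <- split(seq_len(n), g)
  m_cols <- vapply(idx, function(i) rowMeans(kc[, i, drop = FALSE]), numeric(n))
  n_i <- vapply(idx, length, integer(1))
  s_b <- m_cols %*% (t(m_cols) * n_i)
  s_b <- (s_b + t(s_b)) / 2
  s_w <- kc %*% kc - s_b
  s_w <- (s_w + t(s_w)) / 2

  eps <- 1e-8 * max(sum(diag(s_w)), 1e-12) / n
  reg <- s_w + diag(eps, n)
  ch <- tryCatch(chol(reg), error = function(e) NULL)
  if (is.null(ch)) {
    stop_user(paste0(
      "within-class dual scatter is singular even after regularization ",
      sprintf("(epsilon = %.3g); bandwidth sigma = %.3g may be degenerate", eps, sigma)
    ))
  }
  # generalized problem S_B a = lambda (S_W + eps I) a via a = R^{-1} b,
  # R'R = S_W + eps I  =>  R^{-T} S_B R^{-1} b = lambda b (symmetric)
  tmp <- backsolve(ch, t(backsolve(ch, s_b, transpose = TRUE)), transpose = TRUE)
  tmp <- (tmp + t(tmp)) / 2
  es <- eigen(tmp, symmetric = TRUE)
  alpha <- backsolve(ch, es$vectors[, seq_len(d), drop = FALSE])
  eigenvalues <- es$values[seq_len(d)]

  # deterministic sign: largest-|coefficient| positive
  for (j in seq_len(ncol(alpha))) {
    i_max <- which.max(abs(alpha[, j]))
    if (alpha[i_max, j] < 0) alpha[, j] <- -alpha[, j]
  }
  colnames(alpha) <- paste0("LD", seq_len(d))

  tol <- 1e-9 * max(abs(es$values[1]), 1)
  d_effective <- sum(eigenvalues > tol)
  if (d_effective < d) {
    warn(sprintf(
      "only %d of %d requested discriminants have numerically nonzero eigenvalues",
      d_effective, d
    ))
  }

  model <- structure(
    list(
      x_train = x,
      ids = fm$ids,
      labels = as.character(labels),
      sigma = sigma,
      alpha = alpha,
      eigenvalues = eigenvalues,
      d = d,
      d_effective = d_effective,
      col_means = col_means,
      grand_mean = grand_mean
    ),
    class = "klda"
  )
  model$projections <- kc %*% alpha
  model
}

center_gram <- function(km, col_means, grand_mean) {
  sweep(sweep(km, 2L, col_means), 1L, col_means) + grand_mean
}

#' Project new samples with a fitted KLDA model
#'
#' Evaluates the Gaussian kernel between each new sample and every training
#' point, centers the resulting kernel columns with the training centering
#' statistics, and multiplies by the dual coefficients. Transforming the
#' training data reproduces the fit's own projections.
#'
#' @param model A fitted [klda_fit()] object.
#' @param newdata Feature tibble or M x D matrix with the training feature
#'   dimension.
#' @return M x d numeric matrix of projections (columns `LD1` ..).
#' @export
klda_transform <- function(model, newdata) {
  stopifnot(inherits(model, "klda"))
  fm <- as_feature_matrix(newdata)
  xz <- fm$x
  if (nrow(xz) == 0L) {
    out <- matrix(numeric(0), 0L, model$d)
    colnames(out) <- colnames(model$alpha)
    return(out)
  }
  if (ncol(xz) != ncol(model$x_train)) {
    stop_user(sprintf(
      "feature dimension mismatch: model trained on %d features, newdata has %d",
      ncol(model$x_train), ncol(xz)
    ))
  }
  kt <- kernel_cross(xz, model$x_train, model$sigma)
  ktc <- kt - rowMeans(kt) -
    matrix(model$col_means, nrow(kt), ncol(kt), byrow = TRUE) + model$grand_mean
  out <- ktc %*% model$alpha
  rownames(out) <- fm$ids
  out
}

#' @export
predict.klda <- function(object, newdata, ...) klda_transform(object, newdata)

#' @export
print.klda <- function(x, ...) {
  cat(sprintf(
    "<klda> N = %d, sigma = %.4g, d = %d (effective %d), classes: %s\n",
    nrow(x$x_train), x$sigma, x$d, x$d_effective,
    paste(unique(x$labels), collapse = ", ")
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a KLDA fit: one row per discriminant direction
#'
#' @param x A `klda` object.
#' @param ... Unused.
#' @return Tibble with `discriminant`, `eigenvalue`, `effective`.
#' @export
tidy.klda <- function(x, ...) {
  tibble(
    discriminant = colnames(x$alpha),
    eigenvalue = x$eigenvalues,
    effective = seq_along(x$eigenvalues) <= x$d_effective
  )
}

#' One-row summary of a KLDA fit
#'
#' @param x A `klda` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_classes`, `sigma`, `d`, `d_effective`, and
#'   the dispersion `ratio` of the training projections.
#' @export
glance.klda <- function(x, ...) {
  crit <- dispersion_criterion(x$projections, x$labels)
  tibble(
    n = nrow(x$x_train),
    n_classes = length(unique(x$labels)),
    sigma = x$sigma,
    d = x$d,
    d_effective = x$d_effective,
    ratio = crit$ratio
  )
}

#' Scatter plot of the first two KLDA discriminants
#'
#' @param object A `klda` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.klda <- function(object, ...) {
  proj <- object$projections
  df <- tibble(
    LD1 = proj[, 1],
    LD2 = if (ncol(proj) >= 2L) proj[, 2] else 0,
    label = object$labels
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$LD1, .data$LD2, colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(colour = "class",
                  title = sprintf("KLDA projections (sigma = %.3g)", object$sigma))
}
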