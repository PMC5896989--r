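test_that("gaussian kernel matches its closed form", {
  expect_equal(gaussian_kernel(c(1, 2, 3), c(1, 2, 3), 2), 1)
  x <- c(1, 0); y <- c(1 + sqrt(2) * 0.7, 0) # ||x-y||^2 = 2 sigma^2 at sigma 0.7
  expect_equal(gaussian_kernel(x, y, 0.7), exp(-1), tolerance = 1e-12)
  expect_equal(gaussian_kernel(c(0, 0), c(3, 4), 5), exp(-25 / 50), tolerance = 1e-12)
  expect_error(gaussian_kernel(1, 1, 0), "sigma")
  expect_error(gaussian_kernel(1, c(1, 2), 1), "equal length")
})

test_that("kernel matrix is symmetric, unit-diagonal and PSD", {
  set.seed(7)
  x <- matrix(rnorm(10 * 3), 10, 3)
  for (sigma in c(0.1, 1, 10)) {
    k <- kernel_matrix(x, sigma)
    expect_equal(k, t(k))
    expect_equal(unname(diag(k)), rep(1, 10))
    ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * 10)
  }
  expect_error(kernel_matrix(matrix(c(1, NA, 2, 3), 2, 2), 1), "non-finite")
})

test_that("the Gram matrix tends to all-ones as sigma grows", {
  set.seed(8)
  x <- matrix(rnorm(8 * 4), 8, 4)
  sigma <- 1e6 * max(dist(x))
  expect_lt(max(abs(kernel_matrix(x, sigma) - 1)), 1e-6)
})

test_that("dispersions match hand computations and double-loop oracles", {
  # 1-D, one class {0, 2}: D_W = 2
  r1 <- matrix(c(0, 2, 5), ncol = 1)
  expect_equal(within_dispersion(r1[1:2, , drop = FALSE], c("a", "a")), 2)
  # duplicated points -> zero spread
  expect_equal(within_dispersion(matrix(c(1, 1, 4, 4), 2, 2), c("a", "a")), 0)
  # 1-D classes {0},{2}: a = 1, D_B = 2
  expect_equal(between_dispersion(matrix(c(0, 2), ncol = 1), c("a", "b")), 2)
  # coincident class means
  expect_equal(between_dispersion(matrix(c(0, 1, 0, 1), ncol = 1),
                                  c("a", "a", "b", "b")), 0)

  set.seed(3)
  r <- matrix(rnorm(30 * 4), 30, 4)
  labels <- sample(letters[1:3], 30, replace = TRUE)
  expect_equal(within_dispersion(r, labels), oracle_within(r, labels),
               tolerance = 1e-10)
  expect_equal(between_dispersion(r, labels), oracle_between(r, labels),
               tolerance = 1e-10)
})

test_that("weighted between-class dispersion reduces to the unweighted one on balanced classes", {
  set.seed(12)
  r <- matrix(rnorm(20 * 3), 20, 3)
  labels <- rep(c("a", "b"), each = 10)
  expect_equal(between_dispersion(r, labels, weighted = TRUE) / 10,
               between_dispersion(r, labels), tolerance = 1e-12)
})

test_that("criterion composes the dispersions with sentinel conventions", {
  set.seed(4)
  r <- matrix(rnorm(24 * 2), 24, 2)
  labels <- rep(c("a", "b", "c"), each = 8)
  crit <- dispersion_criterion(r, labels)
  expect_equal(crit$ratio, oracle_between(r, labels) / oracle_within(r, labels),
               tolerance = 1e-10)

  # collapsed identical data -> 0 by convention
  collapsed <- matrix(1, 6, 2)
  expect_equal(dispersion_criterion(collapsed, rep(c("a", "b"), 3))$ratio, 0)

  # perfectly collapsed classes at distinct means -> +Inf sentinel
  perfect <- matrix(rep(c(0, 5), each = 3), ncol = 1)
  expect_identical(dispersion_criterion(perfect, rep(c("a", "b"), each = 3))$ratio, Inf)

  expect_error(dispersion_criterion(r, rep("a", 24)), "2 classes")
})

test_that("criterion is invariant to rigid translation and uniform scaling", {
  for (seed in 1:5) {
    set.seed(seed)
    r <- matrix(rnorm(20 * 3), 20, 3)
    labels <- sample(c("a", "b"), 20, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    base <- dispersion_criterion(r, labels)$ratio
    shift <- sweep(r, 2, c(100, -40, 7), "+")
    expect_equal(dispersion_criterion(shift, labels)$ratio, base,
                 tolerance = 1e-9)
    for (alpha in c(0.1, 10)) {
      expect_equal(dispersion_criterion(alpha * r, labels)$ratio, base,
                   tolerance = 1e-9)
    }
  }
})

test_that("klda separates well-separated blobs (LOO 1-NN = 100%)", {
  feats <- simulate_feature_clusters(2, 20, dims = 2, between_sd = 0,
                                     within_sd = 1, seed = 1)
  fm <- as.matrix(feats[, -(1:2)])
  fm[feats$label == "class1", ] <- fm[feats$label == "class1", ] + 8
  sigma <- median_pairwise_distance(fm)
  fit <- klda_fit(fm, feats$label, sigma = sigma, d = 2)
  proj <- fit$projections
  correct <- vapply(seq_len(nrow(proj)), function(i) {
    d <- as.matrix(dist(proj))[i, -i]
    nn <- which.min(d)
    feats$label[-i][nn] == feats$label[i]
  }, logical(1))
  expect_true(all(correct))
})

test_that("identical inputs map identically and transform reproduces the fit", {
  set.seed(2)
  x <- matrix(rnorm(12 * 3), 12, 3)
  x <- rbind(x, x[1:3, ]) # duplicated rows
  labels <- rep(c("a", "b", "c"), 5)
  fit <- suppressWarnings(klda_fit(x, labels, sigma = 2, d = 3))
  proj <- klda_transform(fit, x)
  expect_equal(unname(proj), unname(fit$projections), tolerance = 1e-9)
  expect_equal(unname(proj[1, ]), unname(proj[13, ]), tolerance = 1e-9)

  empty <- klda_transform(fit, x[0, , drop = FALSE])
  expect_equal(dim(empty), c(0L, 3L))
  expect_error(klda_transform(fit, matrix(1, 2, 5)), "dimension mismatch")
})

test_that("requested dimension is capped at the class count with a warning", {
  set.seed(3)
  x <- matrix(rnorm(15 * 4), 15, 4)
  labels <- rep(c("a", "b", "c"), each = 5)
  w <- capture_warnings(fit <- klda_fit(x, labels, sigma = 1.5, d = 10))
  expect_true(any(grepl("capping", w)))
  expect_lte(ncol(fit$alpha), 3L)
  expect_lte(fit$d_effective, 3L)
  expect_true(all(diff(fit$eigenvalues) <= 1e-8))
})

test_that("a query between two blobs projects between the projected class means", {
  feats <- simulate_feature_clusters(2, 15, dims = 2, between_sd = 0,
                                     within_sd = 0.5, seed = 6)
  x <- as.matrix(feats[, -(1:2)])
  x[feats$label == "class2", ] <- x[feats$label == "class2", ] + 6
  fit <- suppressWarnings(
    klda_fit(x, feats$label, sigma = median_pairwise_distance(x), d = 1)
  )
  mid <- matrix(colMeans(rbind(colMeans(x[1:15, ]), colMeans(x[16:30, ]))), 1)
  z <- klda_transform(fit, mid)[1, 1]
  m1 <- mean(fit$projections[feats$label == "class1", 1])
  m2 <- mean(fit$projections[feats$label == "class2", 1])
  expect_true(z > min(m1, m2) && z < max(m1, m2))
})

test_that("klda projections beat label-permuted projections on separated blobs", {
  wins <- vapply(1:20, function(seed) {
    feats <- simulate_feature_clusters(2, 10, dims = 3, between_sd = 6,
                                       within_sd = 1, seed = seed)
    x <- as.matrix(feats[, -(1:2)])
    sigma <- median_pairwise_distance(x)
    fit <- suppressWarnings(klda_fit(x, feats$label, sigma = sigma, d = 2))
    real <- dispersion_criterion(fit$projections, feats$label)$ratio
    set.seed(seed + 1000)
    perm <- sample(feats$label)
    fit_p <- suppressWarnings(klda_fit(x, perm, sigma = sigma, d = 2))
    null <- dispersion_criterion(fit_p$projections, perm)$ratio
    real > null
  }, logical(1))
  expect_true(all(wins))
})

test_that("klda rejects degenerate inputs", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(klda_fit(x, rep("a", 5), sigma = 1), "2 classes")
  expect_error(klda_fit(x, c("a", "a", "b", "b", "b"), sigma = -1), "sigma")
})
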