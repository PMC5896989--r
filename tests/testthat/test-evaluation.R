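test_that("cosine distance covers identical, orthogonal, antipodal and zero vectors", {
  expect_equal(cosine_distance(c(2, 1), c(2, 1)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 3)), 1)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_equal(cosine_distance(c(0, 0), c(1, 1)), 1)
  expect_equal(cosine_distance(c(0, 0), c(0, 0)), 1)
})

test_that("knn_predict handles exact matches, majorities and k bounds", {
  train <- rbind(c(1, 0), c(0.9, 0.1), c(0, 1))
  labels <- c("a", "a", "b")
  expect_equal(knn_predict(train, labels, c(0, 1), k = 1), "b")
  expect_equal(knn_predict(train, labels, c(0.5, 0.5), k = 3), "a")
  expect_error(knn_predict(train, labels, c(1, 0), k = 4), "k")
  expect_error(knn_predict(train, labels, c(1, 0), k = 0), "k")
})

test_that("knn_predict equals the exhaustive-sort oracle across random instances", {
  set.seed(13)
  train <- matrix(rnorm(50 * 4), 50, 4)
  labels <- sample(c("a", "b", "c"), 50, replace = TRUE)
  queries <- matrix(rnorm(20 * 4), 20, 4)
  for (k in c(1, 5, 9)) {
    got <- knn_predict(train, labels, queries, k = k)
    want <- apply(queries, 1, function(q) oracle_knn(train, labels, q, k))
    expect_identical(got, unname(want))
  }
})

test_that("metrics match direct formula evaluation and sentinel semantics", {
  m <- compute_metrics(data.frame(class = "a", tp = 8, tn = 9, fp = 1, fn = 2))
  pc <- m$per_class
  expect_equal(pc$se, 0.8)
  expect_equal(pc$sp, 0.9)
  expect_equal(pc$acc, 0.85)
  expect_equal(pc$mcc, (8 * 9 - 1 * 2) / sqrt(9 * 10 * 10 * 11))
  expect_equal(m$osr, 0.8)

  # perfect prediction -> MCC 1 for every class
  perfect <- compute_metrics(data.frame(
    class = c("a", "b"), tp = c(5, 7), tn = c(7, 5), fp = 0, fn = 0
  ))
  expect_equal(perfect$per_class$mcc, c(1, 1))
  expect_equal(perfect$osr, 1)

  # TP = FP = 0: nothing predicted into the class -> SE 0, MCC undefined
  degen <- compute_metrics(data.frame(class = "a", tp = 0, tn = 10, fp = 0, fn = 4))
  expect_equal(degen$per_class$se, 0)
  expect_true(is.na(degen$per_class$mcc))
})

test_that("MCC lies in [-1, 1] whenever defined (1000 random tables)", {
  set.seed(77)
  tabs <- data.frame(
    class = sprintf("c%04d", 1:1000),
    tp = sample(0:30, 1000, TRUE), tn = sample(0:30, 1000, TRUE),
    fp = sample(0:30, 1000, TRUE), fn = sample(0:30, 1000, TRUE)
  )
  mcc <- compute_metrics(tabs)$per_class$mcc
  defined <- !is.na(mcc)
  expect_true(any(defined))
  expect_true(all(mcc[defined] >= -1 - 1e-12 & mcc[defined] <= 1 + 1e-12))
})

test_that("jackknife on far-separated blobs is perfect; permuted labels near chance", {
  feats <- simulate_feature_clusters(2, 15, dims = 3, between_sd = 0,
                                     within_sd = 0.5, seed = 2)
  x <- as.matrix(feats[, -(1:2)])
  # antipodal centres: cosine distance separates by direction, not magnitude
  x[feats$label == "class1", ] <- x[feats$label == "class1", ] - 40
  x[feats$label == "class2", ] <- x[feats$label == "class2", ] + 40
  rep1 <- evaluate_jackknife(x, feats$label, use_klda = FALSE)
  expect_equal(rep1$osr, 1)
  expect_equal(rep1$best_k, 1L)
  mcc <- tidy(rep1)$mcc
  expect_true(all(mcc[!is.na(mcc)] == 1))
  # OSR agrees with direct label accuracy (independent code path)
  expect_equal(rep1$osr, mean(rep1$predicted == rep1$truth))

  set.seed(1002)
  perm <- sample(feats$label)
  rep0 <- evaluate_jackknife(x, perm, use_klda = FALSE, k_max = 1)
  expect_lt(rep0$osr, 0.75)
})

test_that("a hand-built confusion outcome reproduces the formula metrics", {
  # 10-sample toy set: predictions fixed by construction with k = 1 and
  # duplicated training points
  x <- matrix(c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4), ncol = 1)
  truth <- c("a", "a", "a", "a", "b", "b", "b", "b", "b", "b")
  pred <- c("a", "a", "a", "b", "b", "b", "b", "b", "a", "b")
  stats <- data.frame(
    class = c("a", "b"),
    tp = c(sum(truth == "a" & pred == "a"), sum(truth == "b" & pred == "b")),
    tn = c(sum(truth != "a" & pred != "a"), sum(truth != "b" & pred != "b")),
    fp = c(sum(truth != "a" & pred == "a"), sum(truth != "b" & pred == "b")),
    fn = c(sum(truth == "a" & pred != "a"), sum(truth == "b" & pred != "b"))
  )
  m <- compute_metrics(stats)
  expect_equal(m$per_class$se, c(3 / 4, 5 / 6))
  expect_equal(m$per_class$sp, c(5 / 6, 3 / 4))
  expect_equal(m$per_class$acc, c(0.8, 0.8))
  expect_equal(m$osr, 0.8)
  expect_equal(m$per_class$tp + m$per_class$tn + m$per_class$fp +
                 m$per_class$fn, c(10, 10))
})

test_that("jackknife without KLDA is exactly invariant to positive feature scaling", {
  feats <- simulate_feature_clusters(3, 6, dims = 4, between_sd = 3,
                                     within_sd = 1.5, seed = 4)
  x <- as.matrix(feats[, -(1:2)])
  r1 <- evaluate_jackknife(x, feats$label, use_klda = FALSE)
  r2 <- evaluate_jackknife(37.5 * x, feats$label, use_klda = FALSE)
  expect_identical(r1$k_scan, r2$k_scan)
  expect_identical(r1$predicted, r2$predicted)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("independent test is perfect when test equals separable train", {
  feats <- simulate_feature_clusters(2, 10, dims = 2, between_sd = 0,
                                     within_sd = 0.5, seed = 3)
  x <- as.matrix(feats[, -(1:2)])
  x[feats$label == "class2", ] <- x[feats$label == "class2", ] + 30
  rep <- evaluate_independent(x, x, feats$label, feats$label, use_klda = FALSE)
  expect_equal(rep$osr, 1)

  expect_error(
    evaluate_independent(x, x[0, , drop = FALSE], feats$label, character(0)),
    "empty"
  )
  expect_error(
    evaluate_independent(x, matrix(1, 3, 5), feats$label, c("a", "b", "a")),
    "dimension mismatch"
  )
})

test_that("independent test generalizes across draws from the same profile", {
  feats_tr <- simulate_feature_clusters(2, 15, dims = 3, between_sd = 0,
                                        within_sd = 1, seed = 17)
  feats_te <- simulate_feature_clusters(2, 10, dims = 3, between_sd = 0,
                                        within_sd = 1, seed = 18)
  shift <- function(f) {
    x <- as.matrix(f[, -(1:2)])
    x[f$label == "class2", ] <- x[f$label == "class2", ] + 12
    x
  }
  rep <- evaluate_independent(shift(feats_tr), shift(feats_te),
                              feats_tr$label, feats_te$label)
  expect_gte(rep$osr, 0.9)
})

test_that("the K-scan reports the smallest K attaining the maximum OSR", {
  feats <- simulate_feature_clusters(2, 12, dims = 2, between_sd = 8,
                                     within_sd = 1, seed = 5)
  rep <- evaluate_jackknife(feats, use_klda = FALSE, k_max = 20)
  expect_equal(max(rep$k_scan$k), 20L)
  top <- rep$k_scan$k[rep$k_scan$osr == max(rep$k_scan$osr)]
  expect_equal(rep$best_k, min(top))
})

test_that("evaluation reports serialize with '-' sentinels", {
  feats <- simulate_feature_clusters(2, 6, dims = 2, between_sd = 6,
                                     within_sd = 0.5, seed = 8)
  rep <- evaluate_jackknife(feats, use_klda = FALSE)
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, f)
  parsed <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(parsed$protocol, "jackknife")
  expect_equal(length(parsed$per_class), 2L)
  rep$per_class$mcc[1] <- NA_real_
  write_eval_report(rep, f)
  parsed <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_identical(parsed$per_class[[1]]$mcc, "-")
})
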