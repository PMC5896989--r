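#' Cosine distance between two vectors
#'
#' `1 - x . y / (||x|| ||y||)`, in \[0, 2\]. If either vector has zero norm
#' the distance is defined as 1 (maximally uninformative) rather than an
#' error, so classification never aborts on degenerate features.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Distance in \[0, 2\].
#' @export
#' @examples
#' cosine_distance(c(1, 0), c(-1, 0)) # 2
cosine_distance <- function(x, y) {
  if (length(x) != length(y)) stop_user("`x` and `y` must have equal length")
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(1)
  d <- 1 - sum(x * y) / (nx * ny)
  min(max(d, 0), 2)
}

# rows of `queries` vs rows of `train`: M x N cosine distance matrix
cosine_distance_matrix <- function(queries, train) {
  qn <- sqrt(rowSums(queries^2))
  tn <- sqrt(rowSums(train^2))
  d <- 1 - tcrossprod(queries, train) / outer(qn, tn)
  d[!is.finite(d)] <- 1 # zero-norm rows
  d[d < 0] <- 0
  d[d > 2] <- 2
  d
}

#' Cosine-distance K-nearest-neighbour prediction
#'
#' Majority vote among the K cosine-nearest training samples. Distance ties
#' at the K-th rank are broken by training-set order (first wins); vote ties
#' are broken in favour of the class whose nearest member is closest.
#'
#' @param train Numeric N x D matrix or feature tibble of training samples.
#' @param labels Training class labels (default: `train$label`).
#' @param query Numeric D-vector (or M x D matrix of queries).
#' @param k Number of neighbours, `1 <= k <= N`.
#' @return Predicted class label (character vector of length M).
#' @export
knn_predict <- function(train, labels = NULL, query, k = 1L) {
  fm <- as_feature_matrix(train, labels)
  labels <- check_labels(fm$labels, nrow(fm$x))
  if (k < 1L || k > nrow(fm$x)) {
    stop_user(sprintf("`k` must lie in [1, %d], got %d", nrow(fm$x), k))
  }
  q <- if (is.matrix(query)) query else matrix(query, nrow = 1L)
  d <- cosine_distance_matrix(q, fm$x)
  vapply(seq_len(nrow(q)), function(i) {
    vote_knn(d[i, ], labels, k)
  }, character(1))
}

# stable order => ties at the k-th rank go to the earlier training sample
vote_knn <- function(dists, labels, k) {
  ord <- order(dists, seq_along(dists))
  nb <- ord[seq_len(k)]
  votes <- table(labels[nb])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  # vote tie: class whose nearest member (among neighbours) is closest
  first_rank <- vapply(top, function(cl) which(labels[nb] == cl)[1], integer(1))
  top[which.min(first_rank)]
}

#' Per-class one-vs-rest metrics from confusion counts
#'
#' For each class treated as positive against the rest:
#' `SE = TP / (TP + FN)`, `SP = TN / (TN + FP)`,
#' `ACC = (TP + TN) / (TP + FP + TN + FN)`, and Matthews correlation
#' `MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' plus the overall success rate `OSR = sum TP / sum (TP + FN)`. Any metric
#' with a zero denominator is undefined and reported as `NA` (rendered "-"
#' in serialized reports). The per-class SE is also each class's individual
#' success rate (share of its own proteins correctly located).
#'
#' @param stats Data frame with columns `class`, `tp`, `tn`, `fp`, `fn`.
#' @return List with `per_class` (tibble adding `se`, `sp`, `acc`, `mcc`)
#'   and `osr`.
#' @export
#' @examples
#' compute_metrics(data.frame(class = "a", tp = 8, tn = 9, fp = 1, fn = 2))$per_class
compute_metrics <- function(stats) {
  stats <- as_tibble(stats)
  stopifnot(all(c("class", "tp", "tn", "fp", "fn") %in% names(stats)))
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  per_class <- dplyr::mutate(
    stats,
    se = safe_div(.data$tp, .data$tp + .data$fn),
    sp = safe_div(.data$tn, .data$tn + .data$fp),
    acc = safe_div(.data$tp + .data$tn,
                   .data$tp + .data$fp + .data$tn + .data$fn),
    mcc = {
      den <- sqrt((.data$tp + .data$fp) * (.data$tp + .data$fn) *
                    (.data$tn + .data$fp) * (.data$tn + .data$fn))
      ifelse(den == 0, NA_real_,
             (.data$tp * .data$tn - .data$fp * .data$fn) / den)
    }
  )
  list(
    per_class = per_class,
    osr = safe_div(sum(stats$tp), sum(stats$tp + stats$fn))
  )
}

confusion_stats <- function(truth, predicted, class_names) {
  purrr::map_dfr(class_names, function(cl) {
    pos <- truth == cl
    hit <- predicted == cl
    tibble(
      class = cl,
      tp = sum(pos & hit), tn = sum(!pos & !hit),
      fp = sum(!pos & hit), fn = sum(pos & !hit)
    )
  })
}

# Shared scaffolding for both protocols: given per-query neighbour
# distances, scan K = 1..k_max and build the report at the best K.
build_report <- function(truth, pred_by_k, class_names, protocol, config,
                         flags = character(0)) {
  k_scan <- purrr::map_dfr(seq_len(ncol(pred_by_k)), function(k) {
    tibble(k = k, osr = mean(pred_by_k[, k] == truth))
  })
  best_k <- k_scan$k[which.max(k_scan$osr)] # smallest K on ties (stable order)
  predicted <- pred_by_k[, best_k]
  stats <- confusion_stats(truth, predicted, class_names)
  metrics <- compute_metrics(stats)
  structure(
    list(
      per_class = metrics$per_class,
      osr = metrics$osr,
      best_k = best_k,
      k_scan = k_scan,
      n = length(truth),
      truth = truth,
      predicted = predicted,
      protocol = protocol,
      flags = flags,
      config = config
    ),
    class = "loc_eval"
  )
}

#' Jackknife (leave-one-out) evaluation of the localization pipeline
#'
#' For each sample: remove it, optionally refit the KLDA projection on the
#' remaining N - 1 samples with the globally chosen bandwidth, project both
#' sides, and classify with cosine KNN. Predictions are accumulated for
#' every K in `1..k_max` (capped at N - 1) and the report is built at the
#' best-OSR K (smallest on ties), alongside the full K-scan curve.
#'
#' The bandwidth is selected once on the full dataset (either passed as
#' `sigma` or optimized by DGGA when `sigma = "dgga"`) and reused across
#' folds; `optimize_per_fold = TRUE` re-runs DGGA inside every fold
#' (leakage-free but far more expensive). Independently, `refit_per_fold`
#' (default `TRUE`) controls whether the KLDA projection itself is refit
#' with the held-out sample excluded from the Gram matrix — the
#' leakage-free reading of the jackknife — or projected once globally
#' (`FALSE`, faster, labelled in the report flags).
#'
#' @param data Feature tibble (with `label` column) or N x D matrix.
#' @param labels Class labels (default: `data$label`).
#' @param use_klda Apply KLDA dimension reduction before KNN.
#' @param sigma Bandwidth: a positive number, or `"dgga"` to select by
#'   [select_bandwidth()]. Ignored when `use_klda = FALSE`.
#' @param d Reduced dimension (default: number of classes).
#' @param k_max Largest neighbour count scanned (default 20).
#' @param refit_per_fold Refit the KLDA projection in every fold.
#' @param optimize_per_fold Re-run the bandwidth search in every fold.
#' @param ga [ga_config()] for the DGGA bandwidth search.
#' @param weighted Class-size-weighted between-class dispersion in the
#'   DGGA fitness.
#' @return An object of class `loc_eval`; see [compute_metrics()] for the
#'   per-class fields. `tidy()` returns the per-class table, `glance()` the
#'   one-row summary, `autoplot()` the OSR-vs-K curve.
#' @export
evaluate_jackknife <- function(data, labels = NULL, use_klda = FALSE,
                               sigma = "dgga", d = NULL, k_max = 20L,
                               refit_per_fold = TRUE,
                               optimize_per_fold = FALSE,
                               ga = ga_config(), weighted = FALSE) {
  fm <- as_feature_matrix(data, labels)
  x <- fm$x
  labels <- check_labels(fm$labels, nrow(x))
  class_names <- unique(labels)
  n <- nrow(x)
  if (n < length(class_names) + 1L) {
    stop_user("jackknife needs at least one more sample than classes")
  }
  k_max <- min(k_max, n - 1L)
  flags <- character(0)

  sigma_global <- NULL
  if (use_klda) {
    if (is.null(d)) d <- length(class_names)
    if (identical(sigma, "dgga")) {
      if (!optimize_per_fold) {
        sigma_global <- select_bandwidth(x, labels, d = d, config = ga,
                                         weighted = weighted)$best_sigma
        flags <- c(flags, "sigma optimized once on the full dataset (reused across folds)")
      }
    } else {
      check_sigma(sigma)
      sigma_global <- sigma
    }
    global_model <- NULL
    if (!refit_per_fold) {
      global_model <- suppressWarnings(klda_fit(x, labels, sigma = sigma_global, d = d))
      flags <- c(flags, "single global KLDA projection (fast mode; held-out sample in Gram matrix)")
    }
  }

  singletons <- names(which(table(labels) == 1L))
  if (length(singletons) > 0L) {
    flags <- c(flags, sprintf(
      "class(es) reduced to zero training members in their own fold: %s",
      paste(singletons, collapse = ", ")
    ))
  }

  pred_by_k <- matrix(NA_character_, n, k_max)
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    tr_lab <- labels[-i]
    q <- x[i, , drop = FALSE]
    if (use_klda) {
      sig_i <- sigma_global
      if (optimize_per_fold) {
        sig_i <- select_bandwidth(tr_x, tr_lab, d = d, config = ga,
                                  weighted = weighted)$best_sigma
      }
      if (refit_per_fold || optimize_per_fold) {
        model <- suppressWarnings(klda_fit(tr_x, tr_lab, sigma = sig_i, d = d))
      } else {
        model <- global_model
      }
      r_tr <- klda_transform(model, tr_x)
      r_q <- klda_transform(model, q)
    } else {
      r_tr <- tr_x
      r_q <- q
    }
    dists <- cosine_distance_matrix(r_q, r_tr)[1, ]
    ord <- order(dists, seq_along(dists))
    for (k in seq_len(k_max)) {
      pred_by_k[i, k] <- vote_knn(dists, tr_lab, k)
    }
  }
  config <- list(
    protocol = "jackknife", use_klda = use_klda, sigma = sigma_global,
    d = if (use_klda) d else NA_integer_, k_max = k_max,
    refit_per_fold = refit_per_fold, optimize_per_fold = optimize_per_fold
  )
  build_report(labels, pred_by_k, class_names, "jackknife", config, flags)
}

#' Independent-test evaluation of the localization pipeline
#'
#' Fits everything (bandwidth search and KLDA projection) on the training
#' set only, projects and classifies every test sample, and reports the
#' same per-class metrics, OSR and K-scan as [evaluate_jackknife()].
#'
#' @param train,test Feature tibbles or matrices with matching feature
#'   dimension.
#' @param train_labels,test_labels Class labels (default: `label` columns).
#' @inheritParams evaluate_jackknife
#' @return A `loc_eval` object.
#' @export
evaluate_independent <- function(train, test, train_labels = NULL,
                                 test_labels = NULL, use_klda = FALSE,
                                 sigma = "dgga", d = NULL, k_max = 20L,
                                 ga = ga_config(), weighted = FALSE) {
  fm_tr <- as_feature_matrix(train, train_labels)
  fm_te <- as_feature_matrix(test, test_labels)
  tr_lab <- check_labels(fm_tr$labels, nrow(fm_tr$x))
  te_lab <- check_labels(fm_te$labels, nrow(fm_te$x))
  if (nrow(fm_te$x) == 0L) stop_user("test set is empty")
  if (ncol(fm_tr$x) != ncol(fm_te$x)) {
    stop_user(sprintf("feature dimension mismatch: train %d vs test %d",
                      ncol(fm_tr$x), ncol(fm_te$x)))
  }
  class_names <- unique(c(tr_lab, te_lab))
  k_max <- min(k_max, nrow(fm_tr$x))
  sigma_used <- NULL
  if (use_klda) {
    if (is.null(d)) d <- length(unique(tr_lab))
    sigma_used <- if (identical(sigma, "dgga")) {
      select_bandwidth(fm_tr$x, tr_lab, d = d, config = ga,
                       weighted = weighted)$best_sigma
    } else {
      check_sigma(sigma)
    }
    model <- suppressWarnings(klda_fit(fm_tr$x, tr_lab, sigma = sigma_used, d = d))
    r_tr <- model$projections
    r_te <- klda_transform(model, fm_te$x)
  } else {
    r_tr <- fm_tr$x
    r_te <- fm_te$x
  }
  d_mat <- cosine_distance_matrix(r_te, r_tr)
  pred_by_k <- matrix(NA_character_, nrow(r_te), k_max)
  for (i in seq_len(nrow(r_te))) {
    for (k in seq_len(k_max)) {
      pred_by_k[i, k] <- vote_knn(d_mat[i, ], tr_lab, k)
    }
  }
  config <- list(
    protocol = "independent", use_klda = use_klda, sigma = sigma_used,
    d = if (use_klda) d else NA_integer_, k_max = k_max
  )
  build_report(te_lab, pred_by_k, class_names, "independent", config)
}

#' @export
print.loc_eval <- function(x, ...) {
  cat(sprintf(
    "<loc_eval> %s: N = %d, OSR = %.4f at K = %d (scan 1..%d)\n",
    x$protocol, x$n, x$osr, x$best_k, max(x$k_scan$k)
  ))
  print(x$per_class)
  for (f in x$flags) cat(" note:", f, "\n")
  invisible(x)
}

#' Per-class metric table of an evaluation report
#'
#' @param x A `loc_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per class: confusion counts and SE/SP/ACC/MCC.
#' @export
tidy.loc_eval <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#'
#' @param x A `loc_eval` object.
#' @param ... Unused.
#' @return Tibble with `protocol`, `n`, `n_classes`, `osr`, `best_k`.
#' @export
glance.loc_eval <- function(x, ...) {
  tibble(
    protocol = x$protocol,
    n = x$n,
    n_classes = nrow(x$per_class),
    osr = x$osr,
    best_k = x$best_k
  )
}

#' Plot the OSR against the KNN neighbour count
#'
#' @param object A `loc_eval` object.
#' @param ... Unused.
#' @return A ggplot of the K-scan curve with the chosen K marked.
#' @export
autoplot.loc_eval <- function(object, ...) {
  ggplot2::ggplot(object$k_scan, ggplot2::aes(.data$k, .data$osr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed") +
    ggplot2::labs(x = "K (neighbours)", y = "overall success rate",
                  title = sprintf("%s K-scan (best K = %d)",
                                  object$protocol, object$best_k))
}

#' Serialize an evaluation report to JSON
#'
#' Undefined metrics (`NA`, e.g. an MCC whose denominator is zero) are
#' rendered as the string `"-"`.
#'
#' @param report A `loc_eval` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "loc_eval"))
  dash <- function(v) ifelse(is.na(v), "-", format(v, digits = 10))
  per_class <- report$per_class
  out <- list(
    protocol = report$protocol,
    n = report$n,
    osr = report$osr,
    best_k = report$best_k,
    per_class = purrr::pmap(per_class, function(class, tp, tn, fp, fn, se, sp, acc, mcc) {
      list(class = class, tp = tp, tn = tn, fp = fp, fn = fn,
           se = dash(se), sp = dash(sp), acc = dash(acc), mcc = dash(mcc))
    }),
    k_scan = report$k_scan,
    flags = report$flags,
    config = report$config[!vapply(report$config, is.null, logical(1))]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
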