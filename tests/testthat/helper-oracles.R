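# Brute-force reference implementations used as independent oracles.
# Each recomputes its quantity with naive loops, staying independent of the
# package's vectorized code paths.

oracle_column_means <- function(scores) {
  out <- numeric(20)
  for (j in 1:20) {
    s <- 0
    for (i in seq_len(nrow(scores))) s <- s + scores[i, j]
    out[j] <- s / nrow(scores)
  }
  out
}

oracle_copssm <- function(scores) {
  m <- oracle_column_means(scores)
  out <- numeric(0)
  for (j in 1:20) {
    for (k in j:20) {
      out <- c(out, m[j] * m[k])
    }
  }
  out
}

oracle_pssm400 <- function(scores, sequence) {
  res <- strsplit(sequence, "")[[1]]
  aa <- aa_residues()
  out <- matrix(0, 20, 20)
  for (i in seq_along(res)) {
    a <- match(res[i], aa)
    if (is.na(a)) next
    for (j in 1:20) out[a, j] <- out[a, j] + scores[i, j]
  }
  as.vector(t(out))
}

oracle_cosine <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(1)
  1 - sum(x * y) / (nx * ny)
}

oracle_knn <- function(train, labels, query, k) {
  d <- apply(train, 1, oracle_cosine, y = query)
  ord <- order(d, seq_along(d)) # stable: first training sample wins ties
  nb <- ord[seq_len(k)]
  votes <- table(labels[nb])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    first <- sapply(top, function(cl) which(labels[nb] == cl)[1])
    top <- top[which.min(first)]
  }
  top
}

oracle_within <- function(r, labels) {
  total <- 0
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    mu <- colMeans(r[rows, , drop = FALSE])
    for (i in rows) total <- total + sum((r[i, ] - mu)^2)
  }
  total
}

oracle_between <- function(r, labels) {
  a <- colMeans(r)
  total <- 0
  for (cl in unique(labels)) {
    mu <- colMeans(r[labels == cl, , drop = FALSE])
    total <- total + sum((mu - a)^2)
  }
  total
}

oracle_grid_max <- function(fitness, x0, xn, n_points = 10000L) {
  grid <- seq(x0, xn, length.out = n_points)
  vals <- vapply(grid, fitness, numeric(1))
  list(argmax = grid[which.max(vals)], max = max(vals))
}

random_pssm <- function(L = 10L, seed = NULL, integer_scores = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  scores <- matrix(sample(-8:10, L * 20L, replace = TRUE), L, 20L)
  if (!integer_scores) scores <- scores + matrix(rnorm(L * 20L), L, 20L)
  seq <- paste(sample(aa_residues(), L, replace = TRUE), collapse = "")
  pssm(scores, seq, protein_id = paste0("rand", seed %||% 0L))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
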