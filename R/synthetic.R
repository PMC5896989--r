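#' Simulate a labelled protein dataset with class-structured PSSMs
#'
#' Emulates the class-conditional structure that PSSM-column-mean features
#' assume: each class has a characteristic mean profile over the 20 residue
#' columns, and every protein's PSSM rows are drawn as its class mean plus
#' independent Gaussian noise. Class mean vectors are placed on orthogonal
#' coordinate axes at mutual Euclidean distance exactly `separation`, so
#' `separation` directly controls class separability; `separation = 0`
#' yields a null dataset where labels carry no feature information.
#' Sequences are drawn independently from a per-class residue-composition
#' bias (no substitution-model consistency between sequence and scores is
#' attempted — see the methods vignette).
#'
#' @param n_classes Number of classes (2..20).
#' @param n_per_class Proteins per class (>= 2).
#' @param seq_length Sequence length L (>= 20).
#' @param separation Pairwise distance between class mean score vectors.
#' @param spread Within-class per-entry score SD (default 1).
#' @param seed Integer RNG seed (draws are bit-reproducible).
#' @param integer_scores Round scores to integers, producing
#'   PSI-BLAST-like profiles that round-trip exactly through
#'   [write_pssm_ascii()] / [read_pssm_ascii()].
#' @return An object of class `loc_sim`: list with `records` (tibble `id`,
#'   `sequence`, `label`), `pssms` (named list of [pssm] objects) and
#'   `labels`.
#' @export
#' @examples
#' sim <- simulate_dataset(2, 3, seq_length = 25, separation = 8, seed = 1)
#' sim$records
simulate_dataset <- function(n_classes, n_per_class, seq_length,
                             separation, spread = 1, seed = 1L,
                             integer_scores = FALSE) {
  if (n_classes < 2L || n_classes > 20L) {
    stop_user("`n_classes` must be between 2 and 20")
  }
  if (n_per_class < 2L) stop_user("`n_per_class` must be >= 2")
  if (seq_length < 20L) stop_user("`seq_length` must be >= 20")
  if (separation < 0 || spread <= 0) {
    stop_user("`separation` must be >= 0 and `spread` > 0")
  }
  set.seed(seed)
  class_names <- paste0("class", seq_len(n_classes))
  # orthogonal placement: distance between any two class means = separation
  means <- matrix(0, n_classes, 20L)
  for (c in seq_len(n_classes)) means[c, c] <- separation / sqrt(2)
  # residue composition bias per class (Dirichlet via gamma draws)
  comp <- t(vapply(seq_len(n_classes), function(c) {
    g <- stats::rgamma(20L, shape = 2)
    g / sum(g)
  }, numeric(20L)))

  ids <- character(0)
  labels <- character(0)
  seqs <- character(0)
  pssms <- list()
  for (c in seq_len(n_classes)) {
    for (r in seq_len(n_per_class)) {
      id <- sprintf("%s_p%02d", class_names[c], r)
      seq <- paste(sample(aa_residues(), seq_length, replace = TRUE,
                          prob = comp[c, ]), collapse = "")
      scores <- matrix(rnorm(seq_length * 20L, sd = spread),
                       seq_length, 20L) +
        matrix(means[c, ], seq_length, 20L, byrow = TRUE)
      if (integer_scores) scores <- round(scores)
      ids <- c(ids, id)
      labels <- c(labels, class_names[c])
      seqs <- c(seqs, seq)
      pssms[[id]] <- pssm(scores, seq, protein_id = id)
    }
  }
  structure(
    list(
      records = tibble(id = ids, sequence = seqs, label = labels),
      pssms = pssms,
      labels = labels
    ),
    class = "loc_sim"
  )
}

#' @export
print.loc_sim <- function(x, ...) {
  cat(sprintf("<loc_sim> %d proteins, %d classes, L = %d\n",
              nrow(x$records), length(unique(x$labels)),
              nchar(x$records$sequence[1])))
  invisible(x)
}

#' Simulate labelled spherical Gaussian feature clusters
#'
#' Class means are drawn i.i.d. `N(0, between_sd^2)` per coordinate and
#' points around them with SD `within_sd`. Used for discriminant / search /
#' KNN tests where PSSM structure is irrelevant. Zero SDs are allowed as
#' degenerate limits (e.g. `within_sd = 0` collapses every class onto its
#' mean, driving the dispersion ratio to its `+Inf` sentinel).
#'
#' @param n_classes,n_per_class Class structure (>= 2 each).
#' @param dims Feature dimension.
#' @param between_sd SD of the class-mean placement.
#' @param within_sd Within-class SD.
#' @param seed Integer RNG seed.
#' @return Feature tibble with columns `protein_id`, `label`,
#'   `F1..F<dims>`.
#' @export
simulate_feature_clusters <- function(n_classes, n_per_class, dims = 2L,
                                      between_sd = 5, within_sd = 1,
                                      seed = 1L) {
  if (n_classes < 2L || n_per_class < 2L || dims < 1L) {
    stop_user("`n_classes`, `n_per_class` must be >= 2 and `dims` >= 1")
  }
  if (between_sd < 0 || within_sd < 0) stop_user("SDs must be nonnegative")
  set.seed(seed)
  means <- matrix(rnorm(n_classes * dims, sd = between_sd), n_classes, dims)
  rows <- purrr::map_dfr(seq_len(n_classes), function(c) {
    pts <- matrix(rnorm(n_per_class * dims, sd = within_sd),
                  n_per_class, dims) +
      matrix(means[c, ], n_per_class, dims, byrow = TRUE)
    colnames(pts) <- paste0("F", seq_len(dims))
    dplyr::bind_cols(
      tibble(
        protein_id = sprintf("class%d_p%02d", c, seq_len(n_per_class)),
        label = paste0("class", c)
      ),
      as_tibble(pts)
    )
  })
  rows
}

#' Write a simulated dataset to disk as FASTA + PSSM fixtures + manifest
#'
#' Emits one ASCII PSSM per protein, a single multi-record FASTA, and a TSV
#' manifest referencing both, all consumable by the file-based pipeline
#' unchanged.
#'
#' @param sim A `loc_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest, invisibly.
#' @export
write_dataset_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "loc_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "sequences.fasta")
  write_fasta(sim$records, fasta)
  pssm_files <- vapply(names(sim$pssms), function(id) {
    f <- file.path(dir, paste0(id, ".pssm"))
    write_pssm_ascii(sim$pssms[[id]], f)
    paste0(id, ".pssm")
  }, character(1))
  manifest <- tibble(
    id = sim$records$id,
    label = sim$records$label,
    pssm_path = unname(pssm_files),
    fasta_path = "sequences.fasta"
  )
  path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}
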