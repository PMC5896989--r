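#' Column means of a PSSM
#'
#' Averages each of the 20 residue columns over all L positions of the
#' profile, giving the protein's mean evolutionary substitution propensity
#' towards each residue type. Raw (possibly negative) log-odds scores are
#' used unscaled; all rows contribute, including those at nonstandard
#' sequence positions.
#'
#' @param x A [pssm] object.
#' @return Named numeric vector of length 20 (canonical residue order).
#' @export
column_means <- function(x) {
  stopifnot(is_pssm(x))
  colMeans(x$scores)
}

#' CoPSSM: correlation PSSM feature vector (210-D)
#'
#' The CoPSSM representation of a protein is the vector of all pairwise
#' products of the 20 column means of its PSSM, taken over index pairs
#' j <= k (squares included), which gives 20 * 21 / 2 = 210 components.
#' Components are ordered lexicographically over (j, k):
#' (1,1), (1,2), ..., (1,20), (2,2), ..., (20,20). Because column means are
#' invariant to row order, so is CoPSSM.
#'
#' @param x A [pssm] object.
#' @return Named numeric vector `COPSSM_1` .. `COPSSM_210`.
#' @export
#' @examples
#' p <- pssm(matrix(1, 4, 20), "ACDE")
#' length(copssm(p))
copssm <- function(x) {
  m <- column_means(x)
  vals <- unlist(lapply(1:20, function(j) m[j] * m[j:20]), use.names = FALSE)
  setNames(vals, paste0("COPSSM_", seq_along(vals)))
}

# index of pair (j, k), j <= k, in the CoPSSM lexicographic flattening
copssm_index <- function(j, k) {
  stopifnot(j <= k)
  # rows 1..j-1 hold 21 - i entries each
  21L * (j - 1L) - j * (j - 1L) / 2L + k - j + 1L
}

#' 400-D PSSM row-sum baseline
#'
#' The classical fixed-length PSSM representation: rows of the L x 20
#' profile are grouped by the residue identity of their sequence position
#' and summed, giving a 20 x 20 matrix (observed residue x scored residue)
#' that is flattened row-major into a 400-vector. Rows at nonstandard
#' sequence positions (B/Z/X/U) are skipped; residues absent from the
#' sequence contribute a zero block. Sums are not divided by sequence
#' length.
#'
#' @param x A [pssm] object.
#' @return Named numeric vector `PSSM400_1` .. `PSSM400_400`, ordered with
#'   the observed residue (canonical order) outermost.
#' @export
pssm400 <- function(x) {
  stopifnot(is_pssm(x))
  res <- strsplit(x$sequence, "")[[1]]
  s <- matrix(0, 20L, 20L, dimnames = list(aa_residues(), aa_residues()))
  keep <- res %in% aa_residues()
  if (any(keep)) {
    grp <- rowsum(x$scores[keep, , drop = FALSE], group = res[keep])
    s[rownames(grp), ] <- grp
  }
  setNames(as.vector(t(s)), paste0("PSSM400_", 1:400))
}

#' Amphiphilic hydropathy scales for PseAAC
#'
#' Loads the hydrophobicity (H1) and hydrophilicity (H2) tables used by the
#' amphiphilic pseudo-amino-acid composition and standardizes each to mean 0
#' and unit mean-square deviation over the 20 residues (the conventional
#' normalization in the PseAAC literature, i.e. the population SD). The
#' default table ships with the package (Tanford-type hydrophobicity,
#' Hopp-Woods hydrophilicity) and can be replaced by any JSON file of the
#' same shape: `{"hydrophobicity": {"A": ..., ...}, "hydrophilicity": {...}}`
#' with raw (pre-standardization) values.
#'
#' @param path Path to a JSON scale table; default: the packaged table.
#' @param standardize Standardize the scales (default `TRUE`).
#' @return List with numeric 20-vectors `h1` and `h2`, named by residue in
#'   canonical order.
#' @export
pseaac_scales <- function(path = NULL, standardize = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "pseaac_scales.json", package = "pssmloc")
  }
  raw <- jsonlite::fromJSON(path)
  pick <- function(tab) {
    v <- unlist(tab)[aa_residues()]
    if (anyNA(v)) stop_user("scale table must cover all 20 standard residues")
    v
  }
  h1 <- pick(raw$hydrophobicity)
  h2 <- pick(raw$hydrophilicity)
  std <- function(v) {
    c0 <- v - mean(v)
    c0 / sqrt(mean(c0^2))
  }
  if (standardize) list(h1 = std(h1), h2 = std(h2)) else list(h1 = h1, h2 = h2)
}

#' Amphiphilic pseudo-amino-acid composition (PseAAC)
#'
#' Represents a sequence by its 20 residue count frequencies augmented with
#' 2 * beta amphipathic sequence-order correlation factors. For lag
#' m = 1..beta the odd factor is the mean product of standardized
#' hydrophobicity values at positions i and i + m, the even factor the same
#' with hydrophilicity:
#' tau\[2m-1\] = mean_i H1(R_i) H1(R_i+m), tau\[2m\] = mean_i H2(R_i) H2(R_i+m).
#' Components are p_u = f_u / (sum_v f_v + w * sum_t tau_t) for u <= 20 and
#' p_20+t = w * tau_t / (same denominator), giving a (20 + 2 beta)-vector
#' (40-D at the default beta = 10).
#'
#' Nonstandard residues are dropped with a warning before computation; the
#' (post-drop) sequence must be longer than `beta`.
#'
#' @param sequence Character scalar amino-acid sequence.
#' @param beta Number of correlation tiers (default 10).
#' @param w Weight of the sequence-order terms (default 0.05).
#' @param scales Hydropathy scales as returned by [pseaac_scales()].
#' @return Named numeric vector `PSEAAC_1` .. `PSEAAC_<20+2*beta>`.
#' @export
#' @examples
#' length(pseaac(strrep("ACDEFGHIKLMNPQRSTVWY", 3)))
pseaac <- function(sequence, beta = 10L, w = 0.05,
                   scales = pseaac_scales()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (beta < 1L) stop_user("`beta` must be a positive integer")
  if (w <= 0) stop_user("`w` must be positive")
  res <- strsplit(toupper(sequence), "")[[1]]
  drop <- !res %in% aa_residues()
  if (any(drop)) {
    warn(sprintf("dropping %d nonstandard residue(s) before PseAAC", sum(drop)))
    res <- res[!drop]
  }
  L <- length(res)
  if (L <= beta) {
    stop_user(sprintf("sequence too short for beta: L = %d <= beta = %d", L, beta))
  }
  f <- table(factor(res, levels = aa_residues()))
  f <- as.numeric(f)
  h1 <- scales$h1[res]
  h2 <- scales$h2[res]
  tau <- numeric(2L * beta)
  for (m in seq_len(beta)) {
    i <- seq_len(L - m)
    tau[2L * m - 1L] <- mean(h1[i] * h1[i + m])
    tau[2L * m] <- mean(h2[i] * h2[i + m])
  }
  denom <- sum(f) + w * sum(tau)
  if (!is.finite(denom) || denom <= 0) {
    stop_user("degenerate PseAAC denominator (sum f + w * sum tau <= 0)")
  }
  p <- c(f, w * tau) / denom
  setNames(p, paste0("PSEAAC_", seq_along(p)))
}

#' Compute a feature table for a whole dataset
#'
#' Applies one of the three representations to every protein listed in a
#' manifest and returns a tidy feature table (one row per protein, columns
#' `protein_id`, `label`, then the feature components). `COPSSM` and
#' `PSSM400` require `pssm_path` entries; `PSEAAC` requires `fasta_path`
#' entries (each FASTA must contain the protein's id).
#'
#' @param manifest A `loc_manifest` (see [read_manifest()]), or a list as
#'   returned by [simulate_dataset()] (which carries its PSSMs in memory).
#' @param representation One of `"COPSSM"`, `"PSSM400"`, `"PSEAAC"`.
#' @param ... Passed on to [pseaac()] (e.g. `beta`, `w`, `scales`).
#' @return Feature tibble suitable for [klda_fit()], [evaluate_jackknife()]
#'   and [write_feature_table()].
#' @export
compute_features <- function(manifest,
                             representation = c("COPSSM", "PSSM400", "PSEAAC"),
                             ...) {
  representation <- match.arg(representation)
  if (inherits(manifest, "loc_sim")) {
    return(compute_features_sim(manifest, representation, ...))
  }
  stopifnot(inherits(manifest, "loc_manifest"))
  entries <- manifest$entries
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    id <- entries$id[i]
    label <- entries$label[i]
    pssm_path <- entries$pssm_path[i]
    fasta_path <- entries$fasta_path[i]
    vec <- switch(representation,
      COPSSM = ,
      PSSM400 = {
        if (is.na(pssm_path)) {
          stop_user(sprintf("protein '%s': %s requires a pssm_path", id, representation))
        }
        p <- read_pssm_ascii(pssm_path, protein_id = id)
        if (representation == "COPSSM") copssm(p) else pssm400(p)
      },
      PSEAAC = {
        if (is.na(fasta_path)) {
          stop_user(sprintf("protein '%s': PSEAAC requires a fasta_path", id))
        }
        recs <- read_fasta(fasta_path)
        hit <- match(id, recs$id)
        if (is.na(hit)) {
          stop_user(sprintf("protein '%s' not found in %s", id, fasta_path))
        }
        pseaac(recs$sequence[hit], ...)
      }
    )
    c(list(protein_id = id, label = label), as.list(vec))
  })
  dplyr::bind_rows(rows)
}

compute_features_sim <- function(sim, representation, ...) {
  rows <- purrr::map2(sim$pssms, seq_along(sim$pssms), function(p, i) {
    vec <- switch(representation,
      COPSSM = copssm(p),
      PSSM400 = pssm400(p),
      PSEAAC = pseaac(sim$records$sequence[i], ...)
    )
    c(list(protein_id = sim$records$id[i], label = sim$records$label[i]),
      as.list(vec))
  })
  dplyr::bind_rows(rows)
}
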