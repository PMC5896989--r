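#' Construct a position-specific scoring matrix object
#'
#' A `pssm` bundles an L x 20 matrix of position-specific substitution scores
#' (log-odds integers when parsed from PSI-BLAST output, reals when
#' simulated) with the query sequence whose positions the rows describe.
#' Columns are always stored in the canonical alphabetical residue order
#' ([aa_residues()]); if `residue_order` names a different permutation the
#' columns are reordered on construction.
#'
#' @param scores Numeric L x 20 matrix of per-position substitution scores.
#' @param sequence Character scalar of length L: the query residues, one per
#'   row. Nonstandard letters (B/Z/X/U) are tolerated.
#' @param protein_id Identifier of the protein.
#' @param residue_order Character vector of 20 one-letter codes giving the
#'   meaning of the columns of `scores` as supplied. Default: canonical.
#'
#' @return An object of class `pssm`: a list with elements `protein_id`,
#'   `scores` (canonically ordered, with column names), `sequence`, and
#'   `nonstandard` (integer row indices whose residue letter is not one of
#'   the 20 standard codes).
#' @export
#' @examples
#' p <- pssm(matrix(1, 3, 20), "ACD", "toy")
#' dim(p$scores)
pssm <- function(scores, sequence, protein_id = "protein",
                 residue_order = aa_residues()) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) != 20L) {
    stop_user(sprintf("PSSM must have exactly 20 score columns, got %d", ncol(scores)))
  }
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop_user("`sequence` must be a single string")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) != nrow(scores)) {
    stop_user(sprintf(
      "sequence length (%d) does not match PSSM row count (%d)",
      nchar(sequence), nrow(scores)
    ))
  }
  if (nrow(scores) < 1L) stop_user("PSSM must have at least one row (L >= 1)")
  if (!all(is.finite(scores))) stop_user("PSSM scores must be finite")
  residue_order <- toupper(residue_order)
  if (length(residue_order) != 20L || !setequal(residue_order, aa_residues())) {
    stop_user("`residue_order` must be a permutation of the 20 standard residue codes")
  }
  colnames(scores) <- residue_order
  scores <- scores[, aa_residues(), drop = FALSE]
  res <- strsplit(sequence, "")[[1]]
  nonstandard <- which(!res %in% aa_residues())
  if (length(nonstandard) > 0L && any(!res %in% aa_extended())) {
    bad <- unique(res[!res %in% aa_extended()])
    warn(sprintf(
      "PSSM '%s': residue letter(s) outside the amino-acid alphabet kept verbatim: %s",
      protein_id, paste(bad, collapse = ", ")
    ))
  }
  structure(
    list(
      protein_id = as.character(protein_id),
      scores = scores,
      sequence = sequence,
      nonstandard = nonstandard
    ),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf(
    "<pssm> %s: %d positions x 20 residues (%d nonstandard rows)\n",
    x$protein_id, nrow(x$scores), length(x$nonstandard)
  ))
  invisible(x)
}

is_pssm <- function(x) inherits(x, "pssm")
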