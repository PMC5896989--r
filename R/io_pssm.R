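#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: two header lines, a column-label
#' line with 40 residue letters, then one row per sequence position holding
#' the position index, the query residue, 20 integer log-odds scores and 20
#' weighted-percentage columns (ignored), followed by trailing statistics
#' lines. Only the first 20 score columns are kept, reordered into the
#' canonical alphabetical residue order so feature indices are stable across
#' tools; the query sequence is reconstructed from the per-row residue
#' letters. Rows whose residue letter is nonstandard are recorded in the
#' returned object's `nonstandard` field.
#'
#' @param path Path to an ASCII PSSM file.
#' @param protein_id Identifier to attach; defaults to the file name without
#'   extension.
#' @return A [pssm] object.
#' @export
read_pssm_ascii <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop_user(sprintf("PSSM file not found: %s", path))
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])

  # column-label line: >= 20 single-letter tokens, no numbers
  is_label <- vapply(toks, function(tk) {
    length(tk) >= 20L && all(nchar(tk) == 1L) && !any(grepl("[0-9]", tk))
  }, logical(1))
  label_ln <- which(is_label)[1]
  if (is.na(label_ln)) {
    stop_user(sprintf("%s: no PSSM column-label line found", path))
  }
  residue_order <- toupper(toks[[label_ln]][1:20])
  if (!setequal(residue_order, aa_residues())) {
    stop_user(sprintf(
      "%s:%d: column labels are not a permutation of the 20 standard residues",
      path, label_ln
    ))
  }

  rows <- list()
  residues <- character(0)
  flagged <- character(0)
  for (ln in seq(label_ln + 1L, length.out = max(0L, length(lines) - label_ln))) {
    tk <- toks[[ln]]
    if (length(tk) == 0L) {
      if (length(rows) > 0L) break else next
    }
    if (!grepl("^[0-9]+$", tk[1])) {
      if (length(rows) > 0L) break # trailing K/Lambda statistics
      stop_user(sprintf("%s:%d: expected a position index at row start", path, ln))
    }
    if (length(tk) < 22L) {
      stop_user(sprintf(
        "%s: PSSM row %d (line %d) is truncated: expected >= 20 scores, found %d",
        path, length(rows) + 1L, ln, max(0L, length(tk) - 2L)
      ))
    }
    scores <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(scores)) {
      stop_user(sprintf(
        "%s: PSSM row %d (line %d) has non-numeric scores", path, length(rows) + 1L, ln
      ))
    }
    res <- toupper(tk[2])
    if (!res %in% aa_residues()) flagged <- c(flagged, res)
    residues <- c(residues, res)
    rows[[length(rows) + 1L]] <- scores
  }
  if (length(rows) == 0L) stop_user(sprintf("%s: no PSSM data rows found", path))
  if (length(flagged) > 0L) {
    warn(sprintf(
      "%s: %d row(s) with nonstandard residue letter(s) %s kept verbatim and flagged",
      path, length(flagged), paste(unique(flagged), collapse = ", ")
    ))
  }
  scores <- do.call(rbind, rows)
  pssm(scores, paste(residues, collapse = ""), protein_id,
       residue_order = residue_order)
}

#' Write a PSSM in PSI-BLAST ASCII format
#'
#' Emits the `-out_ascii_pssm` dialect parsed by [read_pssm_ascii()]: scores
#' are written as rounded integers (the dialect is integer-valued), followed
#' by 20 zero weighted-percentage columns and trailing statistics lines.
#' Integer-valued scores therefore round-trip exactly.
#'
#' @param x A [pssm] object.
#' @param path Output path.
#' @param residue_order Column order to emit; defaults to PSI-BLAST's native
#'   `A,R,N,D,...` order so fixtures resemble real tool output.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(x, path, residue_order = psiblast_residue_order()) {
  stopifnot(is_pssm(x))
  residue_order <- toupper(residue_order)
  if (!setequal(residue_order, aa_residues())) {
    stop_user("`residue_order` must be a permutation of the 20 standard residues")
  }
  sc <- round(x$scores[, residue_order, drop = FALSE])
  res <- strsplit(x$sequence, "")[[1]]
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", residue_order), collapse = ""),
           "   ", paste(sprintf("%3s", residue_order), collapse = ""))
  )
  body <- vapply(seq_len(nrow(sc)), function(i) {
    paste0(
      sprintf("%5d %s ", i, res[i]),
      paste(sprintf("%3d", as.integer(sc[i, ])), collapse = ""),
      "  ",
      paste(sprintf("%4d", integer(20L)), collapse = ""),
      sprintf("  %5.2f %9.2f", 0, 0)
    )
  }, character(1))
  footer <- c(
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1347     0.3179",
    "Standard Gapped      0.0410     0.2670"
  )
  writeLines(c(header, body, footer), path)
  invisible(path)
}
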