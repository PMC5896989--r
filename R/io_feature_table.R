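#' Write a feature table to delimited text
#'
#' Feature tables are tibbles with a `protein_id` column, an optional
#' `label` column, and numeric feature columns named
#' `<REPRESENTATION>_<index>` (e.g. `COPSSM_1` .. `COPSSM_210`), as produced
#' by [compute_features()]. Values are written with enough digits to
#' round-trip losslessly to at least 12 significant digits.
#'
#' @param features Feature tibble.
#' @param path Output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  features <- as_tibble(features)
  if (!"protein_id" %in% names(features)) {
    stop_user("feature table must have a `protein_id` column")
  }
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  bad <- vapply(features[num_cols], function(v) any(!is.finite(v)), logical(1))
  if (any(bad)) {
    stop_user(sprintf("feature table has non-finite values in column(s): %s",
                      paste(num_cols[bad], collapse = ", ")))
  }
  out <- features
  for (col in num_cols) out[[col]] <- sprintf("%.15g", out[[col]])
  writer <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv
  } else {
    readr::write_tsv
  }
  writer(out, path, progress = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the delimited table.
#' @return Feature tibble with `protein_id` (and `label` if present) as
#'   character columns and all feature columns numeric.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_user(sprintf("feature table not found: %s", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  tab <- reader(path, show_col_types = FALSE, progress = FALSE)
  tab <- as_tibble(tab)
  if (!"protein_id" %in% names(tab)) {
    stop_user(sprintf("%s: not a feature table (no `protein_id` column)", path))
  }
  tab$protein_id <- as.character(tab$protein_id)
  if ("label" %in% names(tab)) tab$label <- as.character(tab$label)
  for (col in setdiff(names(tab), c("protein_id", "label"))) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}

# Split a feature tibble (or plain matrix) into x / ids / labels.
as_feature_matrix <- function(data, labels = NULL) {
  if (is.matrix(data)) {
    x <- data
    ids <- rownames(data) %||% as.character(seq_len(nrow(data)))
    if (is.null(labels)) labels <- attr(data, "labels")
  } else {
    data <- as_tibble(data)
    ids <- if ("protein_id" %in% names(data)) as.character(data$protein_id) else as.character(seq_len(nrow(data)))
    if (is.null(labels) && "label" %in% names(data)) labels <- data$label
    num <- vapply(data, is.numeric, logical(1))
    num[names(data) %in% c("protein_id", "label")] <- FALSE
    x <- as.matrix(data[, num, drop = FALSE])
  }
  if (!is.null(labels)) labels <- as.character(labels)
  if (any(!is.finite(x))) stop_user("feature matrix contains non-finite values")
  list(x = x, ids = ids, labels = labels)
}
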