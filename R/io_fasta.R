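#' Read a multi-record FASTA file of protein sequences
#'
#' Sequences are uppercased and internal whitespace stripped. Parsing is done
#' with [Biostrings::readAAStringSet()]; a lightweight validation pass first
#' checks the file structure so that malformed headers and empty records are
#' reported with their line number.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "acd", "efg", ">p2", "WY"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop_user(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  validate_fasta_lines(lines, path)
  # internal whitespace is stripped per contract; silence Biostrings' notice
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  tibble(
    id = ids,
    sequence = unname(gsub("\\s+", "", toupper(as.character(set))))
  )
}

validate_fasta_lines <- function(lines, path) {
  nonblank <- which(!grepl("^\\s*$", lines))
  if (length(nonblank) == 0L) stop_user(sprintf("%s: empty FASTA file", path))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop_user(sprintf(
      "%s:%d: expected a FASTA header ('>') before sequence data",
      path, nonblank[1]
    ))
  }
  headers <- which(startsWith(trimws(lines), ">"))
  for (h in seq_along(headers)) {
    ln <- headers[h]
    id <- sub("^>", "", trimws(lines[ln]))
    if (!nzchar(strsplit(id, "\\s+")[[1]][1] %||% "")) {
      stop_user(sprintf("%s:%d: malformed FASTA header (empty id)", path, ln))
    }
    to <- if (h < length(headers)) headers[h + 1] - 1L else length(lines)
    body <- lines[setdiff(seq(ln + 1L, length.out = max(0L, to - ln)), integer(0))]
    if (sum(nchar(gsub("\\s+", "", body))) == 0L) {
      stop_user(sprintf("%s:%d: record '%s' has an empty sequence", path, ln, id))
    }
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) {
  if (is.null(x) || length(x) == 0L || (length(x) == 1L && is.na(x))) y else x
}

#' Write protein records to a FASTA file
#'
#' @param records Data frame with columns `id` and `sequence` (as returned by
#'   [read_fasta()] or [simulate_dataset()]).
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  out <- unlist(purrr::map2(records$id, records$sequence, function(id, seq) {
    c(paste0(">", id),
      substring(seq, seq(1L, nchar(seq), by = width),
                pmin(seq(width, nchar(seq) + width - 1L, by = width), nchar(seq))))
  }))
  writeLines(out, path)
  invisible(path)
}
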