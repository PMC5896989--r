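#' Read a dataset manifest
#'
#' A manifest is a TSV or CSV table mapping protein ids to class labels and
#' (optionally) to the PSSM / FASTA files holding their data. Required
#' columns: `id`, `label`; optional: `pssm_path`, `fasta_path`. Relative
#' paths are resolved against the manifest's directory. Every non-missing
#' path must exist at load time; path columns may be absent or `NA` for
#' label-only manifests (e.g. class-count bookkeeping).
#'
#' @param path Path to a `.tsv` or `.csv` manifest.
#' @return An object of class `loc_manifest`: a list with `entries` (tibble
#'   with columns `id`, `label`, `pssm_path`, `fasta_path`), `class_names`
#'   (labels in first-appearance order) and `class_counts` (named integer
#'   vector).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_user(sprintf("manifest not found: %s", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  entries <- reader(path, show_col_types = FALSE, progress = FALSE)
  new_manifest(entries, base_dir = dirname(path))
}

new_manifest <- function(entries, base_dir = ".") {
  entries <- as_tibble(entries)
  missing_cols <- setdiff(c("id", "label"), names(entries))
  if (length(missing_cols) > 0L) {
    stop_user(sprintf("manifest lacks required column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  for (col in c("pssm_path", "fasta_path")) {
    if (!col %in% names(entries)) entries[[col]] <- NA_character_
    entries[[col]] <- as.character(entries[[col]])
    resolve <- !is.na(entries[[col]]) & !grepl("^(/|[A-Za-z]:)", entries[[col]])
    entries[[col]][resolve] <- file.path(base_dir, entries[[col]][resolve])
    missing <- !is.na(entries[[col]]) & !file.exists(entries[[col]])
    if (any(missing)) {
      stop_user(sprintf(
        "manifest references missing file(s): %s",
        paste(head(entries[[col]][missing], 3L), collapse = ", ")
      ))
    }
  }
  entries$id <- as.character(entries$id)
  entries$label <- as.character(entries$label)
  if (anyNA(entries$id) || anyNA(entries$label)) {
    stop_user("manifest ids and labels must be non-missing")
  }
  if (anyDuplicated(entries$id)) {
    stop_user(sprintf("manifest has duplicated protein id(s): %s",
                      paste(head(unique(entries$id[duplicated(entries$id)]), 3L),
                            collapse = ", ")))
  }
  class_names <- unique(entries$label)
  if (length(class_names) < 2L) {
    stop_user("manifest must contain at least 2 classes (k >= 2)")
  }
  counts <- table(factor(entries$label, levels = class_names))
  structure(
    list(
      entries = entries[, c("id", "label", "pssm_path", "fasta_path")],
      class_names = class_names,
      class_counts = setNames(as.integer(counts), class_names)
    ),
    class = "loc_manifest"
  )
}

#' @export
print.loc_manifest <- function(x, ...) {
  cat(sprintf("<loc_manifest> %d proteins, %d classes\n",
              nrow(x$entries), length(x$class_names)))
  print(x$class_counts)
  invisible(x)
}

#' Write a dataset manifest
#'
#' @param manifest A `loc_manifest`, or a data frame with at least `id` and
#'   `label` columns.
#' @param path Output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  entries <- if (inherits(manifest, "loc_manifest")) manifest$entries else as_tibble(manifest)
  writer <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv
  } else {
    readr::write_tsv
  }
  writer(entries, path, progress = FALSE)
  invisible(path)
}

#' Constitutions of the four public benchmark datasets
#'
#' Per-class protein counts of the standard benchmark collections used in
#' protein compartment prediction: two subnuclear datasets (the SubNucPred
#' set of 10 subnuclear locations, 669 proteins, and the Nuc-PLoc set of 9
#' subnuclear locations, 714 proteins) and the two Gram-negative subcellular
#' sets of 8 locations (653 training, 643 independent-test proteins). The
#' sequence data themselves are distributed by the original web servers;
#' this table records only the published class structure, which is useful
#' for building manifests and sanity-checking downloaded copies.
#'
#' @return Tibble with columns `dataset` (1-4), `class_index`, `location`,
#'   and `n_proteins`.
#' @export
#' @examples
#' dplyr::count(benchmark_constitutions(), dataset, wt = n_proteins)
benchmark_constitutions <- function() {
  d1 <- c(Centromere = 86, Chromosome = 113, `Nuclear envelope` = 17,
          `Nuclear matrix` = 18, `Nuclear pore complex` = 12,
          `Nuclear speckle` = 50, Nucleolus = 294, Nucleoplasm = 30,
          Telomere = 37, `Nuclear PML body` = 12)
  d2 <- c(Chromatin = 99, Heterochromatin = 22, `Nuclear envelope` = 61,
          `Nuclear matrix` = 29, `Nuclear pore complex` = 79,
          `Nuclear speckle` = 67, Nucleolus = 307, Nucleoplasm = 37,
          `Nuclear PML body` = 13)
  d3 <- c(Cytoplasm = 152, Extracell = 76, Fimbrium = 12, Flagellum = 6,
          `Inner membrane` = 186, Nucleoid = 6, `Outer membrane` = 103,
          Periplasm = 112)
  d4 <- c(Cytoplasm = 210, Extracell = 20, Fimbrium = 4, Flagellum = 1,
          `Inner membrane` = 345, Nucleoid = 1, `Outer membrane` = 13,
          Periplasm = 49)
  purrr::imap_dfr(list(d1, d2, d3, d4), function(cc, i) {
    tibble(
      dataset = as.integer(i),
      class_index = seq_along(cc),
      location = names(cc),
      n_proteins = as.integer(cc)
    )
  })
}

#' Expand a dataset constitution into a label-only manifest
#'
#' Builds a `loc_manifest` with one synthetic protein id per listed protein,
#' reproducing the class structure of one of the benchmark datasets (or of
#' any `location`/`n_proteins` table). No files are referenced.
#'
#' @param constitution Data frame with columns `location` and `n_proteins`,
#'   e.g. one dataset of [benchmark_constitutions()].
#' @param id_prefix Prefix for the generated protein ids.
#' @return A `loc_manifest`.
#' @export
#' @examples
#' con <- dplyr::filter(benchmark_constitutions(), dataset == 1)
#' m <- manifest_from_constitution(con)
#' sum(m$class_counts)
manifest_from_constitution <- function(constitution, id_prefix = "P") {
  stopifnot(all(c("location", "n_proteins") %in% names(constitution)))
  entries <- tidyr::uncount(
    tibble(label = constitution$location, n = constitution$n_proteins),
    weights = .data$n
  )
  entries$id <- sprintf("%s%05d", id_prefix, seq_len(nrow(entries)))
  new_manifest(entries[, c("id", "label")])
}
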