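# Sample tables: one row per unique peptide sequence in one sample.

#' Construct a sample table
#'
#' A sample table holds the peptidome of a single sample: one row per unique
#' peptide sequence with its spectral count (number of fragmentation spectra
#' matched to the peptide, a semi-quantitative abundance proxy) and the
#' protein accession(s) the search engine assigned, if any. Rows sharing a
#' sequence are merged by summing their spectral counts and unioning their
#' accessions.
#'
#' @param sequence Character vector of peptide sequences (uppercase,
#'   20-letter alphabet).
#' @param spectral_count Non-negative integer vector, same length.
#' @param accessions Optional character vector of semicolon-separated
#'   accession strings (`NA` or `""` when unassigned).
#' @param sample_id Sample identifier (scalar character).
#' @param group_label Optional group label (e.g. `"acute"`, `"infected"`).
#' @return A tibble of class `sample_table` with columns `sequence`,
#'   `spectral_count`, `accessions`, and attributes `sample_id` and
#'   `group_label`.
#' @examples
#' sample_table(c("NALAHKYH", "NALAHKYH"), c(2, 3), sample_id = "s1")
#' @export
sample_table <- function(sequence, spectral_count, accessions = NULL,
                         sample_id, group_label = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  sequence <- toupper(as.character(sequence))
  if (length(sequence) > 0) check_sequences(sequence)
  spectral_count <- as.numeric(spectral_count)
  if (anyNA(spectral_count) || any(spectral_count < 0)) {
    stop("spectral_count must be non-negative and non-missing", call. = FALSE)
  }
  if (is.null(accessions)) accessions <- rep(NA_character_, length(sequence))
  accessions[!is.na(accessions) & accessions == ""] <- NA_character_
  tbl <- tibble::tibble(
    sequence = sequence,
    spectral_count = spectral_count,
    accessions = as.character(accessions)
  )
  if (anyDuplicated(tbl$sequence)) {
    tbl <- tbl |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(
        spectral_count = sum(.data$spectral_count),
        accessions = merge_accessions(.data$accessions),
        .groups = "drop"
      )
  }
  new_sample_table(tbl, sample_id, group_label)
}

new_sample_table <- function(tbl, sample_id, group_label = NA_character_) {
  structure(tbl,
    sample_id = sample_id, group_label = group_label,
    class = c("sample_table", class(tibble::as_tibble(tbl)))
  )
}

merge_accessions <- function(x) {
  acc <- unique(unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE)))
  acc <- acc[acc != ""]
  if (length(acc) == 0) NA_character_ else paste(acc, collapse = ";")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(
    "<sample_table> sample ", sample_id(x),
    if (!is.na(group_label(x))) paste0(" (group ", group_label(x), ")"),
    ": ", nrow(x), " peptides, total spectral count ",
    total_spectral_count(x), "\n",
    sep = ""
  )
  NextMethod()
}

#' Sample and group accessors
#'
#' @param x A `sample_table`.
#' @return `sample_id()` and `group_label()` return scalar character.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' @rdname sample_id
#' @export
group_label <- function(x) attr(x, "group_label")

#' Read a delimited peptide identification table
#'
#' Reads one sample's peptide table from tab- or comma-separated text (the
#' delimiter is auto-detected from the header line). Source column names are
#' mapped onto the canonical `sequence`, `spectral_count` and (optionally)
#' `accessions` columns through `dialect`. Modified-residue annotations in
#' parentheses or square brackets (e.g. `"N(+.98)ALAHKYH"`) and flanking-
#' residue dots (`"K.NALAHKYH.A"`) are stripped from sequences; every
#' stripped sequence is recorded in the `stripped` attribute of the result.
#' Rows sharing a (stripped) sequence are merged by summing spectral counts.
#'
#' @param path Path to the delimited file (UTF-8; first line is the header).
#' @param sample_id Sample identifier to stamp on the table.
#' @param dialect Named list mapping canonical names to source column names;
#'   see [dialect_plain()] and [dialect_peaks()].
#' @param group_label Optional group label.
#' @return A [sample_table()] with attribute `stripped`, a tibble of
#'   raw/clean sequence pairs that were modified on ingest.
#' @export
read_peptide_table <- function(path, sample_id,
                               dialect = dialect_plain(),
                               group_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = "character", comment.char = ""
  )
  for (col in c("sequence", "spectral_count")) {
    src <- dialect[[col]]
    if (is.null(src) || !src %in% names(raw)) {
      stop("peptide table ", path, " lacks required column '",
        if (is.null(src)) col else src, "'",
        call. = FALSE
      )
    }
  }
  seq_raw <- raw[[dialect$sequence]]
  counts <- suppressWarnings(as.numeric(raw[[dialect$spectral_count]]))
  bad <- which(is.na(counts) & !is.na(seq_raw))
  if (length(bad) > 0) {
    stop("non-numeric spectral count in row ", bad[1], " of ", path,
      call. = FALSE
    )
  }
  acc <- NULL
  if (!is.null(dialect$accessions) && dialect$accessions %in% names(raw)) {
    acc <- raw[[dialect$accessions]]
  }
  cleaned <- strip_modifications(seq_raw)
  tbl <- sample_table(cleaned$clean, counts, acc,
    sample_id = sample_id, group_label = group_label
  )
  attr(tbl, "stripped") <- cleaned$log
  tbl
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) {
    return("\t")
  }
  if (stringi::stri_count_fixed(header, "\t") >=
    stringi::stri_count_fixed(header, ",")) "\t" else ","
}

# Drop bracketed PTM annotations and PEAKS-style flanking-residue dots.
strip_modifications <- function(sequences) {
  clean <- stringi::stri_replace_all_regex(sequences, "\\([^)]*\\)|\\[[^\\]]*\\]", "")
  clean <- stringi::stri_replace_all_regex(clean, "^[A-Z-]\\.|\\.[A-Z-]$", "")
  clean <- toupper(clean)
  changed <- clean != toupper(sequences)
  list(
    clean = clean,
    log = tibble::tibble(raw = sequences[changed], clean = clean[changed])
  )
}

#' Column dialects for peptide tables
#'
#' `dialect_plain()` expects canonical column names; `dialect_peaks()`
#' matches PEAKS-style exports (`Peptide`, `#Spec`, `Accession`).
#'
#' @return Named list with entries `sequence`, `spectral_count`, `accessions`.
#' @export
dialect_plain <- function() {
  list(sequence = "sequence", spectral_count = "spectral_count", accessions = "accessions")
}

#' @rdname dialect_plain
#' @export
dialect_peaks <- function() {
  list(sequence = "Peptide", spectral_count = "#Spec", accessions = "Accession")
}

#' Write a sample table to tab-separated text
#'
#' @param table A `sample_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(table, path) {
  utils::write.table(
    as.data.frame(table)[, c("sequence", "spectral_count", "accessions")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' Concatenate replicate injections of one sample
#'
#' Repeat LC-MS/MS injections of the same sample are merged into a single
#' table: per-sequence spectral counts are summed across replicates and
#' accession assignments are unioned.
#'
#' @param tables List of `sample_table`s sharing one `sample_id`.
#' @return A single merged [sample_table()].
#' @export
concatenate_replicates <- function(tables) {
  stopifnot(length(tables) >= 1)
  ids <- unique(vapply(tables, sample_id, character(1)))
  if (length(ids) != 1L) {
    stop("replicates carry mixed sample_ids: ", paste(ids, collapse = ", "),
      call. = FALSE
    )
  }
  groups <- unique(vapply(tables, group_label, character(1)))
  pooled <- dplyr::bind_rows(lapply(tables, tibble::as_tibble))
  sample_table(pooled$sequence, pooled$spectral_count, pooled$accessions,
    sample_id = ids, group_label = groups[1]
  )
}

#' Filter a sample table on spectral count
#'
#' Retains peptides whose spectral count is at least `min_count`. Filtering
#' on spectral counts removes one-hit identifications that are dominated by
#' false positives; the conventional threshold used throughout this package
#' is 4.
#'
#' @param table A `sample_table`.
#' @param min_count Minimum spectral count retained (default 4).
#' @return The filtered `sample_table` (input is not modified).
#' @examples
#' t <- sample_table(c("AAAA", "CCCC"), c(5, 3), sample_id = "s1")
#' apply_spectral_cutoff(t) # keeps AAAA only
#' @export
apply_spectral_cutoff <- function(table, min_count = 4) {
  if (length(min_count) != 1L || is.na(min_count) || min_count < 0) {
    stop("min_count must be a single non-negative number", call. = FALSE)
  }
  keep <- table$spectral_count >= min_count
  new_sample_table(
    tibble::as_tibble(table)[keep, , drop = FALSE],
    sample_id(table), group_label(table)
  )
}

#' Total spectral count of a sample table
#'
#' @param table A `sample_table`.
#' @return Sum of spectral counts (0 for an empty table).
#' @export
total_spectral_count <- function(table) {
  if (nrow(table) == 0) {
    return(0)
  }
  sum(table$spectral_count)
}
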