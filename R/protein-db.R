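# Protein sequence databases used for peptide localization.

#' Construct a protein database
#'
#' A protein database maps accessions to amino-acid sequences (1-based
#' inclusive coordinates throughout the package). Sequences containing the
#' ambiguity/nonstandard codes X, B, Z or U are tolerated but flagged.
#'
#' @param sequences Named character vector accession -> sequence.
#' @param descriptions Optional named character vector accession -> header
#'   description.
#' @return An object of class `protein_db` with elements `seq`, `desc` and
#'   `nonstandard` (logical flags per accession).
#' @export
protein_db <- function(sequences, descriptions = NULL) {
  if (length(sequences) == 0) stop("empty protein database", call. = FALSE)
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("sequences must be named by accession", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate accession: ", names(sequences)[duplicated(names(sequences))][1],
      call. = FALSE
    )
  }
  sequences <- toupper(sequences)
  if (any(is.na(sequences) | sequences == "")) {
    stop("empty sequence for accession ",
      names(sequences)[which(is.na(sequences) | sequences == "")[1]],
      call. = FALSE
    )
  }
  bad <- stringi::stri_detect_regex(sequences, "[^ACDEFGHIKLMNPQRSTVWYXBZU]")
  if (any(bad)) {
    stop("sequence for ", names(sequences)[bad][1], " contains invalid characters",
      call. = FALSE
    )
  }
  nonstandard <- stringi::stri_detect_regex(sequences, "[XBZU]")
  if (any(nonstandard)) {
    warning(sum(nonstandard), " sequence(s) contain nonstandard residues (X/B/Z/U)",
      call. = FALSE
    )
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sequences)), names(sequences))
  }
  structure(
    list(
      seq = sequences,
      desc = descriptions[names(sequences)],
      nonstandard = stats::setNames(nonstandard, names(sequences))
    ),
    class = "protein_db"
  )
}

#' @export
print.protein_db <- function(x, ...) {
  cat("<protein_db> ", length(x$seq), " proteins, total length ",
    sum(nchar(x$seq)), " residues\n",
    sep = ""
  )
  invisible(x)
}

#' @export
length.protein_db <- function(x) length(x$seq)

#' Read a protein database from FASTA
#'
#' The accession is the first whitespace-delimited token of each header;
#' the remainder of the header is kept as the description. Wrapped and
#' single-line FASTA are both accepted. Duplicate accessions are an error.
#'
#' @param path Path to a FASTA file.
#' @return A [protein_db()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(aa)
  acc <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  desc <- trimws(stringi::stri_replace_first_regex(headers, "^\\S+\\s*", ""))
  if (anyDuplicated(acc)) {
    stop("duplicate accession in FASTA: ", acc[duplicated(acc)][1], call. = FALSE)
  }
  protein_db(stats::setNames(as.character(aa), acc), stats::setNames(desc, acc))
}

#' Write a protein database to FASTA
#'
#' @param db A `protein_db`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (acc in names(db$seq)) {
    header <- if (nzchar(db$desc[[acc]])) paste(acc, db$desc[[acc]]) else acc
    writeLines(paste0(">", header), con)
    s <- db$seq[[acc]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
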