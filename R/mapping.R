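# Peptide-to-protein localization and cleavage-site derivation.
#
# In the per-peptide simplification used throughout: P1 is the peptide's
# last residue (the residue N-terminal of the C-side cleavage) and P1' is
# its first residue (the residue C-terminal of the N-side cleavage). A
# peptide end that coincides with the parent protein's own terminus was not
# generated by a protease and is excluded from cleavage-site statistics.

#' Locate a peptide within a protein sequence
#'
#' Finds every occurrence (overlapping occurrences included) of a peptide
#' in a protein and annotates each with 1-based inclusive coordinates, the
#' flanking residues, protein-terminus flags and the P1/P1' residues.
#'
#' With `met_tolerant = TRUE` (default) a peptide starting at position 2 of
#' a protein whose first residue is the initiator methionine is treated as
#' protein-N-terminal, since the mature protein commonly lacks the
#' initiator Met and such a peptide end reflects no proteolytic cleavage.
#'
#' @param sequence Peptide sequence (uppercase).
#' @param protein Protein sequence (uppercase).
#' @param accession Accession to stamp on the result.
#' @param met_tolerant Treat start = 2 behind an initiator Met as
#'   protein-N-terminal (default `TRUE`).
#' @return A tibble with one row per occurrence: `accession`, `start`,
#'   `end`, `preceding`, `following`, `n_term`, `c_term`, `init_met`,
#'   `p1`, `p1_prime`. Zero rows when the peptide is absent.
#' @examples
#' locate_peptide("AA", "AAA", "toy") # two overlapping occurrences
#' @export
locate_peptide <- function(sequence, protein, accession = "protein",
                           met_tolerant = TRUE) {
  stopifnot(length(sequence) == 1L, length(protein) == 1L)
  hits <- stringi::stri_locate_all_fixed(protein, sequence, overlap = TRUE)[[1]]
  if (nrow(hits) == 1 && is.na(hits[1, 1])) {
    return(empty_locations())
  }
  start <- hits[, 1]
  end <- hits[, 2]
  plen <- nchar(protein)
  init_met <- start == 2L & substr(protein, 1, 1) == "M"
  tibble::tibble(
    accession = accession,
    start = as.integer(start),
    end = as.integer(end),
    preceding = ifelse(start > 1, substring(protein, start - 1, start - 1), NA_character_),
    following = ifelse(end < plen, substring(protein, end + 1, end + 1), NA_character_),
    n_term = start == 1L | (met_tolerant & init_met),
    c_term = end == plen,
    init_met = init_met,
    p1 = substr(sequence, nchar(sequence), nchar(sequence)),
    p1_prime = substr(sequence, 1, 1)
  )
}

empty_locations <- function() {
  tibble::tibble(
    accession = character(), start = integer(), end = integer(),
    preceding = character(), following = character(),
    n_term = logical(), c_term = logical(), init_met = logical(),
    p1 = character(), p1_prime = character()
  )
}

# Locate all unique sequences in all db proteins in a few vectorized passes.
locate_all <- function(sequences, db, met_tolerant = TRUE) {
  out <- vector("list", length(db$seq))
  for (i in seq_along(db$seq)) {
    prot <- db$seq[[i]]
    acc <- names(db$seq)[i]
    hits <- stringi::stri_locate_all_fixed(prot, sequences, overlap = TRUE)
    n_hits <- vapply(hits, function(h) if (is.na(h[1, 1])) 0L else nrow(h), integer(1))
    if (sum(n_hits) == 0) next
    idx <- rep.int(seq_along(sequences), n_hits)
    start <- unlist(lapply(hits[n_hits > 0], function(h) h[, 1]), use.names = FALSE)
    end <- unlist(lapply(hits[n_hits > 0], function(h) h[, 2]), use.names = FALSE)
    plen <- nchar(prot)
    seqs <- sequences[idx]
    init_met <- start == 2L & substr(prot, 1, 1) == "M"
    out[[i]] <- tibble::tibble(
      sequence = seqs,
      accession = acc,
      start = as.integer(start),
      end = as.integer(end),
      preceding = ifelse(start > 1, substring(prot, start - 1, start - 1), NA_character_),
      following = ifelse(end < plen, substring(prot, end + 1, end + 1), NA_character_),
      n_term = start == 1L | (met_tolerant & init_met),
      c_term = end == plen,
      init_met = init_met
    )
  }
  dplyr::bind_rows(out)
}

#' Map a grouped dataset onto a protein database
#'
#' Localizes every peptide record in its parent protein(s). The ambiguity
#' policy controls which proteins are searched:
#' \describe{
#'   \item{`declared_then_all` (default)}{search the record's declared
#'     accessions; records without declared accessions (or whose declared
#'     accessions yield no hit) fall back to a search of the whole
#'     database.}
#'   \item{`declared_accession_only`}{search only declared accessions;
#'     declared accessions absent from the database are counted in the
#'     `missing_accessions` report.}
#'   \item{`all_locations`}{search every protein, keep every occurrence.}
#'   \item{`first_accession`}{search every protein, keep only occurrences
#'     in the first database protein (database order) with a hit.}
#' }
#' Peptides with no location under the policy are retained in the
#' `unmapped` report, never dropped silently.
#'
#' @param ds A [grouped_dataset()].
#' @param db A [protein_db()].
#' @param policy Ambiguity policy (see above).
#' @param met_tolerant Initiator-Met tolerance, see [locate_peptide()].
#' @return An object of class `mapped_dataset`: list with `locations` (one
#'   row per record x location, with flanking residues and terminus flags),
#'   `unmapped` (records without a location) and `missing_accessions`.
#' @export
map_dataset <- function(ds, db,
                        policy = c(
                          "declared_then_all", "declared_accession_only",
                          "all_locations", "first_accession"
                        ),
                        met_tolerant = TRUE) {
  policy <- match.arg(policy)
  records <- dataset_records(ds)
  uniq <- records |>
    dplyr::distinct(.data$sequence, .data$accessions)
  all_hits <- locate_all(unique(uniq$sequence), db, met_tolerant)

  missing_acc <- character()
  pick <- function(sequence, accessions) {
    hits <- all_hits[all_hits$sequence == sequence, , drop = FALSE]
    declared <- if (is.na(accessions)) character() else strsplit(accessions, ";", fixed = TRUE)[[1]]
    if (policy %in% c("declared_accession_only", "declared_then_all") && length(declared) > 0) {
      absent <- setdiff(declared, names(db$seq))
      if (length(absent) > 0) missing_acc <<- union(missing_acc, absent)
      sel <- hits[hits$accession %in% declared, , drop = FALSE]
      if (nrow(sel) > 0 || policy == "declared_accession_only") {
        return(sel)
      }
    }
    if (policy == "declared_accession_only") {
      return(hits[0, , drop = FALSE])
    }
    if (policy == "first_accession" && nrow(hits) > 0) {
      first <- names(db$seq)[min(match(unique(hits$accession), names(db$seq)))]
      return(hits[hits$accession == first, , drop = FALSE])
    }
    hits
  }

  per_pair <- lapply(seq_len(nrow(uniq)), function(i) {
    sel <- pick(uniq$sequence[i], uniq$accessions[i])
    sel$accessions <- uniq$accessions[i]
    sel$sequence <- rep(uniq$sequence[i], nrow(sel))
    sel
  })
  pair_hits <- dplyr::bind_rows(per_pair)

  joined <- dplyr::inner_join(records, pair_hits,
    by = c("sequence", "accessions"), relationship = "many-to-many"
  )
  joined <- joined |>
    dplyr::group_by(.data$sample_id, .data$sequence) |>
    dplyr::mutate(n_locations = dplyr::n(), ambiguous = dplyr::n() > 1L) |>
    dplyr::ungroup() |>
    dplyr::select(
      "sample_id", "group", "sequence", "spectral_count", "accession",
      "start", "end", "preceding", "following", "n_term", "c_term",
      "init_met", "n_locations", "ambiguous"
    )

  unmapped <- dplyr::anti_join(records, pair_hits, by = c("sequence", "accessions"))

  structure(
    list(
      locations = joined,
      unmapped = unmapped,
      missing_accessions = missing_acc,
      met_tolerant = met_tolerant,
      policy = policy
    ),
    class = "mapped_dataset"
  )
}

#' @export
print.mapped_dataset <- function(x, ...) {
  cat("<mapped_dataset> ", nrow(x$locations), " locations; ",
    nrow(x$unmapped), " unmapped records; policy ", x$policy, "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-peptide cleavage-site records
#'
#' Reduces a mapped dataset to one row per peptide record with the residues
#' flanking its two ends and usability flags: the C-side cleavage (P1 = the
#' peptide's last residue) is usable only if no location of the peptide
#' ends at a protein C-terminus, and the N-side cleavage (P1' = the first
#' residue) only if no location starts at a protein N-terminus (position 1,
#' or position 2 behind an initiator Met when `met_tolerant`). An ambiguous
#' peptide contributes its residues once, not once per location — spectral
#' count is a per-peptide quantity.
#'
#' @param mapped A `mapped_dataset`.
#' @param met_tolerant Initiator-Met tolerance; defaults to the value used
#'   at mapping time.
#' @return A tibble of class `cleavage_records` with columns `sample_id`,
#'   `group`, `sequence`, `spectral_count`, `p1`, `p1_prime`, `p1_usable`,
#'   `p1_prime_usable`, `preceding`, `following`. Unmapped records are
#'   excluded; their number is kept in attribute `n_unmapped`.
#' @export
cleavage_site_records <- function(mapped, met_tolerant = mapped$met_tolerant) {
  loc <- mapped$locations
  out <- loc |>
    dplyr::group_by(.data$sample_id, .data$group, .data$sequence, .data$spectral_count) |>
    dplyr::summarise(
      p1_usable = !any(.data$c_term),
      p1_prime_usable = !any(.data$start == 1L | (met_tolerant & .data$init_met)),
      preceding = .data$preceding[1],
      following = .data$following[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p1 = substr(.data$sequence, nchar(.data$sequence), nchar(.data$sequence)),
      p1_prime = substr(.data$sequence, 1, 1)
    ) |>
    dplyr::select(
      "sample_id", "group", "sequence", "spectral_count",
      "p1", "p1_prime", "p1_usable", "p1_prime_usable",
      "preceding", "following"
    )
  structure(out,
    n_unmapped = nrow(mapped$unmapped),
    class = c("cleavage_records", class(out))
  )
}
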