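# Per-protein coverage profiles, region-confined spectral sums and
# literature cross-matching.

#' Define a protein region
#'
#' @param accession Protein accession.
#' @param start,end 1-based inclusive residue positions.
#' @param label Human-readable label (default `"accession:start-end"`).
#' @param reference_peptides Optional character vector of reference peptide
#'   sequences attributed to the region in the literature.
#' @param db Optional [protein_db()]; when given, bounds are validated
#'   against the protein length.
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(accession, start, end, label = NULL,
                        reference_peptides = NULL, db = NULL) {
  if (start < 1 || end < start) stop("need 1 <= start <= end", call. = FALSE)
  if (!is.null(db)) {
    if (!accession %in% names(db$seq)) {
      stop("accession ", accession, " not in database", call. = FALSE)
    }
    if (end > nchar(db$seq[[accession]])) {
      stop("region extends past the end of ", accession, call. = FALSE)
    }
  }
  structure(
    list(
      accession = accession, start = as.integer(start), end = as.integer(end),
      label = if (is.null(label)) paste0(accession, ":", start, "-", end) else label,
      reference_peptides = reference_peptides
    ),
    class = "region_spec"
  )
}

#' Per-residue peptide coverage of a protein
#'
#' For every residue position of a protein: how many distinct peptides
#' cover it and the summed spectral count of the covering peptides — the
#' peptide-alignment ("peptigram") view of a substrate. Aggregation is per
#' sample, per group (per-sample profiles averaged within each group), or
#' pooled over the whole dataset.
#'
#' @param mapped A `mapped_dataset`.
#' @param db The [protein_db()] used for mapping.
#' @param accession Protein to profile.
#' @param aggregate `"per_group"` (default), `"per_sample"` or `"pooled"`.
#' @return A tibble of class `coverage_profile` with columns `unit` (group
#'   or sample label, `"all"` when pooled), `position`, `n_peptides`,
#'   `spectral_count`; attribute `protein_length`. All positions 1..length
#'   are present (zeros where uncovered).
#' @export
coverage_profile <- function(mapped, db, accession,
                             aggregate = c("per_group", "per_sample", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (!accession %in% names(db$seq)) {
    stop("accession ", accession, " not in database", call. = FALSE)
  }
  plen <- nchar(db$seq[[accession]])
  loc <- mapped$locations |>
    dplyr::filter(.data$accession == !!accession) |>
    dplyr::distinct(.data$sample_id, .data$group, .data$sequence, .data$spectral_count,
      .data$start, .data$end,
      .keep_all = FALSE
    )
  unit_of <- switch(aggregate,
    per_sample = loc$sample_id,
    per_group = loc$group,
    pooled = rep("all", nrow(loc))
  )
  units <- switch(aggregate,
    per_sample = unique(mapped$locations$sample_id),
    per_group = unique(mapped$locations$group),
    pooled = "all"
  )
  profile_one <- function(rows) {
    n_pep <- integer(plen)
    spec <- numeric(plen)
    # one distinct peptide may occur at several coordinates; count each
    # covered position once per distinct peptide for n_peptides
    if (nrow(rows) > 0) {
      per_pep <- split(rows, rows$sequence)
      for (pp in per_pep) {
        covered <- unique(unlist(mapply(seq, pp$start, pp$end, SIMPLIFY = FALSE)))
        n_pep[covered] <- n_pep[covered] + 1L
        # spectral mass per sample record, over each distinct placement once
        placements <- unique(pp[, c("sample_id", "start", "end", "spectral_count")])
        pos_counts <- unique(placements[, c("sample_id", "start", "end", "spectral_count")])
        for (k in seq_len(nrow(pos_counts))) {
          idx <- pos_counts$start[k]:pos_counts$end[k]
          spec[idx] <- spec[idx] + pos_counts$spectral_count[k]
        }
      }
    }
    tibble::tibble(position = seq_len(plen), n_peptides = n_pep, spectral_count = spec)
  }
  parts <- lapply(units, function(u) {
    rows <- loc[unit_of == u, , drop = FALSE]
    prof <- if (aggregate == "per_group") {
      # mean over the group's samples of per-sample summed spectral count
      smp <- unique(mapped$locations$sample_id[mapped$locations$group == u])
      per_sample <- lapply(smp, function(s) profile_one(rows[rows$sample_id == s, , drop = FALSE]))
      tibble::tibble(
        position = seq_len(plen),
        n_peptides = profile_one(rows)$n_peptides,
        spectral_count = Reduce(`+`, lapply(per_sample, `[[`, "spectral_count")) /
          max(1L, length(smp))
      )
    } else {
      profile_one(rows)
    }
    prof$unit <- u
    prof
  })
  out <- dplyr::bind_rows(parts)[, c("unit", "position", "n_peptides", "spectral_count")]
  structure(out,
    protein_length = plen, accession = accession,
    class = c("coverage_profile", class(out))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peptide alignment map of a protein
#'
#' One row per distinct peptide placement on a protein with per-group mean
#' spectral counts, ready for drawing an alignment map.
#'
#' @param mapped A `mapped_dataset`.
#' @param accession Protein accession.
#' @return Tibble with columns `sequence`, `start`, `end`, `group`,
#'   `mean_count` (mean over the group's samples, absent samples count 0)
#'   and `total_count`.
#' @export
alignment_map <- function(mapped, accession) {
  loc <- mapped$locations |>
    dplyr::filter(.data$accession == !!accession)
  n_samples <- mapped$locations |>
    dplyr::distinct(.data$group, .data$sample_id) |>
    dplyr::count(.data$group, name = "n_samples")
  loc |>
    dplyr::distinct(
      .data$sequence, .data$start, .data$end, .data$group,
      .data$sample_id, .data$spectral_count
    ) |>
    dplyr::group_by(.data$sequence, .data$start, .data$end, .data$group) |>
    dplyr::summarise(total_count = sum(.data$spectral_count), .groups = "drop") |>
    dplyr::left_join(n_samples, by = "group") |>
    dplyr::mutate(mean_count = .data$total_count / .data$n_samples) |>
    dplyr::select("sequence", "start", "end", "group", "mean_count", "total_count") |>
    dplyr::arrange(.data$start, .data$end, .data$sequence, .data$group)
}

#' Spectral-count totals of a protein region
#'
#' Sums spectral counts of the peptides attributable to a region, per
#' group. In `confined` mode (default) a peptide counts only when it lies
#' entirely inside the region; in `overlapping` mode any overlap counts.
#' When the region carries `reference_peptides`, exact-sequence totals are
#' reported for each of them as well.
#'
#' @param mapped A `mapped_dataset`.
#' @param region A [region_spec()].
#' @param mode `"confined"` or `"overlapping"`.
#' @param stat `"sum"` (default) of per-sample counts per group, or
#'   `"mean"`.
#' @return List with `region_totals` (tibble `group`, `total`) and
#'   `exact_totals` (tibble `sequence`, `group`, `total`; zero rows when
#'   the region lists no reference peptides).
#' @export
region_spectral_sum <- function(mapped, region,
                                mode = c("confined", "overlapping"),
                                stat = c("sum", "mean")) {
  mode <- match.arg(mode)
  stat <- match.arg(stat)
  stopifnot(inherits(region, "region_spec"))
  agg <- if (stat == "sum") sum else mean
  loc <- mapped$locations |>
    dplyr::filter(.data$accession == region$accession)
  in_region <- if (mode == "confined") {
    loc$start >= region$start & loc$end <= region$end
  } else {
    loc$start <= region$end & loc$end >= region$start
  }
  groups <- unique(mapped$locations$group)
  hits <- loc[in_region, , drop = FALSE] |>
    dplyr::distinct(.data$sample_id, .data$group, .data$sequence, .data$spectral_count)
  per_sample <- hits |>
    dplyr::group_by(.data$group, .data$sample_id) |>
    dplyr::summarise(total = sum(.data$spectral_count), .groups = "drop")
  region_totals <- tibble::tibble(group = groups) |>
    dplyr::left_join(
      per_sample |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(total = agg(.data$total), .groups = "drop"),
      by = "group"
    ) |>
    dplyr::mutate(total = dplyr::coalesce(.data$total, 0))
  exact_totals <- tibble::tibble(
    sequence = character(), group = character(), total = numeric()
  )
  if (length(region$reference_peptides) > 0) {
    exact_totals <- tidyr::crossing(
      sequence = region$reference_peptides, group = groups
    ) |>
      dplyr::left_join(
        hits |>
          dplyr::group_by(.data$sequence, .data$group) |>
          dplyr::summarise(total = sum(.data$spectral_count), .groups = "drop"),
        by = c("sequence", "group")
      ) |>
      dplyr::mutate(total = dplyr::coalesce(.data$total, 0))
  }
  list(region_totals = region_totals, exact_totals = exact_totals)
}

#' Cross-match a peptidome against literature peptides
#'
#' For each reference sequence from the literature: exact matches in the
#' dataset, and containment matches in either direction (a dataset peptide
#' contained in the reference, or containing it), with per-group summed
#' spectral counts. Matching is exact-substring only; no similarity
#' scoring.
#'
#' @param ds A [grouped_dataset()].
#' @param references Data frame with columns `sequence` and optionally
#'   `annotation`.
#' @return Tibble with columns `reference`, `annotation`, `match_type`
#'   (`exact`, `contains_reference`, `contained_in_reference`),
#'   `matched_sequence`, `group`, `total`.
#' @export
literature_match <- function(ds, references) {
  if (!"sequence" %in% names(references)) {
    stop("references need a 'sequence' column", call. = FALSE)
  }
  if (!"annotation" %in% names(references)) {
    references$annotation <- rep(NA_character_, nrow(references))
  }
  if (nrow(references) == 0) {
    return(tibble::tibble(
      reference = character(), annotation = character(),
      match_type = character(), matched_sequence = character(),
      group = character(), total = numeric()
    ))
  }
  per_group <- dataset_records(ds) |>
    dplyr::group_by(.data$sequence, .data$group) |>
    dplyr::summarise(total = sum(.data$spectral_count), .groups = "drop")
  seqs <- unique(per_group$sequence)
  out <- lapply(seq_len(nrow(references)), function(i) {
    ref <- toupper(references$sequence[i])
    exact <- seqs[seqs == ref]
    contains_ref <- seqs[nchar(seqs) > nchar(ref) &
      stringi::stri_detect_fixed(seqs, ref)]
    contained <- seqs[nchar(seqs) < nchar(ref) &
      stringi::stri_detect_fixed(ref, seqs)]
    matches <- tibble::tibble(
      match_type = c(
        rep("exact", length(exact)),
        rep("contains_reference", length(contains_ref)),
        rep("contained_in_reference", length(contained))
      ),
      matched_sequence = c(exact, contains_ref, contained)
    )
    if (nrow(matches) == 0) {
      return(NULL)
    }
    matches |>
      dplyr::inner_join(per_group, by = c(matched_sequence = "sequence")) |>
      dplyr::mutate(reference = ref, annotation = references$annotation[i])
  })
  dplyr::bind_rows(out) |>
    dplyr::select(
      "reference", "annotation", "match_type",
      "matched_sequence", "group", "total"
    )
}
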