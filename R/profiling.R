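# Amino-acid composition and terminal-tetrapeptide profiling.

#' Spectral-count weighted amino-acid composition
#'
#' Computes the residue frequency profile of a peptidome. In `full` mode
#' each residue of each peptide contributes its number of occurrences in
#' the sequence multiplied by the peptide's spectral count (or by 1 when
#' `weighting = "unweighted"`). In `P1` / `P1_prime` mode the single
#' cleavage-site residue of each peptide contributes its spectral count;
#' peptide ends that coincide with a protein terminus carry no cleavage
#' information and are excluded, which is why these modes require the
#' cleavage records produced by [cleavage_site_records()].
#'
#' @param tables A `sample_table`, a list of them, or a
#'   [grouped_dataset()]; ignored in P1/P1' modes.
#' @param position_mode One of `"full"`, `"P1"`, `"P1_prime"`.
#' @param cleavage_records A `cleavage_records` tibble (required for
#'   P1/P1' modes).
#' @param weighting `"spectral_count"` (default) or `"unweighted"`.
#' @return A tibble of class `composition_profile` with columns `residue`
#'   and `frequency` (all 20 residues, frequencies summing to 1), and
#'   attributes `position_mode`, `weighting` and `n_effective` (the total
#'   weight). Zero total weight yields all-`NA` frequencies with a warning.
#' @examples
#' t <- sample_table(c("A", "K"), c(1, 3), sample_id = "s1")
#' aa_composition(t) # A 0.25, K 0.75
#' @export
aa_composition <- function(tables = NULL,
                           position_mode = c("full", "P1", "P1_prime"),
                           cleavage_records = NULL,
                           weighting = c("spectral_count", "unweighted")) {
  position_mode <- match.arg(position_mode)
  weighting <- match.arg(weighting)
  if (position_mode == "full") {
    records <- pool_records(tables)
    w <- if (weighting == "spectral_count") records$spectral_count else rep(1, nrow(records))
    if (nrow(records) == 0 || sum(w) == 0) {
      return(null_profile(position_mode, weighting))
    }
    counts <- residue_count_matrix(records$sequence)
    totals <- colSums(counts * w)
  } else {
    if (is.null(cleavage_records)) {
      stop(position_mode, " composition requires cleavage_records ",
        "(protein-terminal peptide ends must be excluded)",
        call. = FALSE
      )
    }
    cr <- tibble::as_tibble(cleavage_records)
    usable <- if (position_mode == "P1") cr$p1_usable else cr$p1_prime_usable
    res <- if (position_mode == "P1") cr$p1 else cr$p1_prime
    res <- res[usable]
    w <- if (weighting == "spectral_count") cr$spectral_count[usable] else rep(1, sum(usable))
    if (length(res) == 0 || sum(w) == 0) {
      return(null_profile(position_mode, weighting))
    }
    totals <- vapply(AA_ALPHABET, function(a) sum(w[res == a]), numeric(1))
  }
  new_composition_profile(totals / sum(totals), position_mode, weighting, sum(w))
}

new_composition_profile <- function(freqs, position_mode, weighting, n_effective) {
  out <- tibble::tibble(residue = AA_ALPHABET, frequency = unname(freqs[AA_ALPHABET]))
  structure(out,
    position_mode = position_mode, weighting = weighting,
    n_effective = n_effective,
    class = c("composition_profile", class(out))
  )
}

null_profile <- function(position_mode, weighting) {
  warning("zero total weight; returning all-NA profile", call. = FALSE)
  new_composition_profile(
    stats::setNames(rep(NA_real_, 20), AA_ALPHABET),
    position_mode, weighting, 0
  )
}

pool_records <- function(tables) {
  if (inherits(tables, "grouped_dataset")) {
    return(dataset_records(tables))
  }
  if (inherits(tables, "sample_table")) tables <- list(tables)
  dplyr::bind_rows(lapply(tables, tibble::as_tibble))
}

#' Collapse a composition profile by side-chain class
#'
#' @param profile A `composition_profile`.
#' @param grouping Named character vector residue -> group label; defaults
#'   to [side_chain_grouping()].
#' @return A tibble with columns `group` and `frequency`, summing to 1.
#' @export
group_composition <- function(profile, grouping = side_chain_grouping()) {
  check_grouping(grouping)
  tibble::as_tibble(profile) |>
    dplyr::mutate(group = unname(grouping[.data$residue])) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop")
}

#' Reference amino-acid composition
#'
#' Either the unweighted residue frequencies over all sequences of a
#' protein database, or (default) the bundled published residue frequencies
#' of the whole UniProtKB/Swiss-Prot database, used as the whole-proteome
#' background a peptidome profile is compared against.
#'
#' @param source A [protein_db()], or `"swissprot"` for the bundled table.
#' @return A `composition_profile` (unweighted, full mode).
#' @export
reference_composition <- function(source = "swissprot") {
  if (identical(source, "swissprot")) {
    f <- SWISSPROT_FREQ_PCT / sum(SWISSPROT_FREQ_PCT)
    return(new_composition_profile(f, "full", "unweighted", NA_real_))
  }
  if (!inherits(source, "protein_db")) {
    stop("source must be a protein_db or \"swissprot\"", call. = FALSE)
  }
  counts <- colSums(residue_count_matrix(unname(source$seq)))
  new_composition_profile(counts / sum(counts), "full", "unweighted", sum(counts))
}

#' Terminal k-mer abundance table
#'
#' Aggregates spectral counts over the unique N- or C-terminal `k`-mer of
#' every peptide (default `k = 4`, the MEROPS convention for terminal
#' tetrapeptides). Unlike the P1/P1' cleavage profiles, peptides whose end
#' coincides with a protein terminus are deliberately kept: inherent
#' termini are themselves of biomarker interest. Peptides shorter than `k`
#' are excluded and counted in the `n_excluded_short` attribute.
#'
#' @param tables A `sample_table`, list of them, or [grouped_dataset()].
#' @param end `"N"` (first `k` residues) or `"C"` (last `k` residues).
#' @param k Terminal length (default 4).
#' @return A tibble of class `terminal_table` with columns `terminal`,
#'   `sample_id`, `group`, `count` (spectral counts aggregated per sample),
#'   and attributes `end`, `k`, `n_excluded_short`.
#' @export
terminal_table <- function(tables, end = c("N", "C"), k = 4) {
  end <- match.arg(end)
  stopifnot(k >= 1)
  records <- pool_records(tables)
  if (!"sample_id" %in% names(records)) {
    records$sample_id <- if (inherits(tables, "sample_table")) sample_id(tables) else NA_character_
    records$group <- if (inherits(tables, "sample_table")) group_label(tables) else NA_character_
  }
  long_enough <- nchar(records$sequence) >= k
  n_excluded <- sum(!long_enough)
  records <- records[long_enough, , drop = FALSE]
  records$terminal <- if (end == "N") {
    substr(records$sequence, 1, k)
  } else {
    substr(records$sequence, nchar(records$sequence) - k + 1, nchar(records$sequence))
  }
  out <- records |>
    dplyr::group_by(.data$terminal, .data$sample_id, .data$group) |>
    dplyr::summarise(count = sum(.data$spectral_count), .groups = "drop")
  structure(out,
    end = end, k = k, n_excluded_short = n_excluded,
    class = c("terminal_table", class(out))
  )
}

#' Group-level summary of a terminal table
#'
#' Mean and standard deviation (N-1 denominator) of each terminal's
#' per-sample aggregated spectral count within each group. Samples of the
#' group lacking a terminal contribute a count of 0.
#'
#' @param tt A `terminal_table`.
#' @return Tibble with columns `terminal`, `group`, `mean`, `sd`, `total`.
#' @export
terminal_summary <- function(tt) {
  x <- tibble::as_tibble(tt)
  units <- dplyr::distinct(x, .data$group, .data$sample_id)
  tidyr::crossing(terminal = unique(x$terminal), units) |>
    dplyr::left_join(x, by = c("terminal", "group", "sample_id")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0)) |>
    dplyr::group_by(.data$terminal, .data$group) |>
    dplyr::summarise(
      mean = mean(.data$count),
      sd = stats::sd(.data$count),
      total = sum(.data$count),
      .groups = "drop"
    )
}

#' Collapse terminal k-mers by side-chain class
#'
#' Translates every terminal residue-wise into its side-chain group label
#' (e.g. `HKYH` -> `basic-basic-polar_uncharged-basic`) and aggregates
#' counts over identical group strings.
#'
#' @param tt A `terminal_table`.
#' @param grouping Named character vector residue -> group label.
#' @return A `terminal_table` whose `terminal` column holds group strings.
#' @export
grouped_terminal_table <- function(tt, grouping = side_chain_grouping()) {
  check_grouping(grouping)
  x <- tibble::as_tibble(tt)
  translate <- function(s) {
    paste(grouping[strsplit(s, "", fixed = TRUE)[[1]]], collapse = "-")
  }
  x$terminal <- vapply(x$terminal, translate, character(1), USE.NAMES = FALSE)
  out <- x |>
    dplyr::group_by(.data$terminal, .data$sample_id, .data$group) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  structure(out,
    end = attr(tt, "end"), k = attr(tt, "k"),
    n_excluded_short = attr(tt, "n_excluded_short"),
    class = c("terminal_table", class(out))
  )
}

#' Rank-abundance series of terminal k-mers
#'
#' Orders terminals by descending aggregated spectral count (summed over
#' samples, or within each group when `per_group`), ties broken
#' lexicographically by terminal sequence so the ordering is deterministic.
#' The shape of the resulting rank-abundance curve reflects how strongly a
#' peptidome prefers particular termini.
#'
#' @param tt A `terminal_table`.
#' @param per_group Rank within each group separately (default `FALSE`).
#' @param stat Aggregate per-sample counts by `"sum"` (default) or
#'   `"mean"`.
#' @return Tibble with columns (`group`,) `terminal`, `value`, `rank`.
#' @export
rank_abundance <- function(tt, per_group = FALSE, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  x <- tibble::as_tibble(tt)
  agg <- if (stat == "sum") sum else mean
  keys <- if (per_group) c("group", "terminal") else "terminal"
  out <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(value = agg(.data$count), .groups = "drop")
  if (per_group) {
    out |>
      dplyr::group_by(.data$group) |>
      dplyr::arrange(dplyr::desc(.data$value), .data$terminal, .by_group = TRUE) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup()
  } else {
    out |>
      dplyr::arrange(dplyr::desc(.data$value), .data$terminal) |>
      dplyr::mutate(rank = dplyr::row_number())
  }
}
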