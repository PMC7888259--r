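# Set algebra between samples/groups, differential peptides, substrate
# abundance, outlier flagging, group statistics and protease attribution.

#' Venn region counts for 2-5 peptide sets
#'
#' Partitions the union of the given sequence sets into its Venn regions:
#' each sequence is counted in exactly one region, the subset of sets that
#' contain it. Region counts therefore always sum to the union size.
#'
#' @param sets Named list of 2-5 character vectors of peptide sequences.
#' @return A tibble of class `venn_counts` with columns `region` (set
#'   labels joined by `&`) and `count`, plus attributes `set_labels` and
#'   `union_size`. Empty regions are included with count 0.
#' @examples
#' venn_counts(list(S1 = c("A", "B"), S2 = c("B", "C")))
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 5) {
    stop("venn_counts needs between 2 and 5 sets", call. = FALSE)
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be named", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1)
  labels <- names(sets)
  region_of <- apply(membership, 1, function(m) paste(labels[m], collapse = "&"))
  all_regions <- unlist(lapply(seq_along(labels), function(r) {
    utils::combn(labels, r, paste, collapse = "&")
  }))
  counts <- table(factor(region_of, levels = all_regions))
  out <- tibble::tibble(region = all_regions, count = as.integer(counts))
  structure(out,
    set_labels = labels, union_size = length(universe),
    class = c("venn_counts", class(out))
  )
}

#' Intersectional peptides of a group
#'
#' The peptide sequences present in every sample of a group — the group's
#' reproducible core. Apply the spectral-count cutoff before calling this
#' if the core should be defined over filtered peptidomes.
#'
#' @param samples Non-empty list of `sample_table`s.
#' @return Character vector of sequences (sorted).
#' @export
intersectional_peptides <- function(samples) {
  stopifnot(length(samples) >= 1)
  sets <- lapply(samples, function(t) unique(t$sequence))
  sort(Reduce(intersect, sets))
}

#' Top differential peptides between two groups
#'
#' Candidate peptides are the union of the two groups' intersectional
#' (core) sets; restricting to cores keeps only reproducibly observed
#' sequences while the union retains group-exclusive markers. For each
#' candidate the difference between the groups' spectral counts (summed
#' over samples by default, 0 when absent from a group) is computed and the
#' `k` peptides with the largest absolute difference are returned, ties
#' broken lexicographically by sequence.
#'
#' @param group_a,group_b Lists of `sample_table`s (cutoff applied
#'   upstream).
#' @param k Number of peptides returned (default 50).
#' @param stat `"sum"` (default) or `"mean"` of per-sample counts.
#' @param mapped Optional `mapped_dataset`; when given, each peptide is
#'   annotated with its first location (accession, start, end) so the table
#'   is ready for protease-prediction tools.
#' @return Tibble with columns `sequence`, `count_a`, `count_b`,
#'   `difference`, `rank` (and location columns when `mapped` is given).
#' @export
differential_peptides <- function(group_a, group_b, k = 50,
                                  stat = c("sum", "mean"), mapped = NULL) {
  stopifnot(k >= 1)
  stat <- match.arg(stat)
  if (length(group_a) == 0 && length(group_b) == 0) {
    return(tibble::tibble(
      sequence = character(), count_a = numeric(),
      count_b = numeric(), difference = numeric(), rank = integer()
    ))
  }
  pool <- union(
    if (length(group_a)) intersectional_peptides(group_a) else character(),
    if (length(group_b)) intersectional_peptides(group_b) else character()
  )
  agg <- function(tables, sequences) {
    per_sample <- vapply(tables, function(t) {
      counts <- stats::setNames(t$spectral_count, t$sequence)[sequences]
      ifelse(is.na(counts), 0, counts)
    }, numeric(length(sequences)))
    if (length(sequences) == 1L) per_sample <- matrix(per_sample, nrow = 1)
    unname(if (stat == "sum") rowSums(per_sample) else rowMeans(per_sample))
  }
  out <- tibble::tibble(
    sequence = pool,
    count_a = if (length(group_a)) agg(group_a, pool) else 0,
    count_b = if (length(group_b)) agg(group_b, pool) else 0
  ) |>
    dplyr::mutate(difference = .data$count_a - .data$count_b) |>
    dplyr::arrange(dplyr::desc(abs(.data$difference)), .data$sequence) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = k)
  if (!is.null(mapped)) {
    first_loc <- mapped$locations |>
      dplyr::distinct(.data$sequence, .data$accession, .data$start, .data$end) |>
      dplyr::group_by(.data$sequence) |>
      dplyr::slice_head(n = 1) |>
      dplyr::ungroup()
    out <- dplyr::left_join(out, first_loc, by = "sequence")
  }
  out
}

#' Protein substrate abundance
#'
#' Sums spectral counts per parent protein, the "which substrates feed this
#' peptidome" view. An ambiguous peptide contributes its full spectral
#' count to each distinct protein it maps to (multiple occurrences within
#' one protein count once); the mass double-counted this way is reported in
#' the `double_counted` attribute. Accessions in `exclude_accessions` (for
#' example the jointly dominating hemoglobin subunits) are removed before
#' ranking.
#'
#' @param mapped A `mapped_dataset`.
#' @param exclude_accessions Character vector of accessions to drop.
#' @param by `"group"` (default) or `"all"`.
#' @return Tibble with columns (`group`,) `accession`, `total`, `share`,
#'   `rank`; attributes `n_proteins` (proteins with at least one peptide,
#'   before exclusion, per grouping unit) and `double_counted`.
#' @export
protein_substrate_abundance <- function(mapped, exclude_accessions = character(),
                                        by = c("group", "all")) {
  by <- match.arg(by)
  per_pep <- mapped$locations |>
    dplyr::distinct(
      .data$sample_id, .data$group, .data$sequence,
      .data$spectral_count, .data$accession
    )
  keys <- if (by == "group") c("group", "accession") else "accession"
  n_prot <- per_pep |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::count(dplyr::across(dplyr::all_of(setdiff(keys, "accession"))), name = "n_proteins")
  single_count <- mapped$locations |>
    dplyr::distinct(.data$sample_id, .data$sequence, .data$spectral_count)
  double_counted <- sum(per_pep$spectral_count) - sum(single_count$spectral_count)
  out <- per_pep |>
    dplyr::filter(!.data$accession %in% exclude_accessions) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(total = sum(.data$spectral_count), .groups = "drop")
  group_keys <- setdiff(keys, "accession")
  if (length(group_keys) > 0) {
    out <- out |> dplyr::group_by(dplyr::across(dplyr::all_of(group_keys)))
  }
  out <- out |>
    dplyr::mutate(share = .data$total / sum(.data$total)) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$accession, .by_group = length(group_keys) > 0) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  structure(out,
    n_proteins = n_prot, double_counted = double_counted,
    class = c("substrate_abundance", class(out))
  )
}

#' Top-n plus "other" pie data
#'
#' Collapses a substrate abundance table to its `top_n` proteins plus a
#' pooled `other` slice, per grouping unit.
#'
#' @param abundance Result of [protein_substrate_abundance()].
#' @param top_n Number of named slices (default 10).
#' @return Tibble with columns (`group`,) `accession`, `total`, `share`.
#' @export
substrate_pie_data <- function(abundance, top_n = 10) {
  x <- tibble::as_tibble(abundance)
  keys <- intersect("group", names(x))
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(accession = ifelse(.data$rank <= top_n, .data$accession, "other")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "accession")))) |>
    dplyr::summarise(
      total = sum(.data$total), share = sum(.data$share),
      .groups = "drop"
    )
}

#' Occurrence-vs-abundance outlier table
#'
#' For each sequence in a group: summed spectral count and the number of
#' samples containing it. Sequences with high total count seen in exactly
#' one sample are candidate false positives (in practice verified against
#' retention times, which is outside this package's scope) and are flagged
#' when their total exceeds the `count_quantile` quantile of all totals.
#'
#' @param group Non-empty list of `sample_table`s.
#' @param count_quantile Quantile defining "high count" (default 0.95).
#' @return Tibble with columns `sequence`, `total`, `n_samples`, `flagged`.
#' @export
occurrence_outliers <- function(group, count_quantile = 0.95) {
  records <- pool_records(group)
  if (!"sample_id" %in% names(records)) {
    records$sample_id <- rep(
      vapply(group, sample_id, character(1)),
      vapply(group, nrow, integer(1))
    )
  }
  out <- records |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      total = sum(.data$spectral_count),
      n_samples = dplyr::n_distinct(.data$sample_id),
      .groups = "drop"
    )
  threshold <- stats::quantile(out$total, count_quantile, names = FALSE)
  out |> dplyr::mutate(flagged = .data$n_samples == 1L & .data$total > threshold)
}

#' Compare a per-sample quantity between two groups
#'
#' Student's t test on two vectors of per-sample values: paired, or
#' Welch's unpaired test by default (group sizes in typical designs are
#' unequal and no natural pairing across patients exists). Zero-variance
#' degenerate inputs (all paired differences identical, or both groups
#' constant) are reported with `degenerate = TRUE` rather than an error.
#'
#' @param values_a,values_b Numeric vectors (per-sample values).
#' @param paired Paired test (requires equal lengths).
#' @param var_equal Use the pooled-variance Student test instead of Welch
#'   for the unpaired case.
#' @return One-row tibble: `t`, `df`, `p`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `method`, `degenerate`.
#' @export
compare_group_means <- function(values_a, values_b, paired = FALSE,
                                var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (paired && length(values_a) != length(values_b)) {
    stop("paired test requires equal group sizes", call. = FALSE)
  }
  base <- tibble::tibble(
    mean_a = mean(values_a), sd_a = stats::sd(values_a),
    mean_b = mean(values_b), sd_b = stats::sd(values_b)
  )
  degenerate <- if (paired) {
    stats::sd(values_a - values_b) == 0
  } else {
    stats::sd(values_a) == 0 && stats::sd(values_b) == 0
  }
  if (degenerate) {
    return(dplyr::bind_cols(
      tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_),
      base,
      tibble::tibble(
        method = if (paired) "paired t" else "unpaired t",
        degenerate = TRUE
      )
    ))
  }
  tt <- stats::t.test(values_a, values_b, paired = paired, var.equal = var_equal)
  dplyr::bind_cols(
    tibble::tibble(
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value
    ),
    base,
    tibble::tibble(method = tt$method, degenerate = FALSE)
  )
}

#' Protease specificity tables
#'
#' A specificity table maps protease names to the P1 residues (and
#' optionally P1' residues) they accept, with non-negative weights. This is
#' a deliberately simplified, fully deterministic rule table — presence or
#' absence of the cleavage-site residue in the allowed set — and makes no
#' claim of equivalence to database-driven protease-prediction services.
#'
#' @param ... Named protease entries, each a list with element `p1` (named
#'   numeric weights, or a bare character vector of residues meaning weight
#'   1) and optional `p1_prime`.
#' @return Object of class `protease_table`.
#' @examples
#' protease_table(
#'   trypsin_like = list(p1 = c("K", "R")),
#'   glu_c_like = list(p1 = c("D", "E"))
#' )
#' @export
protease_table <- function(...) {
  entries <- list(...)
  if (length(entries) == 0) stop("empty specificity table", call. = FALSE)
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop("proteases must be named", call. = FALSE)
  }
  norm <- function(x) {
    if (is.null(x)) {
      return(NULL)
    }
    if (is.character(x)) x <- stats::setNames(rep(1, length(x)), x)
    if (any(x < 0)) stop("specificity weights must be >= 0", call. = FALSE)
    x[x > 0]
  }
  entries <- lapply(entries, function(e) {
    p1 <- norm(e$p1)
    if (length(p1) == 0) stop("each protease needs at least one P1 residue", call. = FALSE)
    list(p1 = p1, p1_prime = norm(e$p1_prime))
  })
  structure(entries, class = "protease_table")
}

#' Rule-based protease attribution of cleavage events
#'
#' Every mapped, non-protein-terminal peptide end is a cleavage event: the
#' N-side event's P1 is the residue preceding the peptide in the protein
#' (its P1' is the peptide's first residue), and the C-side event's P1 is
#' the peptide's last residue (its P1' is the residue following the
#' peptide). Each event is attributed to every protease whose allowed P1
#' set (and P1' set, when the table specifies one) contains the event's
#' residues; a peptide may thus be compatible with several proteases, and
#' an ambiguous peptide contributes each of its two events once.
#'
#' @param cleavage A `cleavage_records` tibble (see
#'   [cleavage_site_records()]).
#' @param table A [protease_table()].
#' @param weight `"events"` (default; each compatible event counts 1) or
#'   `"spectral_count"`.
#' @return Tibble with columns `protease`, `n_events`, `share` (of all
#'   attributable events, may sum above 1 since events can match several
#'   proteases), sorted by descending `n_events`.
#' @export
attribute_proteases <- function(cleavage, table, weight = c("events", "spectral_count")) {
  weight <- match.arg(weight)
  if (!inherits(table, "protease_table")) stop("table must be a protease_table", call. = FALSE)
  cr <- tibble::as_tibble(cleavage)
  events <- dplyr::bind_rows(
    # N-side cut: P1 = preceding residue, P1' = first residue of peptide
    cr |>
      dplyr::filter(.data$p1_prime_usable, !is.na(.data$preceding)) |>
      dplyr::transmute(
        p1 = .data$preceding, p1_prime = .data$p1_prime,
        w = .data$spectral_count
      ),
    # C-side cut: P1 = last residue of peptide, P1' = following residue
    cr |>
      dplyr::filter(.data$p1_usable) |>
      dplyr::transmute(
        p1 = .data$p1, p1_prime = .data$following,
        w = .data$spectral_count
      )
  )
  if (weight == "events") events$w <- 1
  totals <- vapply(table, function(e) {
    ok <- events$p1 %in% names(e$p1)
    if (!is.null(e$p1_prime)) {
      ok <- ok & !is.na(events$p1_prime) & events$p1_prime %in% names(e$p1_prime)
    }
    sum(events$w[ok])
  }, numeric(1))
  tibble::tibble(
    protease = names(totals),
    n_events = unname(totals),
    share = unname(totals) / sum(events$w)
  ) |>
    dplyr::arrange(dplyr::desc(.data$n_events), .data$protease)
}
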