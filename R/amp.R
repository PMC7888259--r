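# Antimicrobial scoring: external prediction scores (or the built-in
# composition heuristic), score x spectral-count arithmetic, heatmap
# matrices and per-substrate AMP totals.

#' Load per-peptide antimicrobial prediction scores
#'
#' Reads a delimited file of per-peptide antimicrobial prediction scores in
#' `[0, 1]` (e.g. the export of a CNN-based AMP predictor). Duplicated
#' sequences must agree to within 1e-9; scores outside `[0, 1]` are an
#' error naming the row.
#'
#' @param path Delimited text with columns `sequence` and `score` (names
#'   adjustable via `sequence_col` / `score_col`).
#' @param sequence_col,score_col Source column names.
#' @return Named numeric vector sequence -> prediction.
#' @export
load_amp_predictions <- function(path, sequence_col = "sequence", score_col = "score") {
  if (!file.exists(path)) stop("predictions file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path,
    header = TRUE, sep = detect_delimiter(path),
    stringsAsFactors = FALSE
  )
  for (col in c(sequence_col, score_col)) {
    if (!col %in% names(raw)) {
      stop("predictions file lacks column '", col, "'", call. = FALSE)
    }
  }
  scores <- suppressWarnings(as.numeric(raw[[score_col]]))
  bad <- which(is.na(scores) | scores < 0 | scores > 1)
  if (length(bad) > 0) {
    stop("prediction score out of [0,1] in row ", bad[1], call. = FALSE)
  }
  seqs <- toupper(raw[[sequence_col]])
  split_scores <- split(scores, seqs)
  conflict <- vapply(split_scores, function(s) diff(range(s)) > 1e-9, logical(1))
  if (any(conflict)) {
    stop(
      "conflicting scores for duplicated sequence ",
      names(split_scores)[conflict][1],
      call. = FALSE
    )
  }
  vapply(split_scores, `[`, numeric(1), 1)
}

#' Built-in composition-based antimicrobial score
#'
#' A deterministic logistic score of cationicity and hydrophobicity, the
#' two composition features classically associated with antimicrobial
#' peptides: with `z = #K + #R + 0.5 #H - (#D + #E)` (net charge proxy)
#' and `h` the fraction of hydrophobic residues (A, I, L, M, F, W, V, C),
#' the score is `1 / (1 + exp(-(0.5 z + 4 h - 3)))`. The formula is frozen
#' so results are reproducible. It is a simple heuristic scorer for running
#' the pipeline end to end and for testing; it does not reproduce any
#' published machine-learning predictor's values.
#'
#' @param sequence Character vector of peptide sequences.
#' @return Numeric vector of scores in (0, 1).
#' @examples
#' builtin_amp_score("KKKK") > builtin_amp_score("DDDD")
#' @export
builtin_amp_score <- function(sequence) {
  if (length(sequence) == 0) {
    return(numeric())
  }
  check_sequences(sequence)
  counts <- residue_count_matrix(sequence)
  z <- counts[, "K"] + counts[, "R"] + 0.5 * counts[, "H"] -
    (counts[, "D"] + counts[, "E"])
  hydrophobic <- c("A", "I", "L", "M", "F", "W", "V", "C")
  h <- rowSums(counts[, hydrophobic, drop = FALSE]) / nchar(sequence)
  unname(stats::plogis(0.5 * z + 4 * h - 3))
}

#' Antimicrobial score tables for a dataset
#'
#' Assigns each peptide a prediction score (from `predictions`, or from
#' [builtin_amp_score()] when `predictions = NULL`), discards peptides
#' below the prediction cutoff, and computes the antimicrobial score
#' `prediction x spectral_count` per peptide and sample — an estimate of
#' the peptide's contribution to the sample's antimicrobial milieu.
#' Peptides longer than `max_length` residues are outside the predictors'
#' domain and are excluded with a report; in external mode, scoreable
#' peptides without a prediction are likewise reported, not fatal.
#'
#' @param ds A [grouped_dataset()] (cutoff-filtered upstream as desired).
#' @param predictions Named numeric vector sequence -> prediction in
#'   `[0, 1]` (see [load_amp_predictions()]), or `NULL` for the built-in
#'   scorer.
#' @param cutoff Prediction cutoff; peptides with prediction >= cutoff are
#'   kept (default 0.7).
#' @param max_length Maximum scoreable peptide length (default 30).
#' @param mapped Optional `mapped_dataset` for the per-substrate AMP
#'   totals.
#' @return Object of class `amp_result`: list with `scores` (tibble
#'   `sample_id`, `group`, `sequence`, `prediction`, `spectral_count`,
#'   `score`), `heatmap` (peptides x samples matrix of scores),
#'   `group_totals` (summed spectral counts of surviving peptides per
#'   group), `substrate` (per-group accession totals over surviving
#'   peptides; `NULL` without `mapped`), `too_long` and
#'   `missing_predictions` (character vectors of excluded sequences).
#' @export
antimicrobial_scores <- function(ds, predictions = NULL, cutoff = 0.7,
                                 max_length = 30, mapped = NULL) {
  records <- dataset_records(ds)
  seqs <- unique(records$sequence)
  too_long <- seqs[nchar(seqs) > max_length]
  scoreable <- setdiff(seqs, too_long)
  if (is.null(predictions)) {
    predictions <- stats::setNames(builtin_amp_score(scoreable), scoreable)
    missing <- character()
  } else {
    missing <- setdiff(scoreable, names(predictions))
  }
  kept <- scoreable[!is.na(predictions[scoreable]) & predictions[scoreable] >= cutoff]
  scores <- records |>
    dplyr::filter(.data$sequence %in% kept) |>
    dplyr::mutate(
      prediction = unname(predictions[.data$sequence]),
      score = .data$prediction * .data$spectral_count
    ) |>
    dplyr::select(
      "sample_id", "group", "sequence", "prediction",
      "spectral_count", "score"
    )
  sample_ids <- names(ds$tables)
  heatmap <- matrix(0,
    nrow = length(kept), ncol = length(sample_ids),
    dimnames = list(sort(kept), sample_ids)
  )
  if (nrow(scores) > 0) {
    heatmap[cbind(
      match(scores$sequence, rownames(heatmap)),
      match(scores$sample_id, sample_ids)
    )] <- scores$score
  }
  group_totals <- scores |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(total_spectral_count = sum(.data$spectral_count), .groups = "drop")
  substrate <- NULL
  if (!is.null(mapped)) {
    substrate <- mapped$locations |>
      dplyr::filter(.data$sequence %in% kept) |>
      dplyr::distinct(
        .data$sample_id, .data$group, .data$sequence,
        .data$spectral_count, .data$accession
      ) |>
      dplyr::group_by(.data$group, .data$accession) |>
      dplyr::summarise(total = sum(.data$spectral_count), .groups = "drop") |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(share = .data$total / sum(.data$total)) |>
      dplyr::arrange(dplyr::desc(.data$total), .by_group = TRUE) |>
      dplyr::ungroup()
  }
  structure(
    list(
      scores = scores, heatmap = heatmap, group_totals = group_totals,
      substrate = substrate, too_long = too_long,
      missing_predictions = missing, cutoff = cutoff
    ),
    class = "amp_result"
  )
}

#' @export
print.amp_result <- function(x, ...) {
  cat("<amp_result> ", nrow(x$heatmap), " peptides at prediction >= ",
    x$cutoff, " across ", ncol(x$heatmap), " samples\n",
    sep = ""
  )
  print(x$group_totals)
  invisible(x)
}
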