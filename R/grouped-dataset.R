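# Grouped datasets: samples organized into labeled groups, plus the
# per-group summary statistics.

#' Construct a grouped dataset
#'
#' Bundles sample tables into a labeled multi-group study design (for
#' example acute wound fluid vs non-infected vs infected dressing fluid).
#' Sample ids must be unique across the whole dataset.
#'
#' @param tables List of [sample_table()]s, each carrying a `group_label`
#'   (or supply `groups`).
#' @param groups Optional named character vector `sample_id -> group_label`
#'   overriding the labels stored on the tables.
#' @return An object of class `grouped_dataset`: a list with elements
#'   `tables` (named by sample id) and `groups`.
#' @export
grouped_dataset <- function(tables, groups = NULL) {
  ids <- vapply(tables, sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in dataset: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- stats::setNames(vapply(tables, group_label, character(1)), ids)
  } else {
    groups <- groups[ids]
  }
  if (anyNA(groups)) {
    stop("every sample needs a group_label", call. = FALSE)
  }
  tables <- lapply(seq_along(tables), function(i) {
    new_sample_table(tibble::as_tibble(tables[[i]]), ids[i], unname(groups[i]))
  })
  names(tables) <- ids
  structure(list(tables = tables, groups = groups), class = "grouped_dataset")
}

#' @export
print.grouped_dataset <- function(x, ...) {
  cat("<grouped_dataset> ", length(x$tables), " samples in ",
    length(unique(x$groups)), " groups\n",
    sep = ""
  )
  for (g in unique(x$groups)) {
    cat("  ", g, ": ", paste(names(x$groups)[x$groups == g], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Dataset accessors
#'
#' `dataset_groups()` lists the distinct group labels; `group_tables()`
#' extracts the sample tables of one group; `dataset_records()` flattens the
#' dataset into one long tibble with `sample_id` and `group` columns.
#'
#' @param ds A `grouped_dataset`.
#' @param label A group label present in `ds`.
#' @return See individual descriptions.
#' @export
dataset_groups <- function(ds) unique(unname(ds$groups))

#' @rdname dataset_groups
#' @export
group_tables <- function(ds, label) {
  if (!label %in% ds$groups) stop("no group labeled '", label, "'", call. = FALSE)
  unname(ds$tables[names(ds$groups)[ds$groups == label]])
}

#' @rdname dataset_groups
#' @export
dataset_records <- function(ds) {
  dplyr::bind_rows(lapply(ds$tables, function(t) {
    tibble::as_tibble(t) |>
      dplyr::mutate(sample_id = sample_id(t), group = group_label(t))
  }))
}

#' Load a dataset from a manifest of peptide-table files
#'
#' The manifest is delimited text with columns `sample_id`, `group_label`
#' and `path` (one row per replicate file; repeated sample ids are read as
#' replicate injections and concatenated with
#' [concatenate_replicates()]). Relative paths are resolved against the
#' manifest's directory.
#'
#' @param manifest_path Path to the manifest file.
#' @param dialect Column dialect passed to [read_peptide_table()].
#' @return A [grouped_dataset()].
#' @export
load_dataset <- function(manifest_path, dialect = dialect_plain()) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- utils::read.table(manifest_path,
    header = TRUE, sep = detect_delimiter(manifest_path),
    stringsAsFactors = FALSE
  )
  need <- c("sample_id", "group_label", "path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  base <- dirname(manifest_path)
  tables <- lapply(split(man, man$sample_id), function(rows) {
    reps <- lapply(rows$path, function(p) {
      full <- if (file.exists(p)) p else file.path(base, p)
      read_peptide_table(full, rows$sample_id[1], dialect, rows$group_label[1])
    })
    concatenate_replicates(reps)
  })
  grouped_dataset(unname(tables))
}

#' Write a JSON run summary for a dataset
#'
#' Records the dataset's bookkeeping — samples, groups, per-sample peptide
#' and spectral-count totals before and after the cutoff, and the log of
#' modified-residue annotations stripped on ingest — so a run is auditable
#' from one file.
#'
#' @param ds A `grouped_dataset`.
#' @param path Output path for the JSON file.
#' @param cutoff Spectral-count cutoff recorded and applied (default 4).
#' @return `path`, invisibly.
#' @export
export_run_summary <- function(ds, path, cutoff = 4) {
  per_sample <- lapply(ds$tables, function(t) {
    stripped <- attr(t, "stripped")
    list(
      sample_id = sample_id(t),
      group = group_label(t),
      n_peptides = nrow(t),
      n_peptides_after_cutoff = nrow(apply_spectral_cutoff(t, cutoff)),
      total_spectral_count = total_spectral_count(t),
      n_stripped_annotations = if (is.null(stripped)) 0L else nrow(stripped),
      stripped = if (is.null(stripped) || nrow(stripped) == 0) NULL else stripped
    )
  })
  jsonlite::write_json(
    list(
      parameters = list(spectral_count_cutoff = cutoff),
      groups = as.list(table(ds$groups)),
      samples = unname(per_sample)
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Per-group summary of a peptidome dataset
#'
#' For each group: mean and standard deviation (N-1 denominator) of the
#' number of unique peptides per sample before and after the spectral-count
#' cutoff, the mean peptide length and mean monoisotopic mass (unweighted
#' over unique peptides, averaged across samples), and the mean fraction of
#' peptides at or above the cutoff.
#'
#' @param ds A `grouped_dataset`.
#' @param cutoff Spectral-count cutoff (default 4).
#' @return A tibble with one row per group. Groups with no samples yield
#'   `NA` statistics.
#' @export
summarize_dataset <- function(ds, cutoff = 4) {
  per_sample <- dplyr::bind_rows(lapply(ds$tables, function(t) {
    n_all <- nrow(t)
    kept <- apply_spectral_cutoff(t, cutoff)
    tibble::tibble(
      sample_id = sample_id(t),
      group = group_label(t),
      n_peptides = n_all,
      n_after_cutoff = nrow(kept),
      mean_length = if (n_all > 0) mean(nchar(t$sequence)) else NA_real_,
      mean_mass = if (n_all > 0) mean(peptide_mass(t$sequence)) else NA_real_,
      fraction_above_cutoff = if (n_all > 0) nrow(kept) / n_all else NA_real_
    )
  }))
  per_sample |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_peptides = mean(.data$n_peptides),
      sd_peptides = stats::sd(.data$n_peptides),
      mean_peptides_after_cutoff = mean(.data$n_after_cutoff),
      sd_peptides_after_cutoff = stats::sd(.data$n_after_cutoff),
      mean_length = mean(.data$mean_length, na.rm = TRUE),
      mean_mass = mean(.data$mean_mass, na.rm = TRUE),
      fraction_above_cutoff = mean(.data$fraction_above_cutoff, na.rm = TRUE),
      .groups = "drop"
    )
}
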