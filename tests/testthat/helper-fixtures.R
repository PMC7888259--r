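# Shared fixtures. The toy protein is the 37-residue hemoglobin-beta
# C-terminal region; NALAHKYH sits at its positions 30-37.
TOY_HBB <- "LVCVLAHHFGKEFTPPVQAAYQKVVAGVANALAHKYH"
TOY_HBB_NTERM <- "MVHLTPEEKSAVTALWGKVNV"

toy_table <- function(counts, sample_id = "s1", group = "g1") {
  sample_table(names(counts), unname(counts), sample_id = sample_id, group_label = group)
}

write_peptide_file <- function(df, sep = "\t") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

random_table <- function(n, sample_id = "s1", group = "g1", max_count = 12) {
  seqs <- unique(replicate(n, paste(sample(AA_ALPHABET, sample(5:12, 1), TRUE), collapse = "")))
  sample_table(seqs, sample.int(max_count, length(seqs), replace = TRUE),
    sample_id = sample_id, group_label = group
  )
}

# Independent occurrence oracle: position-by-position substring scan.
brute_force_locations <- function(peptide, protein) {
  k <- nchar(peptide)
  L <- nchar(protein)
  if (k > L) {
    return(integer())
  }
  starts <- seq_len(L - k + 1)
  starts[substring(protein, starts, starts + k - 1) == peptide]
}
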