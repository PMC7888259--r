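test_that("read_peptide_table merges duplicates, strips modifications, and validates", {
  path <- write_peptide_file(data.frame(
    sequence = c("VVAGVANALAHKYH", "NALAHKYH", "NALAHKYH"),
    spectral_count = c(4, 2, 3)
  ))
  tbl <- read_peptide_table(path, "s1")
  expect_s3_class(tbl, "sample_table")
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$spectral_count[tbl$sequence == "NALAHKYH"], 5)

  # header-only file -> empty table
  empty <- write_peptide_file(data.frame(sequence = character(), spectral_count = numeric()))
  expect_equal(nrow(read_peptide_table(empty, "s1")), 0)

  # modified residues stripped and logged
  mod <- write_peptide_file(data.frame(sequence = "N(+.98)ALAHKYH", spectral_count = 7))
  tbl <- read_peptide_table(mod, "s1")
  expect_equal(tbl$sequence, "NALAHKYH")
  expect_equal(tbl$spectral_count, 7)
  expect_equal(attr(tbl, "stripped")$raw, "N(+.98)ALAHKYH")

  # comma-delimited autodetection + PEAKS dialect
  peaks <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Peptide,#Spec,Accession", "K.NALAHKYH.A,6,HBB"), peaks)
  tbl <- read_peptide_table(peaks, "s1", dialect = dialect_peaks())
  expect_equal(tbl$sequence, "NALAHKYH")
  expect_equal(tbl$accessions, "HBB")

  # errors name the offending column / row
  expect_error(
    read_peptide_table(write_peptide_file(data.frame(seq = "AA", n = 1)), "s1"),
    "sequence"
  )
  bad <- write_peptide_file(data.frame(sequence = c("AAA", "CCC"), spectral_count = c("4", "x")))
  expect_error(read_peptide_table(bad, "s1"), "row 2")
})

test_that("peptide tables round-trip through write/read exactly", {
  tbl <- random_table(60)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(tbl, path)
  back <- read_peptide_table(path, sample_id(tbl))
  ord_b <- order(back$sequence)
  ord_t <- order(tbl$sequence)
  expect_equal(back$sequence[ord_b], tbl$sequence[ord_t])
  expect_equal(back$spectral_count[ord_b], tbl$spectral_count[ord_t])
})

test_that("read_fasta parses headers, preserves order, rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">HBB_TOY test protein", "LVCVLAHHFGK", ">FIBA_TOY", "ADSGEGDF", "LAEGGGVR"), path)
  db <- read_fasta(path)
  expect_equal(length(db), 2)
  expect_equal(names(db$seq), c("HBB_TOY", "FIBA_TOY"))
  expect_equal(nchar(db$seq[["HBB_TOY"]]), 11)
  expect_equal(db$seq[["FIBA_TOY"]], "ADSGEGDFLAEGGGVR") # wrapped lines joined
  expect_equal(db$desc[["HBB_TOY"]], "test protein")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">HBB_TOY", "AAA", ">HBB_TOY", "CCC"), dup)
  expect_error(read_fasta(dup), "HBB_TOY")

  # FASTA round-trip
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db, out)
  expect_equal(read_fasta(out)$seq, db$seq)
})

test_that("replicate concatenation sums per-sequence counts and conserves totals", {
  r1 <- toy_table(c(AAAA = 1))
  r2 <- sample_table(c("AAAA", "CCCC"), c(2, 4), sample_id = "s1", group_label = "g1")
  merged <- concatenate_replicates(list(r1, r2))
  expect_equal(sort(merged$sequence), c("AAAA", "CCCC"))
  expect_equal(merged$spectral_count[merged$sequence == "AAAA"], 3)
  expect_equal(total_spectral_count(merged), total_spectral_count(r1) + total_spectral_count(r2))

  # single input is the identity
  expect_equal(
    tibble::as_tibble(concatenate_replicates(list(r2))),
    tibble::as_tibble(r2)
  )

  # four replicates of {A:1} survive the >= 4 cutoff after concatenation
  reps <- replicate(4, sample_table("AAAA", 1, sample_id = "s1"), simplify = FALSE)
  merged <- concatenate_replicates(reps)
  expect_equal(merged$spectral_count, 4)
  expect_equal(nrow(apply_spectral_cutoff(merged, 4)), 1)

  expect_error(
    concatenate_replicates(list(r1, sample_table("AAAA", 1, sample_id = "s2"))),
    "mixed sample_ids"
  )
})

test_that("spectral cutoff retains exactly the records at or above the threshold", {
  tbl <- sample_table(c("AAAAA", "CCCCC", "DDDDD"), c(5, 4, 3), sample_id = "s1")
  kept <- apply_spectral_cutoff(tbl, 4)
  expect_setequal(kept$sequence, c("AAAAA", "CCCCC"))
  expect_equal(tibble::as_tibble(apply_spectral_cutoff(tbl, 0)), tibble::as_tibble(tbl))
  expect_error(apply_spectral_cutoff(tbl, -1), "non-negative")

  # brute-force agreement and filter monotonicity on random tables
  set.seed(11)
  for (i in 1:5) {
    tbl <- random_table(500, max_count = 10)
    expect_equal(nrow(apply_spectral_cutoff(tbl, 4)), sum(tbl$spectral_count >= 4))
    s2 <- apply_spectral_cutoff(tbl, 2)$sequence
    s6 <- apply_spectral_cutoff(tbl, 6)$sequence
    expect_true(all(s6 %in% s2))
  }
})

test_that("total_spectral_count sums counts and is 0 on empty tables", {
  expect_equal(total_spectral_count(sample_table(c("AAA", "CC"), c(5, 4), sample_id = "s")), 9)
  expect_equal(total_spectral_count(sample_table(character(), numeric(), sample_id = "s")), 0)
  tbl <- random_table(200)
  expect_equal(total_spectral_count(tbl), Reduce(`+`, as.list(tbl$spectral_count)))
})

test_that("dataset summary reproduces per-group statistics with N-1 variance", {
  t1 <- sample_table(c("AA", "CCC"), c(4, 4), sample_id = "s1", group_label = "g1")
  s <- summarize_dataset(grouped_dataset(list(t1)))
  expect_equal(s$mean_length, 2.5)
  expect_equal(s$mean_peptides_after_cutoff, 2)
  expect_equal(s$fraction_above_cutoff, 1)
  expect_equal(s$mean_mass, mean(peptide_mass(c("AA", "CCC"))))

  # sd across samples uses the N-1 denominator
  t2 <- sample_table(paste0(rep("A", 3), c("C", "D", "E")), c(9, 9, 9),
    sample_id = "s2", group_label = "g1"
  )
  t3 <- sample_table(c("AAC", "AAD", "AAE", "AAF", "AAG"), rep(9, 5),
    sample_id = "s3", group_label = "g1"
  )
  ds <- grouped_dataset(list(t2, t3))
  s <- summarize_dataset(ds)
  expect_equal(s$sd_peptides_after_cutoff, sd(c(3, 5)))
  expect_equal(s$mean_peptides_after_cutoff, 4)

  # full brute-force recomputation on a simulated multi-group dataset
  sim <- simulate_dataset(bundled_proteins(), digestion_model(n_peptides = 150),
    c(a = 2, b = 2),
    seed = 3
  )
  s <- summarize_dataset(sim$dataset, cutoff = 4)
  for (g in c("a", "b")) {
    tabs <- group_tables(sim$dataset, g)
    n_after <- vapply(tabs, function(t) sum(t$spectral_count >= 4), numeric(1))
    expect_equal(s$mean_peptides_after_cutoff[s$group == g], mean(n_after))
    expect_equal(s$sd_peptides[s$group == g], sd(vapply(tabs, nrow, integer(1))))
    expect_equal(
      s$mean_length[s$group == g],
      mean(vapply(tabs, function(t) mean(nchar(t$sequence)), numeric(1)))
    )
    expect_equal(
      s$fraction_above_cutoff[s$group == g],
      mean(n_after / vapply(tabs, nrow, integer(1)))
    )
  }
})

test_that("run summaries record counts, parameters and the stripping log", {
  mod <- write_peptide_file(data.frame(
    sequence = c("N(+.98)ALAHKYH", "AAAA"),
    spectral_count = c(7, 2)
  ))
  tbl <- read_peptide_table(mod, "s1", group_label = "g1")
  out <- withr::local_tempfile(fileext = ".json")
  export_run_summary(grouped_dataset(list(tbl)), out)
  j <- jsonlite::read_json(out)
  expect_equal(j$parameters$spectral_count_cutoff, 4)
  expect_equal(j$samples[[1]]$n_peptides, 2)
  expect_equal(j$samples[[1]]$n_peptides_after_cutoff, 1)
  expect_equal(j$samples[[1]]$total_spectral_count, 9)
  expect_equal(j$samples[[1]]$n_stripped_annotations, 1)
  expect_equal(j$samples[[1]]$stripped[[1]]$clean, "NALAHKYH")
})

test_that("manifest loading assigns groups and concatenates replicates", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "s1_rep1.tsv")
  f2 <- file.path(dir, "s1_rep2.tsv")
  f3 <- file.path(dir, "s2.tsv")
  utils::write.table(data.frame(sequence = "AAAA", spectral_count = 2), f1,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.table(data.frame(sequence = "AAAA", spectral_count = 3), f2,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.table(data.frame(sequence = "CCCC", spectral_count = 1), f3,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(
      sample_id = c("s1", "s1", "s2"),
      group_label = c("acute", "acute", "infected"),
      path = basename(c(f1, f2, f3))
    ),
    man,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  ds <- load_dataset(man)
  expect_setequal(dataset_groups(ds), c("acute", "infected"))
  s1 <- group_tables(ds, "acute")[[1]]
  expect_equal(s1$spectral_count, 5) # replicates concatenated by summing
})
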