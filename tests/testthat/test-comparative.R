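test_that("venn regions partition the union of the sets", {
  v <- venn_counts(list(S1 = c("A", "B"), S2 = c("B", "C")))
  expect_equal(v$count[v$region == "S1"], 1L)
  expect_equal(v$count[v$region == "S2"], 1L)
  expect_equal(v$count[v$region == "S1&S2"], 1L)
  expect_equal(sum(v$count), attr(v, "union_size"))

  # identical sets put all mass in the full intersection
  v <- venn_counts(list(a = c("X", "Y"), b = c("X", "Y"), c = c("X", "Y")))
  expect_equal(v$count[v$region == "a&b&c"], 2L)
  expect_equal(sum(v$count), 2L)

  expect_error(venn_counts(list(a = "X")), "between 2 and 5")
  expect_error(venn_counts(list(rep(list(c("X")), 6))[[1]]), "between 2 and 5")
})

test_that("intersectional peptides are the sequences common to every sample", {
  s1 <- toy_table(c(AAAA = 1, CCCC = 2))
  s2 <- sample_table(c("CCCC", "DDDD"), c(1, 1), sample_id = "s2", group_label = "g1")
  s3 <- sample_table("CCCC", 5, sample_id = "s3", group_label = "g1")
  expect_equal(intersectional_peptides(list(s1, s2, s3)), "CCCC")
  expect_equal(intersectional_peptides(list(s1)), sort(s1$sequence))

  # adding a sample never grows the intersection
  set.seed(21)
  tabs <- lapply(1:4, function(i) random_table(100, sample_id = paste0("s", i)))
  for (k in 2:4) {
    expect_true(all(
      intersectional_peptides(tabs[1:k]) %in% intersectional_peptides(tabs[1:(k - 1)])
    ))
  }
})

test_that("differential peptides rank by absolute count difference", {
  a1 <- sample_table(c("MMMM", "YYYY"), c(6, 1), sample_id = "a1", group_label = "A")
  a2 <- sample_table(c("MMMM", "YYYY"), c(4, 1), sample_id = "a2", group_label = "A")
  b1 <- sample_table("MMMM", 1, sample_id = "b1", group_label = "B")
  b2 <- sample_table("MMMM", 1, sample_id = "b2", group_label = "B")
  d <- differential_peptides(list(a1, a2), list(b1, b2))
  x <- d[d$sequence == "MMMM", ]
  expect_equal(x$difference, 8) # 10 in A minus 2 in B
  expect_equal(x$rank, 1L)
  # YYYY is in A's core only: difference equals its full A total
  expect_equal(d$difference[d$sequence == "YYYY"], 2)

  # absent-from-B core peptide gets +total
  d <- differential_peptides(list(a1, a2), list())
  expect_equal(d$difference[d$sequence == "MMMM"], 10)

  # permutation invariance within groups
  d1 <- differential_peptides(list(a1, a2), list(b1, b2))
  d2 <- differential_peptides(list(a2, a1), list(b2, b1))
  expect_equal(d1, d2)

  # k truncation keeps the largest |difference|
  d <- differential_peptides(list(a1, a2), list(b1, b2), k = 1)
  expect_equal(d$sequence, "MMMM")
})

test_that("substrate abundance sums counts per protein with exclusions", {
  db <- protein_db(c(P1 = "AAAACCCC", P2 = "DDDDEEEE", P3 = "AAAADDDD"))
  tbl <- sample_table(
    c("AAAAC", "DDDDE", "AAAAD"),
    c(6, 4, 10),
    sample_id = "s1", group_label = "g1"
  )
  m <- map_dataset(grouped_dataset(list(tbl)), db)
  ab <- protein_substrate_abundance(m)
  expect_equal(ab$total[ab$accession == "P1"], 6)
  expect_equal(ab$total[ab$accession == "P3"], 10)
  expect_equal(sum(ab$share), 1)
  expect_equal(attr(ab, "n_proteins")$n_proteins, 3)

  ab2 <- protein_substrate_abundance(m, exclude_accessions = c("P1", "P3"))
  expect_equal(ab2$share[ab2$accession == "P2"], 1)

  # ambiguous peptide counts once per distinct accession, reported as double-counting
  tbl <- sample_table("AAAA", 5, sample_id = "s1", group_label = "g1")
  m <- map_dataset(grouped_dataset(list(tbl)), db, policy = "all_locations")
  ab <- protein_substrate_abundance(m)
  expect_equal(ab$total[ab$accession == "P1"], 5)
  expect_equal(ab$total[ab$accession == "P3"], 5)
  expect_equal(attr(ab, "double_counted"), 5)
})

test_that("top-n pie data pools everything below the cut into 'other'", {
  db <- protein_db(setNames(
    vapply(1:4, function(i) paste(rep(AA_ALPHABET[i], 10), collapse = ""), character(1)),
    paste0("P", 1:4)
  ))
  tbl <- sample_table(
    vapply(1:4, function(i) paste(rep(AA_ALPHABET[i], 5), collapse = ""), character(1)),
    c(10, 5, 3, 2),
    sample_id = "s1", group_label = "g1"
  )
  pie <- substrate_pie_data(
    protein_substrate_abundance(map_dataset(grouped_dataset(list(tbl)), db)),
    top_n = 2
  )
  expect_equal(pie$total[pie$accession == "other"], 5)
  expect_equal(sum(pie$share), 1)
})

test_that("occurrence outliers flag single-sample high-count sequences", {
  tabs <- list(
    sample_table(c("AAAA", "CCCC"), c(500, 10), sample_id = "s1", group_label = "g"),
    sample_table("CCCC", 12, sample_id = "s2", group_label = "g"),
    sample_table("CCCC", 9, sample_id = "s3", group_label = "g")
  )
  oo <- occurrence_outliers(tabs, count_quantile = 0.5)
  expect_true(oo$flagged[oo$sequence == "AAAA"])
  expect_false(oo$flagged[oo$sequence == "CCCC"]) # present in all samples

  # flags equal a brute-force filter on random data
  set.seed(33)
  tabs <- lapply(1:3, function(i) random_table(150, sample_id = paste0("s", i), max_count = 30))
  oo <- occurrence_outliers(tabs, count_quantile = 0.9)
  pooled <- dplyr::bind_rows(lapply(tabs, tibble::as_tibble), .id = "tab")
  manual <- sapply(oo$sequence, function(s) {
    rows <- pooled[pooled$sequence == s, ]
    nrow(rows) == 1 && sum(rows$spectral_count) > quantile(oo$total, 0.9, names = FALSE)
  })
  expect_equal(oo$flagged, unname(manual))
})

test_that("group-mean comparisons match the closed-form t distribution", {
  r <- compare_group_means(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # paired comparison with constant shift is degenerate, not an error
  r <- compare_group_means(c(1, 2, 4), c(3, 4, 6), paired = TRUE)
  expect_true(r$degenerate)
  expect_true(is.na(r$p))
  expect_equal(r$mean_a - r$mean_b, -2)

  expect_error(compare_group_means(1, c(1, 2)), "at least 2")

  # closed-form oracle: Welch, pooled and paired variants to 1e-10
  set.seed(77)
  for (i in 1:40) {
    a <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    va <- var(a) / length(a)
    vb <- var(b) / length(b)
    t_welch <- (mean(a) - mean(b)) / sqrt(va + vb)
    df_welch <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    r <- compare_group_means(a, b)
    expect_equal(r$t, t_welch, tolerance = 1e-10)
    expect_equal(r$p, 2 * pt(-abs(t_welch), df_welch), tolerance = 1e-10)

    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t_pool <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    r <- compare_group_means(a, b, var_equal = TRUE)
    expect_equal(r$t, t_pool, tolerance = 1e-10)
    expect_equal(r$p, 2 * pt(-abs(t_pool), length(a) + length(b) - 2), tolerance = 1e-10)

    b2 <- rnorm(length(a))
    d <- a - b2
    t_paired <- mean(d) / (sd(d) / sqrt(length(d)))
    r <- compare_group_means(a, b2, paired = TRUE)
    expect_equal(r$t, t_paired, tolerance = 1e-10)
    expect_equal(r$p, 2 * pt(-abs(t_paired), length(d) - 1), tolerance = 1e-10)
  }
})

test_that("protease attribution matches cleavage-site residues against rules", {
  db <- protein_db(c(P = "MKAAAKDEEEGRFFFF"))
  # peptide AAAK: preceding K (N-side trypsin-like), ends K (C-side trypsin-like)
  # peptide DEEE: preceding D? sequence: M K A A A K D E E E G R F F F F
  tbl <- sample_table(c("AAAK", "EEEG"), c(1, 1), sample_id = "s1", group_label = "g1")
  cr <- cleavage_site_records(map_dataset(grouped_dataset(list(tbl)), db))
  pt <- protease_table(
    trypsin_like = list(p1 = c("K", "R")),
    glu_c_like = list(p1 = c("D", "E"))
  )
  at <- attribute_proteases(cr, pt)
  # AAAK: N-side P1 = K, C-side P1 = K -> 2 trypsin-like events
  expect_equal(at$n_events[at$protease == "trypsin_like"], 2)
  # EEEG: N-side P1 = E, C-side P1 = G -> 1 glu-C event
  expect_equal(at$n_events[at$protease == "glu_c_like"], 1)

  # P1' restriction filters events
  pt2 <- protease_table(picky = list(p1 = "K", p1_prime = "Z"))
  expect_equal(attribute_proteases(cr, pt2)$n_events, 0)

  expect_error(protease_table(), "empty")
  expect_error(protease_table(x = list(p1 = character())), "at least one")
})
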