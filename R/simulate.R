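# In-silico proteolysis simulator with recorded ground truth.
#
# The generative model mirrors how an endogenous peptidome arises:
# endoproteases cut substrate proteins at sites whose propensity depends on
# the P1 residue (the residue N-terminal of the scissile bond), and
# exopeptidases then trim the fragment ends, producing nested peptide
# ladders. Spectral counts are overdispersed integers (zero-truncated
# negative binomial). Every emitted peptide records its true origin, so the
# whole analysis pipeline can be validated against planted ground truth.

#' Specify a digestion model
#'
#' @param p1_weights Named non-negative cleavage propensities per residue;
#'   cut-site P1 residues are drawn from this distribution (default
#'   uniform over the 20 residues). At least one weight must be positive.
#' @param exo_trim_prob Geometric exopeptidase-trimming parameter in
#'   `[0, 1)` applied independently to each peptide end: each end loses
#'   `k` residues with probability `(1-q) q^k`. 0 disables trimming.
#' @param length_bounds Retained peptide length range (min >= 4 so that
#'   terminal tetrapeptides exist; default `c(5, 35)`).
#' @param abundance_mean,abundance_dispersion Negative-binomial mean and
#'   size for spectral counts, zero-truncated on draw. The defaults
#'   (1.0, 0.5) put roughly a quarter of observed peptides at or above the
#'   conventional spectral-count cutoff of 4.
#' @param substrate_weights Named relative substrate abundances per
#'   accession (default: equal across the database).
#' @param core_fraction Fraction of a group's peptide pool forced into
#'   every sample of the group (the planted reproducible core).
#' @param core_min_count Spectral-count floor for forced core occurrences
#'   (default 4, so planted cores survive the conventional cutoff).
#' @param n_peptides Target number of emitted peptides per sample.
#' @param mean_fragment_length Expected fragment length between successive
#'   cuts (controls cut density; default 11 residues, which yields mean
#'   peptide lengths in the 12-14 residue range typical of endogenous
#'   peptidomes).
#' @param hotspots List of planted hotspots; use [plant_hotspot()].
#' @return Object of class `digestion_model`.
#' @export
digestion_model <- function(p1_weights = NULL,
                            exo_trim_prob = 0.1,
                            length_bounds = c(5, 35),
                            abundance_mean = 1.0,
                            abundance_dispersion = 0.5,
                            substrate_weights = NULL,
                            core_fraction = 0.06,
                            core_min_count = 4,
                            n_peptides = 1200,
                            mean_fragment_length = 11,
                            hotspots = list()) {
  if (is.null(p1_weights)) {
    p1_weights <- stats::setNames(rep(1, 20), AA_ALPHABET)
  }
  if (any(p1_weights < 0) || sum(p1_weights) <= 0) {
    stop("p1_weights must be non-negative with at least one positive entry",
      call. = FALSE
    )
  }
  if (exo_trim_prob < 0 || exo_trim_prob >= 1) {
    stop("exo_trim_prob must be in [0, 1)", call. = FALSE)
  }
  if (length_bounds[1] < 4) {
    stop("minimum retained length must be >= 4 (terminal tetrapeptides)", call. = FALSE)
  }
  if (length_bounds[2] < length_bounds[1]) stop("invalid length_bounds", call. = FALSE)
  if (abundance_mean <= 0) stop("abundance_mean must be > 0", call. = FALSE)
  structure(
    list(
      p1_weights = p1_weights[p1_weights > 0],
      exo_trim_prob = exo_trim_prob,
      length_bounds = as.integer(length_bounds),
      abundance_mean = abundance_mean,
      abundance_dispersion = abundance_dispersion,
      substrate_weights = substrate_weights,
      core_fraction = core_fraction,
      core_min_count = core_min_count,
      n_peptides = n_peptides,
      mean_fragment_length = mean_fragment_length,
      hotspots = hotspots
    ),
    class = "digestion_model"
  )
}

#' Plant an abundance hotspot in a digestion model
#'
#' Fragments confined within the region get their spectral-count mean
#' multiplied by `enrichment`, emulating a group-specific surge of peptides
#' from one protein region.
#'
#' @param model A [digestion_model()].
#' @param region A [region_spec()].
#' @param enrichment Multiplier >= 1 (1 leaves the model unchanged).
#' @param db Optional [protein_db()]; when given, the region is validated
#'   against it.
#' @return The modified model.
#' @export
plant_hotspot <- function(model, region, enrichment, db = NULL) {
  stopifnot(inherits(model, "digestion_model"), inherits(region, "region_spec"))
  if (enrichment < 1) stop("enrichment must be >= 1", call. = FALSE)
  if (!is.null(db)) {
    region <- region_spec(region$accession, region$start, region$end,
      region$label, region$reference_peptides,
      db = db
    )
  }
  if (enrichment == 1) {
    return(model)
  }
  model$hotspots <- c(model$hotspots, list(list(region = region, enrichment = enrichment)))
  model
}

#' Bundled synthetic protein database
#'
#' A small, byte-identical-across-runs protein database for simulation and
#' testing: two synthetic proteins embedding well-known peptidome regions
#' (a hemoglobin-beta-like protein whose C-terminal residues 112-148 are
#' the classic antimicrobial region ending in ...NALAHKYH, and a
#' fibrinogen-alpha-like protein carrying fibrinopeptide A at residues
#' 20-35), plus four pseudo-random filler proteins drawn from whole-
#' proteome residue frequencies. All accessions carry the `_SYN` suffix:
#' these are synthetic stand-ins, not the real human proteins.
#'
#' @return A [protein_db()].
#' @examples
#' grepl("NALAHKYH", bundled_proteins()$seq[["HBB_SYN"]])
#' @export
bundled_proteins <- function() {
  hbb_nterm <- "MVHLTPEEKSAVTALWGKVNV"
  hbb_cterm <- "LVCVLAHHFGKEFTPPVQAAYQKVVAGVANALAHKYH"
  fpa <- "ADSGEGDFLAEGGGVR"
  withr::with_seed(20413, {
    rand_seq <- function(n) {
      paste(sample(AA_ALPHABET, n,
        replace = TRUE,
        prob = SWISSPROT_FREQ_PCT[AA_ALPHABET]
      ), collapse = "")
    }
    seqs <- c(
      HBB_SYN = paste0(hbb_nterm, rand_seq(90), hbb_cterm), # region at 112-148
      FIBA_SYN = paste0(rand_seq(19), fpa, rand_seq(550)), # fibrinopeptide A at 20-35
      ALB_SYN = rand_seq(585),
      A2M_SYN = rand_seq(450),
      TRFE_SYN = rand_seq(380),
      APOA_SYN = rand_seq(260)
    )
  })
  protein_db(seqs, stats::setNames(
    c(
      "synthetic hemoglobin-subunit-beta-like protein",
      "synthetic fibrinogen-alpha-like protein",
      "synthetic filler protein 1", "synthetic filler protein 2",
      "synthetic filler protein 3", "synthetic filler protein 4"
    ),
    names(seqs)
  ))
}

# Zero-truncated negative binomial draws (observed peptides have >= 1
# matched spectrum).
ztnb <- function(n, mu, size) {
  if (n == 0) {
    return(integer())
  }
  p0 <- stats::dnbinom(0, size = size, mu = mu)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(u, size = size, mu = mu)
}

# One endoproteolytic digest pass of a protein: sample cut sites so that
# the P1 residues of the cuts follow the planted propensity distribution,
# then form fragments between successive cuts.
digest_once <- function(prot, model) {
  L <- nchar(prot)
  n_cuts <- max(1L, round((L - 1) / model$mean_fragment_length))
  residues <- strsplit(substr(prot, 1, L - 1), "", fixed = TRUE)[[1]]
  avail <- split(seq_len(L - 1), residues)
  avail <- avail[names(avail) %in% names(model$p1_weights)]
  cuts <- integer(0)
  for (k in seq_len(n_cuts)) {
    pool <- names(avail)[vapply(avail, length, integer(1)) > 0]
    if (length(pool) == 0) break
    w <- model$p1_weights[pool]
    r <- sample(pool, 1, prob = w)
    j <- if (length(avail[[r]]) == 1L) avail[[r]] else sample(avail[[r]], 1)
    avail[[r]] <- setdiff(avail[[r]], j)
    cuts <- c(cuts, j)
  }
  cuts <- sort(cuts)
  tibble::tibble(start = c(1L, cuts + 1L), end = c(cuts, L))
}

# Geometric exo-trimming of fragment ends, capped so length >= min bound.
trim_fragments <- function(frags, model) {
  q <- model$exo_trim_prob
  n <- nrow(frags)
  if (q > 0 && n > 0) {
    tn <- stats::rgeom(n, 1 - q)
    tc <- stats::rgeom(n, 1 - q)
    len <- frags$end - frags$start + 1L
    tn <- pmin(tn, pmax(0L, len - model$length_bounds[1]))
    tc <- pmin(tc, pmax(0L, len - tn - model$length_bounds[1]))
    frags$start <- frags$start + as.integer(tn)
    frags$end <- frags$end - as.integer(tc)
  }
  len <- frags$end - frags$start + 1L
  frags[len >= model$length_bounds[1] & len <= model$length_bounds[2], , drop = FALSE]
}

in_hotspot <- function(frags, accession, model) {
  boost <- rep(1, nrow(frags))
  for (h in model$hotspots) {
    if (h$region$accession == accession) {
      inside <- frags$start >= h$region$start & frags$end <= h$region$end
      boost[inside] <- boost[inside] * h$enrichment
    }
  }
  boost
}

generate_sample <- function(db, model, sample_id, group, subseed) {
  withr::with_seed(subseed, {
    weights <- model$substrate_weights
    if (is.null(weights)) {
      weights <- stats::setNames(rep(1, length(db$seq)), names(db$seq))
    }
    weights <- weights[names(weights) %in% names(db$seq)]
    weights <- weights / sum(weights)
    targets <- round(model$n_peptides * weights)
    parts <- lapply(names(targets), function(acc) {
      prot <- db$seq[[acc]]
      got <- list()
      n_got <- 0L
      guard <- 0L
      while (n_got < targets[[acc]] && guard < 1000L) {
        guard <- guard + 1L
        frags <- trim_fragments(digest_once(prot, model), model)
        if (nrow(frags) == 0) next
        got[[length(got) + 1L]] <- frags
        n_got <- n_got + nrow(frags)
      }
      if (length(got) == 0) {
        return(NULL)
      }
      frags <- dplyr::bind_rows(got)
      if (nrow(frags) > targets[[acc]]) frags <- frags[seq_len(targets[[acc]]), , drop = FALSE]
      frags$accession <- acc
      frags$sequence <- substr(rep(prot, nrow(frags)), frags$start, frags$end)
      mu <- model$abundance_mean * in_hotspot(frags, acc, model)
      frags$spectral_count <- ztnb(nrow(frags), mu, model$abundance_dispersion)
      frags
    })
    frags <- dplyr::bind_rows(parts)
    if (nrow(frags) == 0) {
      stop("digestion produced no fragments within length_bounds", call. = FALSE)
    }
    # SampleTable semantics: unique sequences, counts summed, first origin kept
    frags |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(
        spectral_count = sum(.data$spectral_count),
        accession = .data$accession[1],
        start = .data$start[1],
        end = .data$end[1],
        .groups = "drop"
      ) |>
      dplyr::mutate(sample_id = sample_id, group = group)
  })
}

derive_seed <- function(seed, group_index, sample_index) {
  (abs(seed) %% 100000L) * 10007L + group_index * 1009L + sample_index
}

#' Simulate a grouped peptidome dataset with known ground truth
#'
#' Per sample: substrate proteins are digested in-silico (cut-site P1
#' residues drawn from the model's planted propensities), fragments are
#' exo-trimmed and length-filtered, and spectral counts drawn from a
#' zero-truncated negative binomial (hotspot regions get boosted means).
#' Per group, a planted core (a `core_fraction` of the group's peptide
#' pool) is then forced into every sample at a spectral count of at least
#' `core_min_count`, and the generator guarantees that in groups with at
#' least two samples no other sequence is ubiquitous — the planted core is
#' exactly the group's intersectional set. One global seed fans out
#' deterministically to per-sample streams, so adding a sample or a group
#' leaves earlier samples unchanged.
#'
#' @param db A [protein_db()], e.g. [bundled_proteins()].
#' @param models A single [digestion_model()] used for every group, or a
#'   named list group_label -> model.
#' @param n_samples Named integer vector group_label -> number of samples.
#' @param seed Integer seed.
#' @return List with elements `dataset` (a [grouped_dataset()]; emitted
#'   tables carry the true origin accession in `accessions`) and `truth`
#'   (class `ground_truth`: planted P1 distribution, substrate shares,
#'   core sets, hotspots, and per-peptide true origins).
#' @export
simulate_dataset <- function(db, models, n_samples, seed = 1) {
  stopifnot(!is.null(names(n_samples)), all(n_samples >= 1))
  groups <- names(n_samples)
  if (inherits(models, "digestion_model")) {
    models <- stats::setNames(rep(list(models), length(groups)), groups)
  }
  stopifnot(all(groups %in% names(models)))

  tables <- list()
  origins <- list()
  core_sets <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    model <- models[[g]]
    samples <- lapply(seq_len(n_samples[[g]]), function(j) {
      generate_sample(
        db, model, sprintf("%s_s%d", g, j), g,
        derive_seed(seed, gi, j)
      )
    })
    # plant the group core and enforce its exactness
    withr::with_seed(derive_seed(seed, gi, 0L), {
      pool <- dplyr::bind_rows(samples) |>
        dplyr::group_by(.data$sequence) |>
        dplyr::summarise(
          spectral_count = sum(.data$spectral_count),
          accession = .data$accession[1],
          start = .data$start[1], end = .data$end[1],
          .groups = "drop"
        )
      n_core <- round(model$core_fraction * nrow(pool))
      # reproducibly detected peptides are the abundant ones: sample the
      # planted core proportional to pooled spectral count
      core <- sort(sample(pool$sequence, n_core, prob = pool$spectral_count))
      core_info <- pool[match(core, pool$sequence), , drop = FALSE]
      samples <- lapply(samples, function(s) {
        absent <- setdiff(core, s$sequence)
        if (length(absent) > 0) {
          add <- core_info[match(absent, core_info$sequence), , drop = FALSE]
          add$spectral_count <- pmax(
            ztnb(length(absent), model$abundance_mean, model$abundance_dispersion),
            model$core_min_count
          )
          add$sample_id <- s$sample_id[1]
          add$group <- g
          s <- dplyr::bind_rows(s, add)
        }
        low <- s$sequence %in% core & s$spectral_count < model$core_min_count
        s$spectral_count[low] <- model$core_min_count
        s
      })
      if (length(samples) >= 2) {
        ubiquitous <- Reduce(intersect, lapply(samples, `[[`, "sequence"))
        stray <- setdiff(ubiquitous, core)
        if (length(stray) > 0) {
          last <- length(samples)
          samples[[last]] <- samples[[last]][!samples[[last]]$sequence %in% stray, , drop = FALSE]
        }
      }
    })
    core_sets[[g]] <- core
    origins[[g]] <- dplyr::bind_rows(samples) |>
      dplyr::distinct(.data$sequence, .data$accession, .data$start, .data$end)
    tables <- c(tables, lapply(samples, function(s) {
      sample_table(s$sequence, s$spectral_count, s$accession,
        sample_id = s$sample_id[1], group_label = g
      )
    }))
  }

  truth <- structure(
    list(
      p1_weights = lapply(models[groups], function(m) m$p1_weights / sum(m$p1_weights)),
      substrate_shares = lapply(models[groups], function(m) {
        w <- m$substrate_weights
        if (is.null(w)) w <- stats::setNames(rep(1, length(db$seq)), names(db$seq))
        w / sum(w)
      }),
      core = core_sets,
      hotspots = lapply(models[groups], `[[`, "hotspots"),
      origins = dplyr::bind_rows(origins) |> dplyr::distinct()
    ),
    class = "ground_truth"
  )
  list(dataset = grouped_dataset(tables), truth = truth)
}
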