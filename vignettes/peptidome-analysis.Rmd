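---
title: "Profiling endogenous peptidomes with spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling endogenous peptidomes with spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptidomics)
```

## The analytical model

An endogenous peptidome is the set of peptides present in a body fluid
before any in vitro digestion. Each peptide is the joint product of two
processes: an endoprotease cleaving a substrate protein (creating the
peptide's original termini) and exopeptidases trimming those termini
(creating nested "ladders" of shorter forms). The analyses in this package
all follow from that picture.

**Quantification.** Abundance is the spectral count: the number of MS/MS
spectra matched to a peptide in a sample. Spectral counting is
semi-quantitative — it compares *different* peptides only approximately —
but it is robust for low-abundance species and supports a simple
false-positive filter: identifications carried by fewer than 4 spectra are
discarded (`apply_spectral_cutoff()`, default `min_count = 4`). Replicate
injections of the same sample are concatenated by summing per-sequence
counts before any filtering, and duplicate rows in input tables are merged
the same way; summation is the only table-level operation consistent with
pooling the underlying spectra.

**Localization and cleavage sites.** Every peptide is located exactly
(substring matching, all overlapping occurrences) in its parent protein;
coordinates are 1-based inclusive. The per-peptide simplification of
cleavage-site nomenclature is used throughout: the peptide's last residue is
the P1 of the C-side cleavage, its first residue the P1′ of the N-side
cleavage, and the residues flanking the peptide in the protein supply the
complementary positions. A peptide end that coincides with the parent
protein's own terminus was not created by a protease, so such ends are
excluded from P1/P1′ statistics. Two policies matter here:

* *Initiator methionine* (`met_tolerant`, default `TRUE`): a peptide
  starting at position 2 of a Met-initiated protein is treated as
  protein-N-terminal, because the mature protein commonly lacks the
  initiator Met and no cleavage event separates such a peptide from the
  protein start. With databases of mature sequences the flag is harmless
  (position 1 is not Met).
* *Ambiguity*: a peptide matching several proteins contributes its P1/P1′
  residues once, not once per location — the spectral count is a property of
  the peptide, not of a placement. For substrate abundance the opposite
  convention is used (full count to every distinct parent), mirroring how
  homologous subunits are tallied separately and then excluded jointly; the
  double-counted mass is reported so the user can see the size of the
  effect. Isoleucine and leucine are kept distinct: the package analyses
  sequences exactly as the search engine exported them.

**Composition profiles.** Residue frequencies are weighted by spectral
count (each residue contributes its occurrences × the peptide's count), so
profiles describe the peptide *population*, not the list of unique
sequences. P1/P1′ profiles weight the single cleavage-site residue by the
count. Profiles can be collapsed by side-chain class; the default grouping
is acidic {D, E}, basic {K, R, H}, polar uncharged {S, T, N, Q, C, Y},
nonpolar {G, A, V, L, I, P, M, F, W}. Conventions differ (H is sometimes
polar, C sometimes nonpolar), so any residue → class map can be supplied.
The bundled whole-Swiss-Prot residue frequencies serve as the background a
peptidome profile is compared against.

**Terminal tetrapeptides.** The 4 proximal residues of each end (the MEROPS
convention) are aggregated by summed spectral count. Protein-inherent
termini are deliberately *kept* here — unlike in P1/P1′ profiles — because
intact protein termini carried into the peptidome are themselves of
diagnostic interest. Peptides shorter than 4 residues cannot contribute a
tetrapeptide and are excluded with a count (never padded). Group statistics
(mean ± sd across samples, absent terminals counted as 0) use the N−1
denominator, and rank-abundance orderings break ties lexicographically so
output is deterministic.

**Group comparisons.** Intersectional (core) peptides are those present in
every sample of a group after filtering. Differential peptides are drawn
from the union of the two groups' cores — restricting to cores keeps only
reproducibly observed sequences, while the union retains group-exclusive
markers — ranked by the absolute difference of summed spectral counts
(mean available as an option), ties again lexicographic. The t-test wrapper
defaults to Welch's unpaired test: clinical groups are typically unequal in
size and there is no natural pairing across patients; the paired variant is
available where a pairing exists. Zero-variance degenerate inputs are
reported with a flag rather than an error, and no multiplicity correction
is applied (single planned comparisons are the intended use).

**Protease attribution.** Each cleavage-derived peptide end is one event;
an event is attributed to every protease class whose allowed P1 (and,
optionally, P1′) residues contain the event's residues. This is an
intentionally transparent, deterministic stand-in for database-driven
protease prediction: it captures first-order specificity (trypsin-like K/R,
glutamyl-endopeptidase-like D/E, chymotrypsin-like aromatic/bulky) and
nothing else.

**Antimicrobial scoring.** Per-peptide prediction scores in [0, 1] are
consumed from a file; peptides below the prediction cutoff (default 0.7,
boundary kept: score ≥ 0.7 survives) are discarded, and the antimicrobial
score is `prediction × spectral_count`, summarizing the peptide's expected
contribution to the sample's antimicrobial milieu. Peptides longer than 30
residues fall outside the domain of short-AMP predictors and are excluded
with a report. When no score file is available, `builtin_amp_score()`
provides a frozen logistic heuristic of cationicity
(`z = #K + #R + 0.5·#H − #D − #E`) and hydrophobic fraction
(`h`, over A/I/L/M/F/W/V/C): `score = plogis(0.5·z + 4·h − 3)`. The two
coefficients and the offset were fixed once so that strongly cationic,
amphipathic-composition peptides score high and acidic peptides score near
0; the function is a plumbing stand-in for running the pipeline end to end
and makes no claim of agreement with any trained predictor.

**Coverage and regions.** Coverage profiles give, per residue position, the
number of distinct covering peptides and their summed spectral count
(group aggregation averages per-sample mass over the group's samples).
Region sums default to *confined* counting (peptide entirely inside the
region); *overlapping* counting is available and always ≥ the confined sum.
Region totals default to summation across a group's samples, with a mean
option. Literature cross-matching is exact-substring only, in both
directions (dataset peptide contained in a reference or containing it);
similarity scoring is out of scope.

## The synthetic-data generator

`simulate_dataset()` emulates the generative process so that every analysis
stage can be validated against known ground truth:

1. substrate proteins are chosen by relative weight;
2. cut sites are placed so that the P1 residues of the cuts follow the
   model's planted propensity distribution (a residue class is drawn from
   the propensities, then a concrete site of that class uniformly);
3. fragments between successive cuts are exo-trimmed (geometric per end,
   parameter `exo_trim_prob`) and length-filtered;
4. spectral counts are drawn from a zero-truncated negative binomial
   (observed peptides have ≥ 1 spectrum; truncation preserves
   overdispersion);
5. a planted core — a fraction of the group's pooled sequences, sampled
   with probability proportional to pooled spectral count, since
   reproducibly detected peptides are the abundant ones — is forced into
   every sample of the group at a count of at least `core_min_count`, and
   accidentally ubiquitous non-core sequences are removed from one sample,
   so the planted core is *exactly* the group's intersectional set (groups
   of ≥ 2 samples).

One global seed fans out deterministically to per-sample streams; adding a
sample or group never perturbs earlier ones, and identical seeds reproduce
the dataset byte for byte.

Default parameters were set once to the characteristics typical of wound-
fluid peptidomes: `mean_fragment_length = 11` residues (realized mean
peptide length ≈ 13), negative-binomial mean 1.0 and size 0.5 (roughly a
quarter to a third of observed peptides at or above the count-4 cutoff),
`core_fraction = 0.06` (intersectional sets are a small minority of a
group's peptides), `length_bounds = c(5, 35)` with the minimum ≥ 4 so every
peptide has terminal tetrapeptides, and `exo_trim_prob = 0.1` for light
trimming ladders.

Two interactions deserve explicit mention:

* *Trimming vs P1 recovery.* Exo-trimming replaces a cleavage-derived
  terminus with a trimmed one, so any nonzero trimming dilutes a planted P1
  preference with background composition — that is a property of the
  biology being modeled, not an estimation error. Recovery experiments that
  quantify how faithfully the P1 profile reflects endoproteolytic
  specificity therefore run with `exo_trim_prob = 0`.
* *Core sampling vs composition.* Because sample tables are unique by
  sequence, recurrent fragments collapse into single rows with summed
  counts. Sampling the planted core uniformly over unique sequences would
  re-weight the peptidome toward the deduplicated composition; sampling
  proportional to pooled counts keeps the planted composition intact and is
  also the biologically sensible choice.

What the generator does **not** emulate: retention times, charge states and
spectra (there is no spectrum-level FDR to model), missed-cleavage
chemistry beyond the P1 propensity model, post-translational modifications,
shared peptides between homologous substrate proteins (filler proteins are
random, so cross-protein ambiguity is rare rather than structural), and
patient-to-patient biological variance beyond sampling noise. Passing the
recovery suite therefore demonstrates the *correctness of the
computations*, not that real wound-fluid data will show any particular
effect.

## Numerical and degenerate-input choices

* All profile normalizations are exact sums; profiles with zero total
  weight return all-`NA` with a warning instead of dividing by zero.
* Duplicate prediction scores must agree within 1e-9; conflicting
  duplicates are an error (silent averaging would hide upstream problems).
* Standard deviations use the N−1 denominator everywhere.
* Sorting ties (differential peptides, rank abundance, substrate ranking)
  break lexicographically so every output is reproducible.
* Sequences are validated against the 20-letter alphabet; protein databases
  tolerate X/B/Z/U with a warning flag, peptide tables do not (search
  engines emit defined residues; modified-residue annotations are stripped,
  and every stripped sequence is logged in the table's `stripped`
  attribute).
* Empty groups, empty reference lists and unmappable peptides yield empty
  or flagged results, never silent drops: unmapped records and missing
  declared accessions are returned as reports alongside the mapped data.

## Known limitations

* Mapping is exact; peptides with sequence variants or residues outside the
  database simply do not map (they remain visible in the unmapped report).
* Protease attribution is presence/absence over one or two subsite
  positions; it cannot separate proteases with overlapping P1 sets.
* The built-in antimicrobial scorer is a two-feature heuristic; analyses
  that depend on the absolute AMP score should use externally computed
  predictions.
* Venn region *counts* are computed exactly for 2–5 sets, but the package
  does not draw diagrams; counts are returned in plotting-ready form.
* Spectral counting compares peptides approximately; intensity-based
  quantification, where available, is preferable for ratios between
  identical peptides across samples and is outside this package's scope.
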