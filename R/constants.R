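# Residue-level constants shared across the package.

#' The 20 standard amino acids
#'
#' One-letter codes of the twenty proteinogenic amino acids, the alphabet
#' every peptide and protein sequence in this package is validated against.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Monoisotopic residue masses (Da); peptide mass = sum(residues) + water.
MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.010565

# Published residue frequencies (%) over UniProtKB/Swiss-Prot; used as the
# whole-proteome reference composition. Normalized to sum exactly 1 on use.
SWISSPROT_FREQ_PCT <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37,
  Q = 3.93, E = 6.75, G = 7.07, H = 2.27, I = 5.96,
  L = 9.66, K = 5.84, M = 2.42, F = 3.86, P = 4.70,
  S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

#' Default side-chain grouping of amino acids
#'
#' Maps each residue to a physicochemical class used when collapsing
#' composition profiles and terminal tetrapeptides: acidic (D, E), basic
#' (K, R, H), polar uncharged (S, T, N, Q, C, Y) and nonpolar
#' (G, A, V, L, I, P, M, F, W). Histidine is counted as basic; cysteine and
#' tyrosine as polar uncharged. Any alternative convention can be supplied
#' wherever a `grouping` argument is accepted, as a named character vector
#' residue -> group label covering all 20 residues.
#'
#' @return Named character vector of length 20 (names are residues, values
#'   are group labels).
#' @examples
#' side_chain_grouping()[["H"]]
#' @export
side_chain_grouping <- function() {
  groups <- list(
    acidic = c("D", "E"),
    basic = c("K", "R", "H"),
    polar_uncharged = c("S", "T", "N", "Q", "C", "Y"),
    nonpolar = c("G", "A", "V", "L", "I", "P", "M", "F", "W")
  )
  out <- unlist(lapply(names(groups), function(g) {
    stats::setNames(rep(g, length(groups[[g]])), groups[[g]])
  }))
  out[AA_ALPHABET]
}

check_grouping <- function(grouping) {
  missing <- setdiff(AA_ALPHABET, names(grouping))
  if (length(missing) > 0) {
    stop("grouping does not assign residue(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  grouping
}

#' Monoisotopic peptide mass
#'
#' @param sequence Character vector of peptide sequences (20-letter alphabet).
#' @return Numeric vector of monoisotopic masses in Da (residue masses plus
#'   one water).
#' @examples
#' peptide_mass("NALAHKYH")
#' @export
peptide_mass <- function(sequence) {
  vapply(sequence, function(s) {
    sum(MONO_MASS[strsplit(s, "", fixed = TRUE)[[1]]]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

# Residue counts per sequence: matrix len(sequences) x 20.
residue_count_matrix <- function(sequences) {
  m <- vapply(AA_ALPHABET, function(a) {
    stringi::stri_count_fixed(sequences, a)
  }, integer(length(sequences)))
  if (length(sequences) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, AA_ALPHABET))
  m
}

check_sequences <- function(sequences, what = "sequence") {
  bad <- which(is.na(sequences) | sequences == "" |
    stringi::stri_detect_regex(sequences, "[^ACDEFGHIKLMNPQRSTVWY]"))
  if (length(bad) > 0) {
    stop(
      what, " at position ", bad[1], " ('", sequences[bad[1]],
      "') is empty or contains characters outside the 20-letter amino-acid alphabet",
      call. = FALSE
    )
  }
  invisible(sequences)
}
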