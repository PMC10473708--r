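# Monoisotopic residue masses (Da) for the 20 standard amino acids.
# Peptide monoisotopic mass = sum of residue masses + one water (18.010565).
RESIDUE_MASS <- c(
  A =  71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G =  57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P =  97.052764, S =  87.032028,
  T = 101.047679, W = 186.079313, Y = 163.063329, V =  99.068414
)

WATER_MASS <- 18.010565

check_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    abort(sprintf("`%s` must be a non-empty amino-acid string.", arg),
          class = "hdxdiff_input_error")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(RESIDUE_MASS))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown residue letter(s) in `%s`: %s", arg,
                  paste(bad, collapse = ", ")),
          class = "hdxdiff_input_error")
  }
  aa
}

#' Count exchangeable backbone amides of a peptide
#'
#' Standard HDX-MS bookkeeping: every residue contributes one backbone amide
#' hydrogen except prolines (no amide NH) and the first `n_term_excluded`
#' residues, whose amide deuterons back-exchange too fast to be retained
#' through quench and chromatography.
#'
#' @param sequence One-letter amino-acid string.
#' @param n_term_excluded Number of N-terminal residues excluded from the
#'   count (default 1; some laboratories use 2).
#' @return Integer count of exchangeable amides (never negative).
#' @examples
#' exchangeable_amides("MKPLSV") # 4: six residues, one Pro, minus N-terminus
#' exchangeable_amides("AAAAA")  # 4
#' @export
exchangeable_amides <- function(sequence, n_term_excluded = 1L) {
  aa <- check_sequence(sequence)
  keep <- seq_along(aa) > n_term_excluded
  as.integer(sum(keep & aa != "P"))
}

#' Monoisotopic mass of a peptide
#'
#' @param sequence One-letter amino-acid string.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence) {
  aa <- check_sequence(sequence)
  sum(RESIDUE_MASS[aa]) + WATER_MASS
}
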