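#' Monoisotopic residue masses and mass-spectrometry constants
#'
#' Monoisotopic masses (Da) of the 20 standard amino-acid residues
#' (i.e. the mass contributed inside a peptide chain, water excluded),
#' plus the constants needed for phosphopeptide mass bookkeeping.
#'
#' @format A named numeric vector of length 20 (one-letter codes).
#' @keywords internal
AA_MONO <- c(
  G =  57.02146372, A =  71.03711379, S =  87.03202841, P =  97.05276385,
  V =  99.06841391, T = 101.04767847, C = 103.00918496, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

# monoisotopic masses (Da)
MASS_WATER   <- 18.010565   # H2O, added once per peptide
MASS_PROTON  <-  1.007276   # charge carrier
MASS_PHOSPHO <- 79.96633    # HPO3, added per phosphorylation
MASS_H3PO4   <- 97.9769     # phosphoric acid, lost as a neutral

#' Check a protein/peptide sequence for unknown residues
#' @param sequence character scalar, one-letter amino-acid codes
#' @return the sequence, invisibly
#' @keywords internal
check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), names(AA_MONO))
  if (length(bad) > 0L) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  invisible(sequence)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water; optionally with phosphate groups.
#'
#' @param sequence peptide sequence (one-letter codes)
#' @param n_phospho number of phosphorylated residues (adds 79.96633 Da each)
#' @return monoisotopic mass in Da
#' @examples
#' peptide_mass("GGGGGG")          # 360.1393
#' peptide_mass("AREQTIDSNASIPEWQK", n_phospho = 1)
#' @export
peptide_mass <- function(sequence, n_phospho = 0L) {
  check_sequence(sequence)
  stopifnot(n_phospho >= 0L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(AA_MONO[chars]) + MASS_WATER + n_phospho * MASS_PHOSPHO
}

#' Mass-to-charge ratio of a (phospho)peptide ion
#'
#' m/z = (M + z * m_proton) / z with monoisotopic peptide mass M.
#'
#' @param sequence peptide sequence
#' @param n_phospho number of phosphorylations; must not exceed the number
#'   of serine, threonine and tyrosine residues in `sequence`
#' @param charge precursor charge state (positive integer)
#' @return theoretical monoisotopic m/z
#' @examples
#' peptide_mz("GGGGGG", 0, 1)                      # 361.1466
#' peptide_mz("AREQTIDSNASIPEWQK", 1, 2)           # 1026.973
#' @export
peptide_mz <- function(sequence, n_phospho = 0L, charge = 1L) {
  if (charge < 1L) stop("charge must be a positive integer")
  n_sty <- sum(strsplit(sequence, "", fixed = TRUE)[[1L]] %in% c("S", "T", "Y"))
  if (n_phospho > n_sty) {
    stop("phospho count (", n_phospho, ") exceeds available S/T/Y residues (",
         n_sty, ")")
  }
  (peptide_mass(sequence, n_phospho) + charge * MASS_PROTON) / charge
}

#' Multistage-activation neutral-loss m/z offsets
#'
#' Precursor ions losing phosphoric acid (H3PO4, 97.9769 Da) shift by
#' 97.9769 / z in m/z. Multistage activation re-activates the neutral-loss
#' product; the instrument method lists one offset per precursor charge
#' state 1-3 (98, 49 and 32.7 Da, to instrument-setting precision).
#'
#' @param charge precursor charge state, one of 1, 2, 3
#' @return list with `offset` (full precision, m/z units) and `rounded`
#'   (one decimal, the value as entered in an instrument method)
#' @examples
#' msa_neutral_loss_offsets(2)$rounded   # 49
#' msa_neutral_loss_offsets(3)$rounded   # 32.7
#' @export
msa_neutral_loss_offsets <- function(charge) {
  if (length(charge) != 1L || !charge %in% c(1L, 2L, 3L)) {
    stop("charge must be 1, 2 or 3 (one neutral-loss offset per charge state)")
  }
  offset <- MASS_H3PO4 / charge
  list(offset = offset, rounded = round(offset, 1L))
}
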