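#' Theoretical b- and y-fragment ions of a (phospho)peptide
#'
#' Computes singly- to `max_charge`-protonated b- and y-series m/z values.
#' Fragments that contain at least one phosphorylated residue are
#' additionally emitted as a neutral-loss variant shifted by
#' -97.9769 / z (loss of phosphoric acid), the diagnostic pattern of
#' phosphopeptide spectra acquired with multistage activation.
#'
#' b_i covers residues 1..i (mass = sum of residues + proton per charge);
#' y_i covers the C-terminal i residues (mass = sum + water + proton per
#' charge). Phosphate mass is added to every fragment containing a site.
#'
#' @param sequence peptide sequence
#' @param phospho_positions integer positions (1-based within the peptide)
#'   of phosphorylated residues; may be empty
#' @param max_charge maximum fragment charge (default 1)
#' @return data frame with columns `type` ("b"/"y"), `index`, `charge`,
#'   `mz`, `neutral_loss` (logical; `TRUE` rows are the -H3PO4 variants)
#' @examples
#' fragment_ions("GK")                       # b1 = 58.0287, y1 = 147.1128
#' fragment_ions("ASK", phospho_positions = 2)
#' @export
fragment_ions <- function(sequence, phospho_positions = integer(0L),
                          max_charge = 1L) {
  check_sequence(sequence)
  stopifnot(max_charge >= 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  phospho_positions <- as.integer(phospho_positions)
  if (any(phospho_positions < 1L) || any(phospho_positions > n)) {
    stop("phospho position outside the peptide (length ", n, ")")
  }
  res_mass <- AA_MONO[chars]
  is_phos <- seq_len(n) %in% phospho_positions

  rows <- list()
  add <- function(type, index, neutral_mass, has_site) {
    for (z in seq_len(max_charge)) {
      mz <- (neutral_mass + z * MASS_PROTON) / z
      rows[[length(rows) + 1L]] <<- data.frame(
        type = type, index = index, charge = z, mz = mz,
        neutral_loss = FALSE, stringsAsFactors = FALSE)
      if (has_site) {
        rows[[length(rows) + 1L]] <<- data.frame(
          type = type, index = index, charge = z, mz = mz - MASS_H3PO4 / z,
          neutral_loss = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_len(n - 1L)) {
    pre <- seq_len(i)
    add("b", i, sum(res_mass[pre]) + sum(is_phos[pre]) * MASS_PHOSPHO,
        any(is_phos[pre]))
    suf <- (n - i + 1L):n
    add("y", i, sum(res_mass[suf]) + sum(is_phos[suf]) * MASS_PHOSPHO +
        MASS_WATER, any(is_phos[suf]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
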