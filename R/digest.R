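#' Digestion parameters
#'
#' Parameter object for in-silico proteolytic digestion. Defaults mirror a
#' phosphosite search configuration for low-abundance membrane proteins:
#' up to four missed cleavages, peptides of at least six residues, and a
#' maximum (unmodified) monoisotopic peptide mass of 6,000 Da.
#'
#' @param protease one of `"trypsin"`, `"lysc"`, `"aspn"`
#' @param max_missed maximum number of missed cleavages (default 4)
#' @param min_length minimum peptide length in residues (default 6)
#' @param max_mass maximum unmodified monoisotopic peptide mass in Da
#'   (default 6000)
#' @param trypsin_no_p if `TRUE` (classical rule, default) trypsin does not
#'   cleave K/R-P bonds; set `FALSE` for the cut-anywhere dialect
#' @param aspn_d_only if `TRUE` (default) Asp-N cleaves N-terminal to
#'   aspartate only; set `FALSE` to also cleave before glutamate
#' @return object of class `digest_params`
#' @export
digest_params <- function(protease = c("trypsin", "lysc", "aspn"),
                          max_missed = 4L, min_length = 6L, max_mass = 6000,
                          trypsin_no_p = TRUE, aspn_d_only = TRUE) {
  protease <- match.arg(protease)
  stopifnot(max_missed >= 0L, min_length > 0L, max_mass > 0)
  structure(
    list(protease = protease, max_missed = as.integer(max_missed),
         min_length = as.integer(min_length), max_mass = max_mass,
         trypsin_no_p = isTRUE(trypsin_no_p), aspn_d_only = isTRUE(aspn_d_only)),
    class = "digest_params")
}

#' Cleavage positions of a protease on a sequence
#'
#' Positions are 0-based cut points: a value `i` means the bond between
#' residues `i` and `i + 1` (1-based) is cleaved.
#'
#' Rules: trypsin cleaves C-terminal to K or R (optionally not before P);
#' Lys-C cleaves C-terminal to K; Asp-N cleaves N-terminal to D (optionally
#' also E).
#'
#' @param sequence protein sequence
#' @param params a [digest_params()] object
#' @return sorted integer vector of cut points (possibly empty)
#' @export
cleavage_sites <- function(sequence, params) {
  check_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer(0L))
  i <- seq_len(n - 1L)                       # candidate cut after residue i
  cut <- switch(params$protease,
    trypsin = chars[i] %in% c("K", "R") &
              (!params$trypsin_no_p | chars[i + 1L] != "P"),
    lysc    = chars[i] == "K",
    aspn    = if (params$aspn_d_only) chars[i + 1L] == "D"
              else chars[i + 1L] %in% c("D", "E"))
  i[cut]
}

#' In-silico proteolytic digestion with missed cleavages
#'
#' Enumerates all peptides obtainable with 0 to `max_missed` missed
#' cleavages (every run of consecutive fully-cleaved fragments), then
#' filters by minimum length and maximum unmodified monoisotopic mass.
#'
#' @param sequence protein sequence (20-letter amino-acid alphabet)
#' @param params a [digest_params()] object
#' @return data frame with one row per peptide: `sequence`, `start`, `end`
#'   (1-based, inclusive), `missed` (missed-cleavage count), `mass`
#'   (unmodified monoisotopic mass, Da); ordered by `start`, then length
#' @examples
#' digest("MKAAAAARGGGGG", digest_params("trypsin", max_missed = 1))
#' @export
digest <- function(sequence, params = digest_params()) {
  check_sequence(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  cuts <- cleavage_sites(sequence, params)
  bounds <- c(0L, cuts, n)                   # fragment boundaries, 0-based
  k <- length(bounds) - 1L                   # number of fully-cleaved fragments
  out <- vector("list", 0L)
  for (i in seq_len(k)) {
    for (mc in 0L:min(params$max_missed, k - i)) {
      start <- bounds[i] + 1L
      end <- bounds[i + 1L + mc]
      len <- end - start + 1L
      if (len < params$min_length) next
      pep <- substr(sequence, start, end)
      mass <- peptide_mass(pep)
      if (mass > params$max_mass) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = pep, start = start, end = end, missed = mc, mass = mass,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sequence = character(0L), start = integer(0L),
                      end = integer(0L), missed = integer(0L),
                      mass = numeric(0L), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end - res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Sequence coverage of a protein by a set of peptides
#'
#' Fraction of protein residues covered by the union of peptide spans.
#'
#' @param peptides data frame with `start` and `end` columns (1-based,
#'   inclusive), e.g. the output of [digest()]
#' @param protein_length protein length in residues
#' @return coverage fraction in `[0, 1]`
#' @export
sequence_coverage <- function(peptides, protein_length) {
  stopifnot(protein_length >= 1L)
  if (nrow(peptides) == 0L) return(0)
  if (any(peptides$start < 1L) || any(peptides$end > protein_length) ||
      any(peptides$start > peptides$end)) {
    stop("peptide span outside the protein (length ", protein_length, ")")
  }
  covered <- logical(protein_length)
  for (i in seq_len(nrow(peptides))) {
    covered[peptides$start[i]:peptides$end[i]] <- TRUE
  }
  sum(covered) / protein_length
}
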