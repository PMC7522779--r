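#' Phosphopeptide evidence tables
#'
#' An evidence table holds one row per phosphopeptide observation from one
#' protease digest, with columns:
#' \describe{
#'   \item{window}{peptide or sequence-window string}
#'   \item{positions}{phosphorylated residue position(s) in protein
#'     coordinates (1-based, counting from the initiator methionine),
#'     semicolon-separated for multiply phosphorylated peptides}
#'   \item{residues}{one-letter residue code per position, semicolon list}
#'   \item{protease}{`"trypsin"`, `"lysc"` or `"aspn"`}
#'   \item{loc_probs}{per-site localization probability, semicolon list,
#'     aligned with `positions`}
#'   \item{pep}{posterior error probability of the peptide-spectrum match}
#' }
#'
#' @param path TSV file with the columns above
#' @return data frame of evidence rows
#' @export
read_evidence <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  need <- c("window", "positions", "residues", "protease", "loc_probs", "pep")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols) > 0L) {
    stop("evidence table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  validate_evidence(ev)
  ev
}

split_int <- function(x) lapply(strsplit(as.character(x), ";", fixed = TRUE),
                                function(v) as.integer(trimws(v)))
split_num <- function(x) lapply(strsplit(as.character(x), ";", fixed = TRUE),
                                function(v) as.numeric(trimws(v)))
split_chr <- function(x) lapply(strsplit(as.character(x), ";", fixed = TRUE),
                                trimws)

#' Validate an evidence table
#'
#' Checks semicolon-list alignment (multiplicity = number of sites),
#' probability ranges and protease labels; reports offending row numbers.
#'
#' @param evidence evidence data frame (see [read_evidence()])
#' @return the evidence, invisibly
#' @export
validate_evidence <- function(evidence) {
  pos <- split_int(evidence$positions)
  lp <- split_num(evidence$loc_probs)
  res <- split_chr(evidence$residues)
  for (i in seq_len(nrow(evidence))) {
    if (length(pos[[i]]) != length(lp[[i]]) ||
        length(pos[[i]]) != length(res[[i]])) {
      stop("evidence row ", i, ": positions, residues and loc_probs must ",
           "have equal multiplicity")
    }
    if (anyNA(pos[[i]]) || anyNA(lp[[i]])) {
      stop("evidence row ", i, ": malformed positions or loc_probs")
    }
    if (any(lp[[i]] < 0) || any(lp[[i]] > 1)) {
      stop("evidence row ", i, ": localization probability outside [0, 1]")
    }
  }
  if (any(evidence$pep < 0 | evidence$pep > 1)) {
    stop("PEP outside [0, 1]")
  }
  bad <- setdiff(unique(evidence$protease), c("trypsin", "lysc", "aspn"))
  if (length(bad) > 0L) {
    stop("unknown protease label(s): ", paste(bad, collapse = ", "))
  }
  invisible(evidence)
}

#' Assemble a confidence-filtered phosphosite table
#'
#' Applies the two-stage confidence filter used for reporting in-vivo
#' phosphosites: a peptide observation must have a posterior error
#' probability below `pep_max`, and a site within it must carry a
#' localization probability of at least `locprob_min`. Each residue of a
#' multiply phosphorylated peptide is assessed separately, so one peptide
#' row can contribute several sites (and a site can pass from one peptide
#' but fail from another). A residue enters the table if at least one
#' observation passes both thresholds.
#'
#' @param evidence evidence data frame (see [read_evidence()])
#' @param pep_max maximum posterior error probability (default 0.01)
#' @param locprob_min minimum localization probability (default 0.95)
#' @param prior_sites optional integer vector of previously known site
#'   positions; sites absent from it are flagged `novel`
#' @return data frame of class `site_table`, one row per distinct residue,
#'   ordered by position: `position`, `residue`, best localization
#'   probability per protease (`aspn`, `lysc`, `trypsin`; `NA` if the site
#'   was not confidently observed in that digest), `n_peptides` (number of
#'   passing observations) and, when `prior_sites` is given, `novel`
#' @examples
#' ev <- data.frame(window = "REQTIDpSNASIPE", positions = "310",
#'                  residues = "S", protease = "trypsin",
#'                  loc_probs = "0.999", pep = 0.001)
#' filter_and_assemble_sites(ev)
#' @export
filter_and_assemble_sites <- function(evidence, pep_max = 0.01,
                                      locprob_min = 0.95,
                                      prior_sites = NULL) {
  empty <- data.frame(position = integer(0L), residue = character(0L),
                      aspn = numeric(0L), lysc = numeric(0L),
                      trypsin = numeric(0L), n_peptides = integer(0L),
                      stringsAsFactors = FALSE)
  class(empty) <- c("site_table", "data.frame")
  if (nrow(evidence) == 0L) return(empty)
  validate_evidence(evidence)

  pos <- split_int(evidence$positions)
  lp <- split_num(evidence$loc_probs)
  res <- split_chr(evidence$residues)
  # long form: one row per (evidence row, site)
  long <- do.call(rbind, lapply(seq_len(nrow(evidence)), function(i) {
    data.frame(position = pos[[i]], residue = res[[i]], loc_prob = lp[[i]],
               protease = evidence$protease[i], pep = evidence$pep[i],
               stringsAsFactors = FALSE)
  }))
  pass <- long[long$pep < pep_max & long$loc_prob >= locprob_min, , drop = FALSE]
  if (nrow(pass) == 0L) return(empty)

  positions <- sort(unique(pass$position))
  tab <- do.call(rbind, lapply(positions, function(p) {
    hits <- pass[pass$position == p, , drop = FALSE]
    best <- vapply(c("aspn", "lysc", "trypsin"), function(enz) {
      v <- hits$loc_prob[hits$protease == enz]
      if (length(v) == 0L) NA_real_ else max(v)
    }, numeric(1L))
    data.frame(position = p, residue = hits$residue[1L],
               aspn = best[["aspn"]], lysc = best[["lysc"]],
               trypsin = best[["trypsin"]], n_peptides = nrow(hits),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(prior_sites)) {
    tab$novel <- !(tab$position %in% as.integer(prior_sites))
  }
  rownames(tab) <- NULL
  class(tab) <- c("site_table", "data.frame")
  tab
}

#' Write a phosphosite table as TSV
#'
#' @param sites a `site_table` from [filter_and_assemble_sites()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "-")
  invisible(path)
}

#' @export
print.site_table <- function(x, ...) {
  cat("Phosphosite table:", nrow(x), "distinct residue(s)\n")
  if (nrow(x) > 0L) {
    cat(paste0(x$residue, x$position, collapse = ", "), "\n")
  }
  NextMethod()
}
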