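#' Normalize one iBAQ run to bait-relative abundances
#'
#' Each protein's raw iBAQ intensity is divided by the summed iBAQ of all
#' proteins identified in the run (missing values are "not identified"
#' and excluded from the sum), and the resulting fractions are rescaled
#' so that the bait equals 100\%. The output is invariant to any
#' multiplicative rescaling of the raw column (instrument response,
#' loading), which is the point of the normalization.
#'
#' @param intensities named numeric vector of raw iBAQ intensities for
#'   one replicate; `NA` marks proteins not identified in this run
#' @param bait_id name of the bait protein; must be present with a
#'   positive intensity
#' @param contaminants optional protein names excluded from the run sum
#'   (and from the output)
#' @return named numeric vector of bait-relative abundances in percent
#'   (bait exactly 100); `NA` entries stay `NA`
#' @examples
#' normalize_run(c(PEX14 = 50, PEX5 = 25, PEX13 = 25), "PEX14")
#' @export
normalize_run <- function(intensities, bait_id, contaminants = NULL) {
  if (is.null(names(intensities))) stop("intensities must be named")
  if (!is.null(contaminants)) {
    intensities <- intensities[!names(intensities) %in% contaminants]
  }
  if (!bait_id %in% names(intensities) || is.na(intensities[[bait_id]]) ||
      intensities[[bait_id]] <= 0) {
    stop("bait '", bait_id, "' missing (or non-positive) in this run")
  }
  if (any(intensities < 0, na.rm = TRUE)) stop("negative iBAQ intensity")
  total <- sum(intensities, na.rm = TRUE)
  if (total <= 0) stop("run total is not positive")
  frac <- intensities / total * 100
  frac / frac[[bait_id]] * 100
}

#' Aggregate bait-relative abundances over replicates
#'
#' @param runs list of named vectors as returned by [normalize_run()]
#'   (one per replicate), or a proteins x replicates matrix of normalized
#'   values
#' @return data frame `protein`, `mean` (\%), `sd` (sample SD over the
#'   replicates in which the protein was observed; 0 when `n = 1`), `n`;
#'   ordered by decreasing mean. The bait aggregates to exactly
#'   `mean = 100, sd = 0`.
#' @export
aggregate_replicates <- function(runs) {
  if (is.matrix(runs)) {
    runs <- lapply(seq_len(ncol(runs)), function(j) runs[, j])
  }
  if (length(runs) == 0L) stop("at least one replicate is required")
  proteins <- unique(unlist(lapply(runs, names)))
  rows <- lapply(proteins, function(p) {
    v <- unlist(lapply(runs, function(r) if (p %in% names(r)) r[[p]] else NA))
    v <- v[!is.na(v)]
    data.frame(protein = p, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full iBAQ complex-composition normalization
#'
#' Applies [normalize_run()] to every replicate column of a raw
#' protein-by-replicate iBAQ table and aggregates with
#' [aggregate_replicates()].
#'
#' @param ibaq_table numeric matrix proteins x replicates (dimnames
#'   required), e.g. from [generate_ibaq_table()] or [read_ibaq_tsv()]
#' @param bait_id bait protein identifier
#' @param contaminants optional protein names excluded from run sums
#' @return data frame as from [aggregate_replicates()]
#' @export
ibaq_normalize <- function(ibaq_table, bait_id, contaminants = NULL) {
  stopifnot(is.matrix(ibaq_table), !is.null(rownames(ibaq_table)))
  runs <- lapply(seq_len(ncol(ibaq_table)), function(j) {
    normalize_run(ibaq_table[, j], bait_id, contaminants)
  })
  aggregate_replicates(runs)
}

#' Read a protein-by-replicate iBAQ TSV
#'
#' First column `protein`, remaining columns one replicate each; empty
#' cells or `NA` mark proteins not identified in that run.
#'
#' @param path TSV file
#' @return numeric matrix with protein rownames
#' @export
read_ibaq_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "protein") stop("first column must be 'protein'")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df$protein
  mat
}

#' Write a normalized abundance table as TSV
#' @param abundance data frame from [ibaq_normalize()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ibaq_tsv <- function(abundance, path) {
  utils::write.table(abundance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
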