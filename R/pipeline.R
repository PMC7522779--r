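#' Run the imaging pipeline end to end
#'
#' Composes the single-strain workflow (simulate or load stacks, segment
#' the best-focused bright-field slice, project the GFP stack, filter
#' false positives, quantify cytosolic intensities) for two or more
#' strains, then compares the first two strains with a Welch t-test on
#' the background-corrected (uncentered) per-cell intensities.
#'
#' Each entry of `strains` is either an [image_sim_config()] (or a list
#' of them, one per field of view) or a list of pre-built image pairs
#' (elements with `brightfield`/`gfp` stacks). When `out_dir` is given,
#' per-cell measurement CSVs, a per-strain summary CSV and a JSON run
#' manifest (parameters, seed, package version) are written; reruns with
#' the same configuration and seed are byte-identical.
#'
#' @param strains named list (>= 2 entries) as described above
#' @param seg_params,fp_params,q_params module parameter objects
#' @param seed seed recorded in the manifest and used to derive per-strain
#'   simulation seeds when `strains` holds simulation configs whose seeds
#'   should be offset per strain (`NULL` leaves config seeds untouched)
#' @param out_dir optional output directory
#' @return list with `measurements` (all strains), `summaries`, `test`
#'   (a `test_result` comparing the first two strains) and `paths`
#'   (written files, if any)
#' @export
run_imaging_pipeline <- function(strains,
                                 seg_params = segmentation_params(),
                                 fp_params = filter_params(),
                                 q_params = quant_params(),
                                 seed = NULL, out_dir = NULL) {
  if (length(strains) < 2L || is.null(names(strains))) {
    stop("at least two named strains are required")
  }
  results <- lapply(seq_along(strains), function(k) {
    entry <- strains[[k]]
    name <- names(strains)[k]
    configs <- if (inherits(entry, "image_sim_config")) list(entry)
               else entry
    pairs <- lapply(seq_along(configs), function(j) {
      cfg <- configs[[j]]
      if (inherits(cfg, "image_sim_config")) {
        if (!is.null(seed)) {
          # independent per-strain, per-field streams derived from the seed
          cfg$seed <- (seed * 1000L + k * 100L + j) %% .Machine$integer.max
        }
        generate_image_pair(cfg)
      } else {
        cfg   # already an image pair
      }
    })
    tryCatch(
      quantify_strain(pairs, strain = name, seg_params = seg_params,
                      fp_params = fp_params, q_params = q_params),
      error = function(e) stop("strain '", name, "': ", conditionMessage(e)))
  })
  measurements <- do.call(rbind, lapply(results, `[[`, "measurements"))
  summaries <- do.call(rbind, lapply(results, `[[`, "summary"))
  a <- results[[1L]]$measurements$corrected
  b <- results[[2L]]$measurements$corrected
  test <- if (length(a) >= 2L && length(b) >= 2L) welch_t_test(a, b) else NULL

  paths <- character(0L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(measurements = file.path(out_dir, "measurements.csv"),
               summaries = file.path(out_dir, "strain_summaries.csv"),
               manifest = file.path(out_dir, "run_manifest.json"))
    utils::write.csv(measurements, paths[["measurements"]], row.names = FALSE)
    utils::write.csv(summaries, paths[["summaries"]], row.names = FALSE)
    manifest <- list(
      seed = seed,
      strains = names(strains),
      segmentation = unclass(seg_params),
      filters = unclass(fp_params),
      quantification = unclass(q_params),
      package_version = as.character(utils::packageVersion("pexphos")))
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  }
  list(measurements = measurements, summaries = summaries, test = test,
       paths = paths)
}

#' Run the phosphosite pipeline
#'
#' Loads (or accepts) a phosphopeptide evidence table, applies the
#' confidence filter (PEP < `pep_max`, localization probability >=
#' `locprob_min`) and assembles the per-residue site table. When a
#' protein sequence is supplied, a per-protease in-silico digestion
#' coverage report is produced alongside.
#'
#' @param evidence evidence data frame or path to an evidence TSV
#'   (see [read_evidence()])
#' @param protein optional protein sequence (character) or path to a
#'   FASTA file with one entry
#' @param pep_max,locprob_min confidence thresholds (defaults 0.01, 0.95)
#' @param prior_sites optional previously known site positions (novelty
#'   flag)
#' @param digest_defaults a [digest_params()] template; the protease is
#'   overridden per digest in the coverage report
#' @param out_dir optional output directory for `site_table.tsv` and
#'   `coverage.tsv`
#' @return list with `sites` (a `site_table`), `coverage` (data frame
#'   `protease`, `n_peptides`, `coverage`, or `NULL` without a protein)
#'   and `paths`
#' @export
run_sites_pipeline <- function(evidence, protein = NULL,
                               pep_max = 0.01, locprob_min = 0.95,
                               prior_sites = NULL,
                               digest_defaults = digest_params(),
                               out_dir = NULL) {
  if (is.character(evidence) && length(evidence) == 1L) {
    evidence <- read_evidence(evidence)
  }
  if (nrow(evidence) == 0L) {
    warning("empty evidence table; site table is empty")
  }
  sites <- filter_and_assemble_sites(evidence, pep_max = pep_max,
                                     locprob_min = locprob_min,
                                     prior_sites = prior_sites)
  coverage <- NULL
  if (!is.null(protein)) {
    if (file.exists(protein)) protein <- read_fasta_protein(protein)
    coverage <- do.call(rbind, lapply(c("aspn", "lysc", "trypsin"),
      function(enz) {
        p <- digest_defaults; p$protease <- enz
        peps <- digest(protein, p)
        data.frame(protease = enz, n_peptides = nrow(peps),
                   coverage = sequence_coverage(peps, nchar(protein)),
                   stringsAsFactors = FALSE)
      }))
  }
  paths <- character(0L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(sites = file.path(out_dir, "site_table.tsv"))
    write_site_table(sites, paths[["sites"]])
    if (!is.null(coverage)) {
      paths <- c(paths, coverage = file.path(out_dir, "coverage.tsv"))
      utils::write.table(coverage, paths[["coverage"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  list(sites = sites, coverage = coverage, paths = paths)
}

#' Read the first protein sequence from a FASTA file
#'
#' Uses Biostrings when available, otherwise a minimal reader for plain
#' single-record FASTA.
#'
#' @param path FASTA file
#' @return protein sequence as a character scalar
#' @export
read_fasta_protein <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    if (length(set) == 0L) stop("no sequences in ", path)
    return(as.character(set[[1L]]))
  }
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("not a FASTA file: ", path)
  from <- headers[1L] + 1L
  to <- if (length(headers) > 1L) headers[2L] - 1L else length(lines)
  paste(gsub("\\s", "", lines[from:to]), collapse = "")
}
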