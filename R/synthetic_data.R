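#' Run code with a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic microscopy generator
#'
#' Describes a field of yeast-like cells imaged in two channels: a
#' bright-field stack in which cells appear as disks delimited by a dark
#' boundary ring on a bright background (interiors slightly darker than
#' the background so that thresholding captures the full cell), and a GFP
#' stack in which each cell carries a diffuse cytosolic level plus a few
#' punctate peroxisome-like foci. One plane is in focus; the others are
#' blurred copies, emulating a z-series.
#'
#' @param rows,cols field size in pixels
#' @param n_planes number of z planes (default 5)
#' @param n_cells number of cells to place (non-overlapping)
#' @param radius_range cell radius range in pixels (default 22-28)
#' @param bf_background bright-field background level (default 200)
#' @param boundary_dark intensity drop of the cell boundary ring below the
#'   background (default 120)
#' @param interior_dim intensity drop of the cell interior below the
#'   background (default 30); keeps interiors in the dark (cell) phase
#' @param ring_width boundary ring thickness in pixels (default 3)
#' @param gfp_level mean true cytosolic GFP level per cell (default 40)
#' @param gfp_level_sd between-cell spread of the cytosolic level
#'   (default: 10\% of `gfp_level`)
#' @param n_foci punctate foci per cell (default 3)
#' @param focus_amplitude peak intensity of a focus above the cytosolic
#'   level (default 120)
#' @param focus_sigma Gaussian width of a focus in pixels (default 1.8)
#' @param gfp_bleed extent of the fluorescent footprint beyond the outer
#'   ring edge in pixels (default 2); the cell wall producing the dark
#'   bright-field ring is itself inside the fluorophore-filled volume
#' @param noise_sd additive Gaussian noise standard deviation (default 5)
#' @param saturation intensity cap; values are clipped to
#'   `[0, saturation]` (default 255, 8-bit)
#' @param blur_sigma out-of-focus blur per plane of defocus (default 1.5)
#' @param margin minimum distance of cell centers from the field edge,
#'   as a fraction of the field size, in addition to the cell radius
#'   (default 0.08, keeping cells clear of the border-removal band)
#' @param seed random seed fixing all randomness of the generator
#' @return object of class `image_sim_config`
#' @export
image_sim_config <- function(rows = 512L, cols = 512L, n_planes = 5L,
                             n_cells = 20L, radius_range = c(22, 28),
                             bf_background = 200, boundary_dark = 120,
                             interior_dim = 30, ring_width = 3,
                             gfp_level = 40, gfp_level_sd = gfp_level * 0.1,
                             n_foci = 3L, focus_amplitude = 120,
                             focus_sigma = 1.8, gfp_bleed = 2,
                             noise_sd = 5,
                             saturation = 255, blur_sigma = 1.5,
                             margin = 0.08, seed = 1L) {
  if (rows <= 0L || cols <= 0L || n_planes <= 0L) {
    stop("field dimensions and plane count must be positive")
  }
  if (n_cells < 0L) stop("cell count must be >= 0")
  stopifnot(length(radius_range) == 2L, radius_range[1L] <= radius_range[2L],
            radius_range[1L] > 0, saturation >= bf_background,
            noise_sd >= 0, margin >= 0, margin < 0.5)
  structure(as.list(environment()), class = "image_sim_config")
}

place_cells <- function(config) {
  n <- config$n_cells
  if (n == 0L) {
    return(data.frame(id = integer(0L), row = numeric(0L), col = numeric(0L),
                      radius = numeric(0L), cyto_level = numeric(0L)))
  }
  mrow <- config$margin * config$rows
  mcol <- config$margin * config$cols
  rs <- numeric(n); cs <- numeric(n); rad <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 500L * n
  # boundary-to-boundary gap; larger than the default closing-disk
  # diameter so that morphological closing cannot bridge two cells
  min_gap <- 12
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " non-overlapping cells in a ",
           config$rows, "x", config$cols, " field")
    }
    r <- stats::runif(1L, config$radius_range[1L], config$radius_range[2L])
    lo_r <- mrow + r + config$ring_width; hi_r <- config$rows - lo_r
    lo_c <- mcol + r + config$ring_width; hi_c <- config$cols - lo_c
    if (hi_r <= lo_r || hi_c <= lo_c) stop("field too small for cell radius")
    cr <- stats::runif(1L, lo_r, hi_r)
    cc <- stats::runif(1L, lo_c, hi_c)
    if (placed > 0L) {
      d <- sqrt((rs[seq_len(placed)] - cr)^2 + (cs[seq_len(placed)] - cc)^2)
      if (any(d < rad[seq_len(placed)] + r + 2 * config$ring_width + min_gap)) next
    }
    placed <- placed + 1L
    rs[placed] <- cr; cs[placed] <- cc; rad[placed] <- r
  }
  level <- stats::rnorm(n, config$gfp_level, config$gfp_level_sd)
  level <- pmax(level, 1)
  data.frame(id = seq_len(n), row = rs, col = cs, radius = rad,
             cyto_level = level)
}

# paint a radially defined value into a sub-window around one cell
paint_disk <- function(img, cr, cc, r_outer, fun) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(cr - r_outer)); r1 <- min(nr, ceiling(cr + r_outer))
  c0 <- max(1L, floor(cc - r_outer)); c1 <- min(nc, ceiling(cc + r_outer))
  rr <- r0:r1; cci <- c0:c1
  d <- sqrt(outer((rr - cr)^2, (cci - cc)^2, "+"))
  img[rr, cci] <- fun(img[rr, cci], d)
  img
}

#' Generate a paired bright-field/GFP z-stack with ground truth
#'
#' @param config an [image_sim_config()]
#' @return list with elements `brightfield` and `gfp` (3D arrays
#'   `[row, col, plane]` on the 0-saturation intensity scale), `cells`
#'   (ground-truth data frame: `id`, `row`, `col`, `radius`,
#'   `cyto_level`), `foci` (data frame of focus positions, planes and
#'   amplitudes) and `focal_plane` (index of the in-focus plane)
#' @examples
#' sim <- generate_image_pair(image_sim_config(n_cells = 3, seed = 7))
#' dim(sim$brightfield)
#' @export
generate_image_pair <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  with_seed(config$seed, {
    cells <- place_cells(config)
    nr <- config$rows; nc <- config$cols; np <- config$n_planes
    focal <- (np + 1L) %/% 2L

    # clean bright-field image: bright background, dark ring, dim interior
    bf_clean <- matrix(config$bf_background, nr, nc)
    for (i in seq_len(nrow(cells))) {
      r <- cells$radius[i]; w <- config$ring_width
      bf_clean <- paint_disk(bf_clean, cells$row[i], cells$col[i], r + w,
        function(block, d) {
          block[d <= r + w] <- config$bf_background - config$interior_dim
          block[d > r - w & d <= r + w] <- config$bf_background - config$boundary_dark
          block
        })
    }

    # clean cytosolic GFP image (identical across planes); fluorescence
    # fills the cell out to the outer edge of the wall that forms the dark
    # bright-field ring, i.e. slightly beyond the segmented footprint
    gfp_cyto <- matrix(0, nr, nc)
    for (i in seq_len(nrow(cells))) {
      r <- cells$radius[i] + config$ring_width + config$gfp_bleed
      lev <- cells$cyto_level[i]
      gfp_cyto <- paint_disk(gfp_cyto, cells$row[i], cells$col[i], r,
        function(block, d) { block[d <= r] <- block[d <= r] + lev; block })
    }

    # punctate foci: each lives on one z plane, inside its cell
    foci <- if (nrow(cells) > 0L && config$n_foci > 0L) {
      do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
        ang <- stats::runif(config$n_foci, 0, 2 * pi)
        rad <- stats::runif(config$n_foci, 0, 0.55 * cells$radius[i])
        data.frame(cell = cells$id[i],
                   row = cells$row[i] + rad * sin(ang),
                   col = cells$col[i] + rad * cos(ang),
                   plane = sample.int(np, config$n_foci, replace = TRUE),
                   amplitude = config$focus_amplitude *
                     stats::runif(config$n_foci, 0.7, 1.3))
      }))
    } else {
      data.frame(cell = integer(0L), row = numeric(0L), col = numeric(0L),
                 plane = integer(0L), amplitude = numeric(0L))
    }

    clip <- function(x) pmin(pmax(x, 0), config$saturation)
    bf <- array(0, dim = c(nr, nc, np))
    gfp <- array(0, dim = c(nr, nc, np))
    for (p in seq_len(np)) {
      dz <- abs(p - focal)
      plane_bf <- if (dz == 0L) bf_clean else {
        as.matrix(EBImage::gblur(bf_clean, sigma = config$blur_sigma * dz))
      }
      bf[, , p] <- clip(plane_bf + stats::rnorm(nr * nc, 0, config$noise_sd))
      plane_gfp <- gfp_cyto
      sel <- which(foci$plane == p)
      for (j in sel) {
        s <- config$focus_sigma
        plane_gfp <- paint_disk(plane_gfp, foci$row[j], foci$col[j], 4 * s,
          function(block, d) block + foci$amplitude[j] * exp(-d^2 / (2 * s^2)))
      }
      gfp[, , p] <- clip(plane_gfp + stats::rnorm(nr * nc, 0, config$noise_sd))
    }
    list(brightfield = bf, gfp = gfp, cells = cells, foci = foci,
         focal_plane = focal)
  })
}

#' Write a simulated image pair to disk
#'
#' Writes the two stacks as multi-page grayscale TIFFs plus a ground-truth
#' CSV (`id,row,col,radius,cyto_level`; positions in 1-based pixel
#' coordinates of the array).
#'
#' @param sim output of [generate_image_pair()]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix (default `"field"`)
#' @param saturation intensity scale for TIFF storage (default 255)
#' @return named character vector of the three paths, invisibly
#' @export
write_image_pair <- function(sim, dir, prefix = "field", saturation = 255) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    brightfield = file.path(dir, paste0(prefix, "_brightfield.tif")),
    gfp = file.path(dir, paste0(prefix, "_gfp.tif")),
    truth = file.path(dir, paste0(prefix, "_truth.csv")))
  write_stack_tiff(sim$brightfield, paths[["brightfield"]], scale = saturation)
  write_stack_tiff(sim$gfp, paths[["gfp"]], scale = saturation)
  utils::write.csv(sim$cells, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' Configuration for the synthetic phosphopeptide-evidence generator
#'
#' @param protein_length protein length in residues
#' @param true_sites integer positions of the true phosphosites
#' @param proteases protease labels used (default all three digests)
#' @param detect_prob probability that a true site is observed in a given
#'   protease digest; scalar or one value per protease (default 1)
#' @param true_locprob_range localization probabilities of true-site
#'   observations are drawn uniformly from this range (default
#'   `c(0.95, 1)`, i.e. all pass the reporting filter)
#' @param spurious_locprob_range range for spurious observations (default
#'   `c(0.50, 0.94)`, below the filter)
#' @param n_spurious number of spurious single-site records (default 5)
#' @param pep_range PEP values drawn uniformly from this range (default
#'   `c(0.0001, 0.009)`)
#' @param seed random seed
#' @return object of class `evidence_sim_config`
#' @export
evidence_sim_config <- function(protein_length = 341L,
                                true_sites = integer(0L),
                                proteases = c("aspn", "lysc", "trypsin"),
                                detect_prob = 1,
                                true_locprob_range = c(0.95, 1),
                                spurious_locprob_range = c(0.50, 0.94),
                                n_spurious = 5L,
                                pep_range = c(0.0001, 0.009),
                                seed = 1L) {
  stopifnot(protein_length >= 1L)
  true_sites <- as.integer(true_sites)
  if (any(true_sites < 1L) || any(true_sites > protein_length)) {
    stop("true site positions must lie within the protein (1..",
         protein_length, ")")
  }
  if (length(detect_prob) == 1L) {
    detect_prob <- rep(detect_prob, length(proteases))
  }
  stopifnot(length(detect_prob) == length(proteases),
            all(detect_prob >= 0), all(detect_prob <= 1))
  structure(as.list(environment()), class = "evidence_sim_config")
}

sim_window <- function(seq_chars, pos, half = 6L) {
  n <- length(seq_chars)
  idx <- (pos - half):(pos + half)
  w <- ifelse(idx >= 1L & idx <= n, seq_chars[pmax(pmin(idx, n), 1L)], "_")
  w[half + 1L] <- paste0("p", seq_chars[pos])
  paste(w, collapse = "")
}

#' Generate a synthetic phosphopeptide-evidence table
#'
#' Each true site yields one single-site record per protease with the
#' configured detection probability and a localization probability drawn
#' from the true-site range; spurious records are drawn at random
#' non-true positions with localization probabilities below the filter.
#' A random protein sequence (with S/T forced at the phosphosites)
#' supplies residue letters and sequence windows.
#'
#' @param config an [evidence_sim_config()]
#' @return evidence data frame (see [read_evidence()]) with an extra
#'   `true_site` logical column
#' @export
generate_evidence_table <- function(config) {
  stopifnot(inherits(config, "evidence_sim_config"))
  with_seed(config$seed, {
    n <- config$protein_length
    seq_chars <- sample(names(AA_MONO), n, replace = TRUE)
    seq_chars[config$true_sites] <-
      sample(c("S", "T"), length(config$true_sites), replace = TRUE,
             prob = c(0.8, 0.2))
    rows <- list()
    for (k in seq_along(config$proteases)) {
      for (s in config$true_sites) {
        if (stats::runif(1L) > config$detect_prob[k]) next
        rows[[length(rows) + 1L]] <- data.frame(
          window = sim_window(seq_chars, s),
          positions = as.character(s), residues = seq_chars[s],
          protease = config$proteases[k],
          loc_probs = sprintf("%.4f", stats::runif(1L,
            config$true_locprob_range[1L], config$true_locprob_range[2L])),
          pep = stats::runif(1L, config$pep_range[1L], config$pep_range[2L]),
          true_site = TRUE, stringsAsFactors = FALSE)
      }
    }
    candidates <- setdiff(which(seq_chars %in% c("S", "T", "Y")),
                          config$true_sites)
    n_spur <- min(config$n_spurious, length(candidates))
    if (n_spur > 0L) {
      spur <- sample(candidates, n_spur)
      for (s in spur) {
        rows[[length(rows) + 1L]] <- data.frame(
          window = sim_window(seq_chars, s),
          positions = as.character(s), residues = seq_chars[s],
          protease = sample(config$proteases, 1L),
          loc_probs = sprintf("%.4f", stats::runif(1L,
            config$spurious_locprob_range[1L],
            config$spurious_locprob_range[2L])),
          pep = stats::runif(1L, config$pep_range[1L], config$pep_range[2L]),
          true_site = FALSE, stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(window = character(0L), positions = character(0L),
                        residues = character(0L), protease = character(0L),
                        loc_probs = character(0L), pep = numeric(0L),
                        true_site = logical(0L), stringsAsFactors = FALSE))
    }
    ev <- do.call(rbind, rows)
    rownames(ev) <- NULL
    ev
  })
}

#' Generate a synthetic protein-by-replicate iBAQ table
#'
#' Raw iBAQ intensities are drawn log-normally per protein (a common shape
#' for protein abundances in affinity-purified eluates), with the bait set
#' an order of magnitude above the prey median, and independent
#' multiplicative replicate noise.
#'
#' @param n_proteins number of proteins including the bait
#' @param bait_id bait protein identifier (default `"PEX14"`)
#' @param replicate_count number of replicates (default 2)
#' @param seed random seed
#' @param protein_ids optional explicit identifiers; must contain
#'   `bait_id`
#' @return numeric matrix proteins x replicates of strictly positive raw
#'   intensities, with `dimnames`
#' @export
generate_ibaq_table <- function(n_proteins = 50L, bait_id = "PEX14",
                                replicate_count = 2L, seed = 1L,
                                protein_ids = NULL) {
  stopifnot(n_proteins >= 1L, replicate_count >= 1L)
  if (is.null(protein_ids)) {
    protein_ids <- c(bait_id,
                     sprintf("PROT%03d", seq_len(n_proteins - 1L)))
  }
  if (!bait_id %in% protein_ids) {
    stop("bait '", bait_id, "' is not among the protein identifiers")
  }
  with_seed(seed, {
    base <- stats::rlnorm(length(protein_ids), meanlog = 20, sdlog = 1.5)
    base[protein_ids == bait_id] <-
      stats::rlnorm(1L, meanlog = 23, sdlog = 0.3)
    mat <- vapply(seq_len(replicate_count), function(j) {
      base * stats::rlnorm(length(protein_ids), 0, 0.25)
    }, numeric(length(protein_ids)))
    mat <- matrix(mat, nrow = length(protein_ids),
                  dimnames = list(protein_ids,
                                  paste0("replicate_", seq_len(replicate_count))))
    mat
  })
}
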