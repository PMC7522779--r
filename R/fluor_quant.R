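#' False-positive filter parameters
#'
#' Segmented rectangles are discarded as false positives when either side
#' ("axis") of the bounding rectangle exceeds 100 pixels or falls below
#' 40 pixels, when the GFP crop reaches the detector maximum (255 on the
#' 8-bit scale, i.e. saturated), when the crop's intensity standard
#' deviation is below 5 (featureless, likely not a cell), or when the
#' rectangle lies within a border band of 5\% of the image size (cell
#' likely truncated).
#'
#' @param max_axis maximum rectangle side in pixels (default 100)
#' @param min_axis minimum rectangle side in pixels (default 40)
#' @param saturation saturation intensity (default 255)
#' @param min_sd minimum intensity standard deviation (default 5)
#' @param border_margin border band width as a fraction of each image
#'   dimension (default 0.05)
#' @return object of class `filter_params`
#' @export
filter_params <- function(max_axis = 100L, min_axis = 40L, saturation = 255,
                          min_sd = 5, border_margin = 0.05) {
  stopifnot(min_axis < max_axis, min_axis > 0L,
            border_margin >= 0, border_margin < 0.5)
  structure(list(max_axis = max_axis, min_axis = min_axis,
                 saturation = saturation, min_sd = min_sd,
                 border_margin = border_margin),
            class = "filter_params")
}

#' Quantification parameters
#'
#' The cytosolic GFP level of a cell is estimated as a lower quantile of
#' all pixel intensities in its rectangle (default: 25th percentile,
#' linear interpolation), the background as the mean of the lowest
#' fraction of intensities (default 10\%), and the reported value is
#' quantile minus background. Per-strain centering is applied for
#' visualization; between-strain tests run on uncentered corrected values
#' (centering every strain to its own median would null exactly the
#' location difference being tested).
#'
#' @param quantile_p lower quantile used as the cytosolic surrogate
#'   (default 0.25)
#' @param background_fraction fraction of lowest intensities averaged as
#'   background (default 0.10)
#' @param centering `"none"`, `"subtract-median"` or `"divide-median"`,
#'   applied per strain to the corrected values (default
#'   `"subtract-median"`)
#' @return object of class `quant_params`
#' @export
quant_params <- function(quantile_p = 0.25, background_fraction = 0.10,
                         centering = c("subtract-median", "none",
                                       "divide-median")) {
  centering <- match.arg(centering)
  stopifnot(quantile_p > 0, quantile_p < 1,
            background_fraction > 0, background_fraction < 1)
  structure(list(quantile_p = quantile_p,
                 background_fraction = background_fraction,
                 centering = centering),
            class = "quant_params")
}

crop_rect <- function(image, region) {
  # region rectangles are 0-based half-open; R indexing is 1-based inclusive
  image[(region$row_min + 1L):region$row_max,
        (region$col_min + 1L):region$col_max, drop = FALSE]
}

#' Flag false-positive cell rectangles on a GFP projection
#'
#' Applies the size, saturation, variance and border rules of
#' [filter_params()]. All removal reasons are recorded per region;
#' filtering is idempotent (re-filtering the kept set removes nothing).
#'
#' @param regions `cell_regions` data frame (see [segment_cells()])
#' @param projection 2D GFP maximum-intensity projection
#' @param params a [filter_params()] object
#' @return list with `kept` (subset of `regions`) and `flags` (one row
#'   per input region: `label`, logical `oversize`, `undersize`,
#'   `saturated`, `low_sd`, `border`, `kept`)
#' @export
filter_false_positives <- function(regions, projection,
                                   params = filter_params()) {
  nr <- nrow(projection); nc <- ncol(projection)
  if (nrow(regions) == 0L) {
    return(list(kept = regions,
                flags = data.frame(label = integer(0L), oversize = logical(0L),
                                   undersize = logical(0L),
                                   saturated = logical(0L),
                                   low_sd = logical(0L), border = logical(0L),
                                   kept = logical(0L))))
  }
  if (any(regions$row_min < 0L) || any(regions$col_min < 0L) ||
      any(regions$row_max > nr) || any(regions$col_max > nc)) {
    stop("region rectangle outside the projection")
  }
  h <- regions$row_max - regions$row_min
  w <- regions$col_max - regions$col_min
  oversize <- h > params$max_axis | w > params$max_axis
  undersize <- h < params$min_axis | w < params$min_axis
  saturated <- logical(nrow(regions))
  low_sd <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    crop <- crop_rect(projection, regions[i, ])
    saturated[i] <- max(crop) >= params$saturation
    low_sd[i] <- stats::sd(as.vector(crop)) < params$min_sd
  }
  mr <- params$border_margin * nr
  mc <- params$border_margin * nc
  border <- regions$row_min < mr | regions$col_min < mc |
    regions$row_max > nr - mr | regions$col_max > nc - mc
  kept <- !(oversize | undersize | saturated | low_sd | border)
  list(kept = regions[kept, , drop = FALSE],
       flags = data.frame(label = regions$label, oversize = oversize,
                          undersize = undersize, saturated = saturated,
                          low_sd = low_sd, border = border, kept = kept))
}

#' Cytosolic intensity of one cell crop
#'
#' @param crop numeric matrix (or vector) of GFP intensities inside the
#'   cell rectangle
#' @param params a [quant_params()] object
#' @return named numeric vector `raw` (lower quantile of all crop
#'   intensities, linear interpolation), `background` (mean of the lowest
#'   `background_fraction` of intensities) and `corrected`
#'   (`raw - background`; invariant under a global additive offset)
#' @examples
#' cytosolic_intensity(matrix(0:99, 10))  # raw 24.75, background 4.5
#' @export
cytosolic_intensity <- function(crop, params = quant_params()) {
  v <- as.numeric(crop)
  if (length(v) == 0L) stop("empty crop")
  raw <- unname(stats::quantile(v, params$quantile_p, type = 7))
  k <- max(1L, floor(length(v) * params$background_fraction))
  background <- mean(sort(v)[seq_len(k)])
  c(raw = raw, background = background, corrected = raw - background)
}

#' Quantify cytosolic GFP per cell for one strain
#'
#' End-to-end single-strain analysis: select the best-focused bright-field
#' slice, segment cells, project the GFP stack, map cell rectangles onto
#' the projection, discard false positives, and compute the per-cell
#' corrected cytosolic intensity. The configured centering is applied
#' across all kept cells of the strain.
#'
#' @param pairs list of image pairs; each element is a list with
#'   `brightfield` and `gfp` 3D stacks of identical shape (e.g. output of
#'   [generate_image_pair()])
#' @param strain strain label recorded in the output
#' @param seg_params [segmentation_params()]
#' @param fp_params [filter_params()]
#' @param q_params [quant_params()]
#' @return list with `measurements` (data frame: `strain`, `image`,
#'   `label`, `raw`, `background`, `corrected`, `centered`), `flags`
#'   (per-region filter flags across all images) and `summary` (one-row
#'   data frame: `strain`, `n`, `median_corrected`, `note`)
#' @export
quantify_strain <- function(pairs, strain = "strain",
                            seg_params = segmentation_params(),
                            fp_params = filter_params(),
                            q_params = quant_params()) {
  if (length(pairs) == 0L) stop("at least one image pair is required")
  meas <- list(); flags <- list()
  for (im in seq_along(pairs)) {
    bf <- as_image_stack(pairs[[im]]$brightfield)
    gf <- as_image_stack(pairs[[im]]$gfp)
    if (!all(dim(bf) == dim(gf))) {
      stop("bright-field and GFP stacks of image ", im, " differ in shape")
    }
    slice <- select_brightfield_slice(bf)
    regions <- segment_cells(bf[, , slice], seg_params)
    proj <- max_projection(gf)
    fp <- filter_false_positives(regions, proj, fp_params)
    if (nrow(fp$flags) > 0L) {
      flags[[length(flags) + 1L]] <- cbind(image = im, fp$flags)
    }
    for (i in seq_len(nrow(fp$kept))) {
      ci <- cytosolic_intensity(crop_rect(proj, fp$kept[i, ]), q_params)
      meas[[length(meas) + 1L]] <- data.frame(
        strain = strain, image = im, label = fp$kept$label[i],
        raw = ci[["raw"]], background = ci[["background"]],
        corrected = ci[["corrected"]], stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags) > 0L) do.call(rbind, flags) else
    data.frame(image = integer(0L), label = integer(0L))
  if (length(meas) == 0L) {
    return(list(
      measurements = data.frame(strain = character(0L), image = integer(0L),
                                label = integer(0L), raw = numeric(0L),
                                background = numeric(0L),
                                corrected = numeric(0L),
                                centered = numeric(0L)),
      flags = flags,
      summary = data.frame(strain = strain, n = 0L,
                           median_corrected = NA_real_, note = "no cells")))
  }
  m <- do.call(rbind, meas)
  med <- stats::median(m$corrected)
  m$centered <- switch(q_params$centering,
    "none" = m$corrected,
    "subtract-median" = m$corrected - med,
    "divide-median" = m$corrected / med)
  rownames(m) <- NULL
  list(measurements = m, flags = flags,
       summary = data.frame(strain = strain, n = nrow(m),
                            median_corrected = med, note = ""))
}
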