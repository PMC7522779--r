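#' Segmentation parameters
#'
#' Bright-field cell segmentation follows a four-step recipe: binary
#' thresholding, removal of small objects (< 300 pixels), morphological
#' closing of small openings (disk of radius 5 pixels), and filling of
#' open holes. The steps are applied in exactly that order; closing
#' before small-object removal gives different results.
#'
#' @param threshold `"otsu"` (default, adaptive) or `"fixed"`
#' @param threshold_value threshold intensity when `threshold = "fixed"`
#' @param min_area minimum object area in pixels (default 300); smaller
#'   connected components of the raw binarization are discarded
#' @param closing_radius radius of the closing disk in pixels (default 5);
#'   0 disables closing
#' @param fill_holes fill enclosed holes after closing (default `TRUE`)
#' @param dark_cells if `TRUE` (default) cells are the below-threshold
#'   (dark) phase, matching bright-field images in which cell boundaries
#'   appear dark on a bright background; set `FALSE` to invert
#' @return object of class `segmentation_params`
#' @export
segmentation_params <- function(threshold = c("otsu", "fixed"),
                                threshold_value = NULL,
                                min_area = 300L, closing_radius = 5L,
                                fill_holes = TRUE, dark_cells = TRUE) {
  threshold <- match.arg(threshold)
  if (threshold == "fixed" && is.null(threshold_value)) {
    stop("threshold_value is required when threshold = \"fixed\"")
  }
  stopifnot(min_area > 0L, closing_radius >= 0L)
  structure(
    list(threshold = threshold, threshold_value = threshold_value,
         min_area = as.integer(min_area),
         closing_radius = as.integer(closing_radius),
         fill_holes = isTRUE(fill_holes), dark_cells = isTRUE(dark_cells)),
    class = "segmentation_params")
}

# connected-component labelling with small-object removal
drop_small <- function(mask, min_area) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Segment cells in a bright-field image
#'
#' Binarizes the image (Otsu by default; cells are the darker phase),
#' removes connected components below `min_area`, closes small openings
#' with a disk-shaped structuring element, fills holes, and labels the
#' result. Regions are returned with pixel areas and axis-aligned
#' bounding rectangles in 0-based, half-open coordinates
#' (`row_min <= row < row_max`).
#'
#' @param image 2D numeric matrix (a single bright-field slice)
#' @param params a [segmentation_params()] object
#' @return data frame of class `cell_regions`: `label`, `area`,
#'   `row_min`, `col_min`, `row_max`, `col_max` (0-based half-open),
#'   ordered by label
#' @examples
#' sim <- generate_image_pair(image_sim_config(n_cells = 3, seed = 2))
#' slice <- sim$brightfield[, , sim$focal_plane]
#' segment_cells(slice)
#' @export
segment_cells <- function(image, params = segmentation_params()) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2D numeric matrix")
  }
  if (length(image) == 0L) stop("empty image")

  empty <- data.frame(label = integer(0L), area = integer(0L),
                      row_min = integer(0L), col_min = integer(0L),
                      row_max = integer(0L), col_max = integer(0L))
  class(empty) <- c("cell_regions", "data.frame")

  rng <- range(image)
  if (rng[1L] == rng[2L]) return(empty)    # uniform image: nothing to segment

  th <- if (params$threshold == "otsu") {
    # Otsu on the min-max normalized histogram, mapped back to intensity
    # units; invariant under affine intensity changes by construction
    scaled <- (image - rng[1L]) / (rng[2L] - rng[1L])
    rng[1L] + EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) *
      (rng[2L] - rng[1L])
  } else {
    params$threshold_value
  }
  mask <- if (params$dark_cells) image < th else image > th
  if (!any(mask)) return(empty)

  mask <- drop_small(mask, params$min_area)
  if (params$closing_radius > 0L) {
    brush <- EBImage::makeBrush(2L * params$closing_radius + 1L, "disc")
    mask <- EBImage::closing(mask, brush) > 0
  }
  if (params$fill_holes) mask <- EBImage::fillHull(mask) > 0
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0L) return(empty)

  idx <- which(lab > 0L)
  coords <- arrayInd(idx, dim(lab))
  labv <- lab[idx]
  area <- tabulate(labv, nbins = n)
  rmin <- vapply(split(coords[, 1L], labv), min, numeric(1L))
  rmax <- vapply(split(coords[, 1L], labv), max, numeric(1L))
  cmin <- vapply(split(coords[, 2L], labv), min, numeric(1L))
  cmax <- vapply(split(coords[, 2L], labv), max, numeric(1L))
  out <- data.frame(label = seq_len(n), area = area,
                    row_min = as.integer(rmin) - 1L,
                    col_min = as.integer(cmin) - 1L,
                    row_max = as.integer(rmax),      # half-open upper bound
                    col_max = as.integer(cmax))
  class(out) <- c("cell_regions", "data.frame")
  out
}

#' Write segmented regions as CSV
#'
#' Coordinates are 0-based, half-open rectangles (`row_min <= row <
#' row_max`), stated in a comment header.
#'
#' @param regions `cell_regions` data frame from [segment_cells()]
#' @param path output path
#' @param image_id identifier recorded with each row (default `""`)
#' @return `path`, invisibly
#' @export
write_regions_csv <- function(regions, path, image_id = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# bounding rectangles are 0-based, half-open:",
                   "row_min <= row < row_max, col_min <= col < col_max"), con)
  df <- cbind(image = image_id, as.data.frame(regions))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
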