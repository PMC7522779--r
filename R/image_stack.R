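#' Image stacks
#'
#' A stack is a 3D numeric array `[row, col, plane]` of grayscale
#' intensities on the detector scale (0-255 for the default 8-bit
#' configuration). Helper constructors/readers keep that convention.
#'
#' @param x numeric 3D array or a matrix (treated as a single plane)
#' @return validated 3D array
#' @export
as_image_stack <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L || !is.numeric(x)) {
    stop("an image stack must be a numeric [row, col, plane] array")
  }
  if (any(dim(x) == 0L)) stop("empty image stack")
  x
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' @param path TIFF file
#' @param scale intensity scale factor applied to the `[0, 1]` values
#'   returned by the TIFF reader (default 255, i.e. 8-bit counts)
#' @return 3D array `[row, col, plane]`
#' @export
read_stack_tiff <- function(path, scale = 255) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 0L) stop("no pages in ", path)
  arr <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # collapse RGB written as gray
    arr[, , i] <- p * scale
  }
  arr
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' @param stack 3D array `[row, col, plane]`
#' @param path output path
#' @param scale divisor mapping intensities into `[0, 1]` for storage
#'   (default 255)
#' @param bits.per.sample sample depth in the file (default 8)
#' @return `path`, invisibly
#' @export
write_stack_tiff <- function(stack, path, scale = 255, bits.per.sample = 8L) {
  stack <- as_image_stack(stack)
  pages <- lapply(seq_len(dim(stack)[3L]), function(i) {
    pmin(pmax(stack[, , i] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits.per.sample)
  invisible(path)
}

#' Maximum-intensity z-projection
#'
#' Collapses a z-stack to a 2D image by the per-pixel maximum over planes.
#'
#' @param stack 3D array `[row, col, plane]` (or a matrix, returned as is)
#' @return matrix with the stack's spatial dimensions
#' @export
max_projection <- function(stack) {
  stack <- as_image_stack(stack)
  out <- stack[, , 1L]
  np <- dim(stack)[3L]
  if (np > 1L) for (i in 2L:np) out <- pmax(out, stack[, , i])
  out
}

#' Pick the best-focused bright-field plane
#'
#' Scores every plane by the variance of its gradient magnitude (computed
#' from first differences along rows and columns) and returns the argmax —
#' a proxy for the visual "best separation of individual cells" criterion
#' used when a focal slice is chosen by eye. An explicit override wins.
#'
#' @param stack 3D array `[row, col, plane]`
#' @param override optional 1-based plane index to force
#' @return 1-based plane index
#' @export
select_brightfield_slice <- function(stack, override = NULL) {
  stack <- as_image_stack(stack)
  np <- dim(stack)[3L]
  if (!is.null(override)) {
    override <- as.integer(override)
    if (override < 1L || override > np) {
      stop("slice override ", override, " outside 1..", np)
    }
    return(override)
  }
  scores <- vapply(seq_len(np), function(i) {
    focus_score(stack[, , i])
  }, numeric(1L))
  which.max(scores)
}

#' Focus score of a 2D image (variance of the gradient magnitude)
#' @param img matrix
#' @return scalar score; sharper images score higher
#' @keywords internal
focus_score <- function(img) {
  gr <- img[-1L, , drop = FALSE] - img[-nrow(img), , drop = FALSE]
  gc <- img[, -1L, drop = FALSE] - img[, -ncol(img), drop = FALSE]
  n <- min(nrow(gr), nrow(gc))
  m <- min(ncol(gr), ncol(gc))
  g <- sqrt(gr[seq_len(n), seq_len(m)]^2 + gc[seq_len(n), seq_len(m)]^2)
  stats::var(as.vector(g))
}
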