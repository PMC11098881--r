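#' Tissue labelmap
#'
#' A raster grid (2D slice or 3D volume) of integer tissue labels with
#' physical spacing in mm. Row 1 of a 2D slice is the transducer side;
#' depth increases with row index.
#'
#' @param grid Integer array, 2D or 3D. Every value must appear in `legend`.
#' @param spacing Numeric, mm per axis (length = number of dims), all > 0.
#'   A scalar is recycled.
#' @param origin Numeric mm offset of the grid corner (defaults to 0).
#' @param legend Named character vector mapping label integers (names) to
#'   tissue names; defaults to [default_legend()].
#' @return A `labelmap` object.
#' @examples
#' lm <- labelmap(matrix(7L, 32, 32), spacing = 0.5)
#' dim(lm$grid)
#' @export
labelmap <- function(grid, spacing, origin = NULL, legend = default_legend()) {
  if (!is.array(grid) && !is.matrix(grid)) stop("grid must be a matrix or array")
  nd <- length(dim(grid))
  if (!nd %in% c(2L, 3L)) stop("grid must be 2D or 3D")
  if (any(grid != round(grid))) stop("labelmap grid must hold integer labels")
  storage.mode(grid) <- "integer"
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  if (length(spacing) != nd || any(spacing <= 0))
    stop("spacing must be strictly positive, one value per axis")
  if (is.null(origin)) origin <- rep(0, nd)
  lm <- structure(list(grid = grid, spacing = as.numeric(spacing),
                       origin = as.numeric(origin), legend = legend),
                  class = "labelmap")
  validate_labelmap(lm)
  lm
}

validate_labelmap <- function(lm) {
  labs <- sort(unique(as.integer(lm$grid)))
  known <- as.integer(names(lm$legend))
  missing <- setdiff(labs, known)
  if (length(missing))
    stop("labelmap contains label(s) absent from legend: ",
         paste(missing, collapse = ", "))
  invisible(lm)
}

#' @export
print.labelmap <- function(x, ...) {
  cat("<labelmap> ", paste(dim(x$grid), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  labels: ",
      paste(sprintf("%s=%s", names(x$legend)[as.integer(names(x$legend)) %in%
                                               unique(as.integer(x$grid))],
                    x$legend[as.integer(names(x$legend)) %in%
                               unique(as.integer(x$grid))]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# label integer for a tissue name, from a legend
legend_label <- function(legend, tissue) {
  i <- which(legend == tissue)
  if (!length(i)) stop("legend has no '", tissue, "' tissue")
  as.integer(names(legend)[i[1]])
}

#' Ultrasound image container
#'
#' Scan-converted Cartesian image with pixel values in \[0, 1\], a fan-shaped
#' support mask and isotropic pixel spacing (mm). Pixels outside `fan_mask`
#' are exactly zero; row 1 is the transducer face.
#'
#' @param pixels Square numeric matrix in \[0, 1\].
#' @param pixel_spacing Pixel size in mm.
#' @param fan_mask Logical matrix, same shape as `pixels`.
#' @param mode One of `"IR"`, `"realistic"`, `"edge"`.
#' @return An `ultrasound_image` object.
#' @export
ultrasound_image <- function(pixels, pixel_spacing, fan_mask,
                             mode = c("IR", "realistic", "edge")) {
  mode <- match.arg(mode)
  if (nrow(pixels) != ncol(pixels)) stop("image must be square")
  if (!identical(dim(pixels), dim(fan_mask))) stop("fan_mask shape mismatch")
  pixels[!fan_mask] <- 0
  pixels <- pmin(pmax(pixels, 0), 1)
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 fan_mask = fan_mask, mode = mode),
            class = "ultrasound_image")
}

#' @export
print.ultrasound_image <- function(x, ...) {
  cat("<ultrasound_image> ", nrow(x$pixels), "x", ncol(x$pixels),
      " px, ", signif(x$pixel_spacing, 4), " mm/px, mode ", x$mode,
      ", ", round(100 * mean(x$fan_mask)), "% fan\n", sep = "")
  invisible(x)
}

#' Display an ultrasound image or labelmap slice
#'
#' @param x An `ultrasound_image` or 2D `labelmap`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.ultrasound_image <- function(x, ...) {
  px <- x$pixels
  graphics::image(t(px[nrow(px):1, ]), col = grey.colors(256, 0, 1),
                  asp = 1, axes = FALSE, ...)
  invisible(x)
}

#' @rdname plot.ultrasound_image
#' @export
plot.labelmap <- function(x, ...) {
  g <- x$grid
  if (length(dim(g)) == 3L) g <- g[, , 1]
  graphics::image(t(g[nrow(g):1, ]), col = grDevices::hcl.colors(
    max(g) - min(g) + 1, "viridis"), asp = 1, axes = FALSE, ...)
  invisible(x)
}
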