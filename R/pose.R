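#' Probe pose
#'
#' Position and orientation of the virtual transducer: a point in mm, the
#' unit beam axis (`direction`, pointing into the tissue) and the unit
#' in-plane axis spanning the imaging plane. The in-plane axis is
#' orthogonalized against the beam axis and both are normalized.
#'
#' @param position Numeric point, mm (length 2 or 3).
#' @param direction Beam axis (same length).
#' @param in_plane In-plane (lateral) axis; must not be parallel to
#'   `direction`.
#' @return A `probe_pose` object.
#' @export
probe_pose <- function(position, direction, in_plane = NULL) {
  nd <- length(position)
  if (is.null(in_plane)) {
    in_plane <- if (nd == 2L) c(direction[2], -direction[1]) else {
      # any axis least aligned with the beam
      basis <- diag(nd)[, which.min(abs(direction))]
      basis
    }
  }
  stopifnot(length(direction) == nd, length(in_plane) == nd)
  direction <- direction / sqrt(sum(direction^2))
  in_plane <- in_plane - sum(in_plane * direction) * direction
  n <- sqrt(sum(in_plane^2))
  if (n < 1e-9) stop("in_plane axis is parallel to the beam direction")
  structure(list(position = as.numeric(position),
                 direction = as.numeric(direction),
                 in_plane = as.numeric(in_plane / n)),
            class = "probe_pose")
}

#' Sample probe poses along an interpolating spline
#'
#' Interpolates positions with a natural cubic spline through the control
#' poses (component-wise) and directions by component-wise interpolation
#' followed by renormalization, then samples `n` poses at uniform parameter
#' values. Deterministic.
#'
#' @param control_points List of [probe_pose()] anchors (>= 1).
#' @param n Number of poses to sample (>= 1).
#' @return List of `n` `probe_pose` objects.
#' @export
sample_probe_poses <- function(control_points, n) {
  if (n < 1) stop("n must be >= 1")
  m <- length(control_points)
  if (m < 1) stop("at least one control point is required")
  if (m == 1L) return(rep(control_points, n))
  tt <- seq(0, 1, length.out = m)
  ts <- seq(0, 1, length.out = n)
  interp <- function(get) {
    comps <- sapply(control_points, get)            # nd x m
    t(apply(comps, 1, function(v) {
      if (m == 2L) stats::approx(tt, v, xout = ts)$y
      else stats::spline(tt, v, xout = ts, method = "natural")$y
    }))
  }
  pos <- interp(function(p) p$position)
  dir <- interp(function(p) p$direction)
  ipl <- interp(function(p) p$in_plane)
  lapply(seq_len(n), function(i)
    probe_pose(pos[, i], dir[, i], ipl[, i]))
}

#' Extract a 2D labelmap slice along a probe pose
#'
#' Resamples the plane spanned by the beam axis (depth, rows) and in-plane
#' axis (lateral, columns) by nearest-neighbour lookup, so no new labels
#' are invented. Samples outside the volume receive the Background label.
#' A 2D input with `pose = NULL` is returned unchanged.
#'
#' @param lm A [labelmap()] (2D or 3D).
#' @param pose A [probe_pose()]; `pose$position` is the physical location
#'   of the slice's top-center (row 1, middle column).
#' @param extent_mm Length-2 numeric: lateral width and depth of the slice
#'   in mm.
#' @param resolution Slice pixel size, mm.
#' @return A 2D [labelmap()] with origin `c(0, -width/2)` in the slice
#'   frame (rows = depth from the pose position, columns = lateral).
#' @export
extract_slice <- function(lm, pose = NULL, extent_mm = c(120, 120),
                          resolution = 0.5) {
  stopifnot(inherits(lm, "labelmap"))
  nd <- length(dim(lm$grid))
  if (nd == 2L && is.null(pose)) return(lm)
  if (is.null(pose)) stop("a probe pose is required for 3D volumes")
  width <- extent_mm[1]; depth <- extent_mm[2]
  ncol_s <- max(2L, round(width / resolution))
  nrow_s <- max(2L, round(depth / resolution))
  xs <- (seq_len(ncol_s) - 0.5) * resolution - width / 2   # lateral, mm
  zs <- (seq_len(nrow_s) - 0.5) * resolution               # depth, mm
  u <- pose$in_plane; v <- pose$direction; p0 <- pose$position
  # physical sample points: p0 + x*u + z*v, laid out (nrow_s*ncol_s) x nd
  grid_pts <- matrix(0, nrow_s * ncol_s, length(p0))
  zrep <- rep(zs, times = ncol_s)
  xrep <- rep(xs, each = nrow_s)
  for (a in seq_along(p0))
    grid_pts[, a] <- p0[a] + xrep * u[a] + zrep * v[a]
  dims <- dim(lm$grid)
  idx <- matrix(0L, nrow(grid_pts), nd)
  inside <- rep(TRUE, nrow(grid_pts))
  for (a in seq_len(nd)) {
    ia <- floor((grid_pts[, a] - lm$origin[a]) / lm$spacing[a]) + 1L
    inside <- inside & ia >= 1L & ia <= dims[a]
    idx[, a] <- pmin(pmax(ia, 1L), dims[a])
  }
  if (!any(inside)) stop("slice plane does not intersect the volume")
  vals <- lm$grid[idx]
  bg <- legend_label(lm$legend, "Background")
  vals[!inside] <- bg
  out <- matrix(vals, nrow_s, ncol_s)
  labelmap(out, spacing = resolution, origin = c(0, -width / 2),
           legend = lm$legend)
}
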