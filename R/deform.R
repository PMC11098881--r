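#' AAA size classes
#'
#' Clinical size classes of abdominal aortic aneurysm by maximal diameter:
#' small 30-45 mm, medium 45-55 mm, large above 55 mm (capped at 70 mm for
#' synthesis).
#'
#' @return Named list of length-2 diameter intervals (mm).
#' @export
aaa_classes <- function() {
  list(small = c(30, 45), medium = c(45, 55), large = c(55, 70))
}

#' Dilate the aorta cross-section to a target diameter
#'
#' Scales the blood-labelled aorta about its centroid so that its
#' anterior-posterior diameter equals `target_diameter` within one pixel.
#' Only dilation is supported (aneurysms grow).
#'
#' @param lm A 2D [labelmap()] containing a Blood-labelled aorta.
#' @param target_diameter Target AP diameter, mm (>= current diameter).
#' @return Logical mask of the dilated aorta on the labelmap grid.
#' @export
dilate_aorta_mask <- function(lm, target_diameter) {
  stopifnot(inherits(lm, "labelmap"), length(dim(lm$grid)) == 2L)
  blood <- legend_label(lm$legend, "Blood")
  src <- largest_component(lm$grid == blood)
  if (!any(src)) stop("labelmap contains no Blood-labelled aorta")
  sp <- lm$spacing
  d0 <- ap_diameter(src, sp[1])
  if (target_diameter < d0 - sp[1])
    stop("target diameter (", target_diameter,
         " mm) is smaller than the current diameter (", round(d0, 2),
         " mm); only dilation is supported")
  s <- target_diameter / d0
  ctr <- mask_centroid_mm(src, lm)
  # inverse scaling lookup about the centroid (nearest neighbour)
  pc <- pixel_centers_mm(lm)
  qz <- ctr[1] + (pc$Z - ctr[1]) / s
  qx <- ctr[2] + (pc$X - ctr[2]) / s
  lookup_mask(src, lm, qz, qx)
}

mask_centroid_mm <- function(mask, lm) {
  idx <- which(mask, arr.ind = TRUE)
  c((mean(idx[, 1]) - 0.5) * lm$spacing[1] + lm$origin[1],
    (mean(idx[, 2]) - 0.5) * lm$spacing[2] + lm$origin[2])
}

pixel_centers_mm <- function(lm) {
  d <- dim(lm$grid)
  zc <- (seq_len(d[1]) - 0.5) * lm$spacing[1] + lm$origin[1]
  xc <- (seq_len(d[2]) - 0.5) * lm$spacing[2] + lm$origin[2]
  list(Z = matrix(zc, d[1], d[2]), X = matrix(xc, d[1], d[2], byrow = TRUE))
}

lookup_mask <- function(mask, lm, qz, qx) {
  d <- dim(mask)
  ri <- floor((qz - lm$origin[1]) / lm$spacing[1]) + 1
  ci <- floor((qx - lm$origin[2]) / lm$spacing[2]) + 1
  inside <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
  out <- matrix(FALSE, d[1], d[2])
  out[inside] <- mask[cbind(ri[inside], ci[inside])]
  out
}

contour_pixels <- function(mask) {
  d <- dim(mask)
  er <- mask
  er[-1, ] <- er[-1, ] & mask[-d[1], ]
  er[-d[1], ] <- er[-d[1], ] & mask[-1, ]
  er[, -1] <- er[, -1] & mask[, -d[2]]
  er[, -d[2]] <- er[, -d[2]] & mask[, -1]
  er[1, ] <- FALSE; er[d[1], ] <- FALSE; er[, 1] <- FALSE; er[, d[2]] <- FALSE
  mask & !er
}

#' Estimate the dense deformation between a healthy and a dilated aorta
#'
#' Builds a dense displacement field (the aneurysm deformation) from
#' paired boundary samples of the source and dilated aorta masks (radial
#' correspondence about the centroid), zero-displacement constraints on
#' the rigid spine surface and on the grid border, interpolated with a
#' thin-plate-spline radial basis function. The interpolant reproduces all
#' control displacements exactly, and the returned field is exactly zero
#' on every rigid voxel.
#'
#' @param src_mask,dst_mask Logical masks on the same grid; `src_mask`
#'   must be contained in `dst_mask` (dilation).
#' @param rigid_mask Logical mask of rigid voxels (the spine); must not
#'   intersect `dst_mask`.
#' @param lm The [labelmap()] supplying grid spacing and origin.
#' @param control_stride Keep every n-th source-boundary pixel as a
#'   control point (default 4).
#' @param rigid_stride Keep every n-th rigid-surface pixel as a zero
#'   constraint (default 8).
#' @param n_border Zero constraints on the grid border (default 16).
#' @return A `deformation_field`: list with `dz`, `dx` (mm displacement
#'   matrices, forward: healthy to aneurysm), `spacing`, `origin`.
#' @export
estimate_deformation <- function(src_mask, dst_mask, rigid_mask, lm,
                                 control_stride = 4L, rigid_stride = 8L,
                                 n_border = 16L) {
  if (!any(src_mask) || !any(dst_mask)) stop("empty source or target mask")
  if (!identical(dim(src_mask), dim(dst_mask)))
    stop("masks are on different grids")
  if (any(src_mask & !dst_mask))
    stop("source mask is not contained in the target mask")
  if (any(rigid_mask & dst_mask))
    stop("rigid mask overlaps the dilated aorta: inconsistent constraints")

  sp <- lm$spacing; org <- lm$origin
  ctr <- mask_centroid_mm(src_mask, lm)
  to_mm <- function(idx) cbind((idx[, 1] - 0.5) * sp[1] + org[1],
                               (idx[, 2] - 0.5) * sp[2] + org[2])
  src_b <- to_mm(which(contour_pixels(src_mask), arr.ind = TRUE))
  dst_b <- to_mm(which(contour_pixels(dst_mask), arr.ind = TRUE))
  ang_s <- atan2(src_b[, 2] - ctr[2], src_b[, 1] - ctr[1])
  rad_s <- sqrt(rowSums(sweep(src_b, 2, ctr)^2))
  ang_d <- atan2(dst_b[, 2] - ctr[2], dst_b[, 1] - ctr[1])
  rad_d <- sqrt(rowSums(sweep(dst_b, 2, ctr)^2))
  ord <- order(ang_s)
  keep <- ord[seq(1, length(ord), by = control_stride)]
  # radial correspondence: for each kept source-boundary angle, the target
  # radius at the nearest target-boundary angle
  nearest_dst <- vapply(ang_s[keep], function(a) {
    dd <- abs(ang_d - a)
    which.min(pmin(dd, 2 * pi - dd))
  }, integer(1))
  disp_mag <- rad_d[nearest_dst] - rad_s[keep]
  ur <- cbind(cos(ang_s[keep]), sin(ang_s[keep]))   # unit radial (z, x)
  pts <- src_b[keep, , drop = FALSE]
  disp <- ur * disp_mag

  zero_pts <- NULL
  if (any(rigid_mask)) {
    rb <- to_mm(which(contour_pixels(rigid_mask), arr.ind = TRUE))
    zero_pts <- rb[seq(1, nrow(rb), by = rigid_stride), , drop = FALSE]
  }
  d <- dim(src_mask)
  ext <- c(d[1] * sp[1], d[2] * sp[2])
  per_side <- max(1L, n_border %/% 4L)
  bs <- seq(0, 1, length.out = per_side + 2)[-c(1, per_side + 2)]
  border <- rbind(cbind(org[1], org[2] + bs * ext[2]),
                  cbind(org[1] + ext[1], org[2] + bs * ext[2]),
                  cbind(org[1] + bs * ext[1], org[2]),
                  cbind(org[1] + bs * ext[1], org[2] + ext[2]))
  pts_all <- rbind(pts, zero_pts, border)
  val_all <- rbind(disp, matrix(0, nrow(pts_all) - nrow(pts), 2))
  dup <- duplicated(round(pts_all, 9))
  fit <- tps_fit(pts_all[!dup, , drop = FALSE], val_all[!dup, , drop = FALSE])

  pc <- pixel_centers_mm(lm)
  q <- cbind(as.numeric(pc$Z), as.numeric(pc$X))
  dv <- tps_eval(fit, q)
  dz <- matrix(dv[, 1], d[1], d[2])
  dx <- matrix(dv[, 2], d[1], d[2])
  dz[rigid_mask] <- 0
  dx[rigid_mask] <- 0
  structure(list(dz = dz, dx = dx, spacing = sp, origin = org,
                 tps = fit,
                 controls = list(pts = pts, disp = disp,
                                 zero_pts = rbind(zero_pts, border))),
            class = "deformation_field")
}

# interpolating 2D thin-plate spline, U(r) = r^2 log r, affine part [1 z x]
tps_fit <- function(pts, vals) {
  n <- nrow(pts)
  r2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  K <- ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)
  P <- cbind(1, pts)
  A <- rbind(cbind(K + diag(1e-9, n), P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(vals, matrix(0, 3, ncol(vals)))
  coef <- solve(A, rhs)
  list(pts = pts, w = coef[1:n, , drop = FALSE],
       a = coef[(n + 1):(n + 3), , drop = FALSE])
}

tps_eval <- function(fit, q, chunk = 20000L) {
  out <- matrix(0, nrow(q), ncol(fit$w))
  for (start in seq(1, nrow(q), by = chunk)) {
    i <- start:min(start + chunk - 1L, nrow(q))
    r2 <- outer(q[i, 1], fit$pts[, 1], "-")^2 +
          outer(q[i, 2], fit$pts[, 2], "-")^2
    U <- ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)
    out[i, ] <- U %*% fit$w + cbind(1, q[i, , drop = FALSE]) %*% fit$a
  }
  out
}

#' Evaluate a deformation field at arbitrary points
#'
#' @param field A `deformation_field`.
#' @param pts_mm Matrix of (depth, lateral) query points in mm.
#' @param exact Evaluate the underlying thin-plate-spline interpolant
#'   directly (exact at its control points) instead of the rasterized
#'   nearest-voxel lookup.
#' @return Matrix of (dz, dx) displacements in mm.
#' @export
eval_deformation <- function(field, pts_mm, exact = FALSE) {
  if (exact) {
    if (is.null(field$tps)) stop("field carries no interpolant")
    return(tps_eval(field$tps, pts_mm))
  }
  d <- dim(field$dz)
  ri <- pmin(pmax(floor((pts_mm[, 1] - field$origin[1]) / field$spacing[1]) + 1, 1), d[1])
  ci <- pmin(pmax(floor((pts_mm[, 2] - field$origin[2]) / field$spacing[2]) + 1, 1), d[2])
  cbind(dz = field$dz[cbind(ri, ci)], dx = field$dx[cbind(ri, ci)])
}

#' Warp a labelmap by a deformation field
#'
#' Backward warping with nearest-neighbour label lookup: the output label
#' at x is the input label at x - d(x), where d is the forward
#' displacement. No labels absent from the input can appear; samples
#' falling outside the grid become Background.
#'
#' @param lm A 2D [labelmap()].
#' @param field A `deformation_field` on the same grid.
#' @return The warped [labelmap()].
#' @export
apply_deformation <- function(lm, field) {
  stopifnot(inherits(lm, "labelmap"), inherits(field, "deformation_field"))
  if (!identical(dim(lm$grid), dim(field$dz)))
    stop("deformation field shape does not match the labelmap")
  pc <- pixel_centers_mm(lm)
  qz <- pc$Z - field$dz
  qx <- pc$X - field$dx
  d <- dim(lm$grid)
  ri <- floor((qz - lm$origin[1]) / lm$spacing[1]) + 1
  ci <- floor((qx - lm$origin[2]) / lm$spacing[2]) + 1
  inside <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
  out <- matrix(legend_label(lm$legend, "Background"), d[1], d[2])
  out[inside] <- lm$grid[cbind(ri[inside], ci[inside])]
  labelmap(out, spacing = lm$spacing, origin = lm$origin, legend = lm$legend)
}

#' Synthesize an abdominal aortic aneurysm in a labelmap
#'
#' Samples a target diameter in the requested size class, dilates the
#' aorta, estimates the surrounding deformation with a rigid spine
#' constraint, warps the labelmap and re-stamps the dilated aorta as
#' Blood. Spine voxels are guaranteed unchanged.
#'
#' @param lm A 2D [labelmap()] with Blood aorta and Bone spine.
#' @param cls One of `"small"`, `"medium"`, `"large"` (see
#'   [aaa_classes()]).
#' @param seed Integer seed for the diameter draw.
#' @return List with `labelmap` (deformed), `aorta_mask`, `diameter_mm`
#'   (measured AP diameter), `target_diameter` and `field`.
#' @examples
#' ph <- generate_phantom(phantom_config(seed = 3))
#' aaa <- synthesize_aaa(ph$labelmap, "medium", seed = 3)
#' aaa$diameter_mm
#' @export
synthesize_aaa <- function(lm, cls = c("small", "medium", "large"), seed = 1L) {
  cls <- match.arg(cls)
  interval <- aaa_classes()[[cls]]
  target <- withr::with_seed(seed, stats::runif(1, interval[1], interval[2]))
  blood <- legend_label(lm$legend, "Blood")
  bone <- legend_label(lm$legend, "Bone")
  src <- largest_component(lm$grid == blood)
  rigid <- lm$grid == bone
  dst <- dilate_aorta_mask(lm, target)
  field <- estimate_deformation(src, dst, rigid, lm)
  out <- apply_deformation(lm, field)
  g <- out$grid
  # rigidity: the zeroed field keeps bone in place; restore any stray pixel
  # that a neighbouring lookup pulled out of the spine
  stray <- g == bone & !rigid
  g[stray] <- lm$grid[stray]
  g[rigid] <- bone
  g[dst] <- blood
  out <- labelmap(g, spacing = lm$spacing, origin = lm$origin,
                  legend = lm$legend)
  list(labelmap = out, aorta_mask = dst,
       diameter_mm = ap_diameter(dst, lm$spacing[1]),
       target_diameter = target, field = field)
}
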