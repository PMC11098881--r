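#' Convex-fan beam geometry
#'
#' Geometry of the convex probe implied by [machine_params()]: the
#' transducer arc has radius `r0 = probe_width / (2 sin(angle/2))` about a
#' virtual apex above the skin; scan lines fan out at uniform angles over
#' the probe opening; the Cartesian output window is the square bounding
#' the fan at full depth (side `S = 2 (r0 + depth) sin(angle/2)`), so
#' `pixel_spacing = S / out_size`.
#'
#' @param mp A [machine_params()] list.
#' @param out_size Output image side in pixels.
#' @return List with `half` (rad), `r0`, `apex` (x, z mm), `phi` (line
#'   angles), `origin_x`/`origin_z`, `dir_x`/`dir_z` (per line), `delta`
#'   (axial step mm), `S` (window side mm), `pixel_spacing` and
#'   `analytic_fan_fraction` (annular-sector area over window area).
#' @export
fan_geometry <- function(mp = machine_params(), out_size = 256L) {
  half <- mp$probe_angle * pi / 360
  r0 <- mp$probe_width / (2 * sin(half))
  apex <- c(x = 0, z = -r0 * cos(half))
  phi <- seq(-half, half, length.out = mp$scan_lines)
  S <- 2 * (r0 + mp$image_depth) * sin(half)
  list(half = half, r0 = r0, apex = apex, phi = phi,
       origin_x = apex[["x"]] + r0 * sin(phi),
       origin_z = apex[["z"]] + r0 * cos(phi),
       dir_x = sin(phi), dir_z = cos(phi),
       delta = mp$image_depth / mp$axial_samples,
       S = S, pixel_spacing = S / out_size,
       analytic_fan_fraction =
         (2 * half / 2) * ((r0 + mp$image_depth)^2 - r0^2) / S^2)
}

# separable Gaussian smoothing with replicate padding
gauss_smooth <- function(img, sigma = 1) {
  r <- ceiling(3 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2)); w <- w / sum(w)
  d <- dim(img)
  acc <- matrix(0, d[1], d[2])
  for (i in seq_along(w)) {
    rows <- pmin(pmax(seq_len(d[1]) + (i - r - 1L), 1L), d[1])
    acc <- acc + w[i] * img[rows, , drop = FALSE]
  }
  out <- matrix(0, d[1], d[2])
  for (i in seq_along(w)) {
    cols <- pmin(pmax(seq_len(d[2]) + (i - r - 1L), 1L), d[2])
    out <- out + w[i] * acc[, cols, drop = FALSE]
  }
  out
}

# boundary normals from the gradient of a Gaussian-smoothed (sigma = 1 px)
# acoustic-impedance map; returns unit normal components and gradient norm
normal_map <- function(slice, tt) {
  Zv <- tissue_lookup(tt, "Z")
  Zimg <- matrix(Zv[slice$grid], nrow(slice$grid), ncol(slice$grid))
  Zs <- gauss_smooth(Zimg, 1)
  d <- dim(Zs)
  gz <- (Zs[pmin(seq_len(d[1]) + 1L, d[1]), ] -
         Zs[pmax(seq_len(d[1]) - 1L, 1L), ]) / 2
  gx <- (Zs[, pmin(seq_len(d[2]) + 1L, d[2])] -
         Zs[, pmax(seq_len(d[2]) - 1L, 1L)]) / 2
  g <- sqrt(gz^2 + gx^2)
  nz <- ifelse(g > 0, gz / g, 1)
  nx <- ifelse(g > 0, gx / g, 0)
  list(nz = nz, nx = nx, gnorm = g)
}

# sample tissue labels of a slice at ray positions; NA outside the grid
sample_labels <- function(slice, Xp, Zp) {
  d <- dim(slice$grid)
  ri <- floor((Zp - slice$origin[1]) / slice$spacing[1]) + 1
  ci <- floor((Xp - slice$origin[2]) / slice$spacing[2]) + 1
  inside <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
  lab <- matrix(NA_integer_, nrow(Xp), ncol(Xp))
  lab[inside] <- slice$grid[cbind(ri[inside], ci[inside])]
  list(lab = lab, ri = pmin(pmax(ri, 1L), d[1]), ci = pmin(pmax(ci, 1L), d[2]))
}

# core ray march over all scan lines at once; returns the reflection echo
# matrix (axial_samples x scan_lines), the cumulative two-way-usable
# one-way transmission (attenuation x interface losses) and the sampled
# label matrix
trace_field <- function(slice, tt, mp, geom = fan_geometry(mp)) {
  validate_tissue_table(tt)
  labs_present <- unique(as.integer(slice$grid))
  missing <- setdiff(labs_present, tt$label)
  if (length(missing))
    stop("tissue table does not cover label(s): ",
         paste(missing, collapse = ", "))
  K <- mp$axial_samples; L <- length(geom$phi)
  dd <- (seq_len(K) - 0.5) * geom$delta
  Xp <- outer(dd, geom$dir_x) + matrix(geom$origin_x, K, L, byrow = TRUE)
  Zp <- outer(dd, geom$dir_z) + matrix(geom$origin_z, K, L, byrow = TRUE)
  sl <- sample_labels(slice, Xp, Zp)
  lab <- sl$lab
  av <- tissue_lookup(tt, "alpha")
  Zv <- tissue_lookup(tt, "Z")
  att <- matrix(1, K, L)
  ok <- !is.na(lab)
  att[ok] <- 10^(-av[lab[ok]] * mp$center_frequency * (geom$delta / 10) / 20)
  Tcum <- apply(att, 2, cumprod)
  nm <- normal_map(slice, tt)
  refl <- matrix(0, K, L)
  Tfull <- Tcum
  chg <- lab[-1, , drop = FALSE] != lab[-K, , drop = FALSE]
  chg[is.na(chg)] <- FALSE
  p <- mp$specular_p
  for (j in seq_len(L)) {
    ks <- which(chg[, j]) + 1L
    if (!length(ks)) next
    a <- lab[ks - 1L, j]; b <- lab[ks, j]
    R <- ((Zv[b] - Zv[a]) / (Zv[b] + Zv[a]))^2
    pr <- cbind(sl$ri[cbind(ks, rep(j, length(ks)))],
                sl$ci[cbind(ks, rep(j, length(ks)))])
    cosw <- abs(geom$dir_z[j] * nm$nz[pr] + geom$dir_x[j] * nm$nx[pr])
    cosw[nm$gnorm[pr] == 0] <- 1
    trans <- cumprod(1 - R)
    trans_before <- c(1, trans[-length(trans)])
    Tb <- Tcum[ks - 1L, j] * trans_before
    refl[ks, j] <- Tb^2 * R * cosw^p
    # fold interface transmission losses into the cumulative transmission
    tf <- rep(1, K)
    for (i in seq_along(ks)) tf[ks[i]:K] <- tf[ks[i]:K] * (1 - R[i])
    Tfull[, j] <- Tcum[, j] * tf
  }
  list(reflection = refl, transmission = Tfull, lab = lab, geom = geom)
}

#' Trace a single ultrasound ray through a labelmap slice
#'
#' Marches one ray with axial step `image_depth / axial_samples`,
#' accumulating one-way transmission (per-tissue attenuation and interface
#' losses) and recording, at each tissue change a to b, the echo
#' `T^2 R(Z_a, Z_b) |cos(theta)|^p`, where theta is the angle between the
#' ray and the local boundary normal (gradient of a Gaussian-smoothed
#' impedance map). Samples beyond the slice are zero.
#'
#' @param slice A 2D [labelmap()].
#' @param origin Ray origin (x, z) in mm.
#' @param direction Unit ray direction (x, z).
#' @param tt A [tissue_table()] covering every label of the slice.
#' @param mp A [machine_params()] list.
#' @return Numeric reflection profile of length `axial_samples`.
#' @export
trace_ray <- function(slice, origin, direction, tt = tissue_table(),
                      mp = machine_params()) {
  direction <- direction / sqrt(sum(direction^2))
  geom <- fan_geometry(mp)
  geom$phi <- 0
  geom$origin_x <- origin[1]; geom$origin_z <- origin[2]
  geom$dir_x <- direction[1]; geom$dir_z <- direction[2]
  trace_field(slice, tt, mp, geom)$reflection[, 1]
}

# speckle amplitudes along all lines, weighted by squared transmission and
# blurred axially by a depth-dependent Gaussian point-spread function whose
# width is minimal at the focus depth
scatter_field <- function(tf, tt, mp, seed = 1L, psf = TRUE) {
  lab <- tf$lab
  mu0 <- tissue_lookup(tt, "mu0")
  mu1 <- tissue_lookup(tt, "mu1")
  sg0 <- tissue_lookup(tt, "sigma0")
  K <- nrow(lab); L <- ncol(lab)
  if (max(mu0[tf$lab[!is.na(tf$lab)]], 0, na.rm = TRUE) == 0 &&
      max(abs(mu1[tf$lab[!is.na(tf$lab)]]), 0, na.rm = TRUE) == 0 &&
      max(sg0[tf$lab[!is.na(tf$lab)]], 0, na.rm = TRUE) == 0)
    return(matrix(0, K, L))
  amp <- withr::with_seed(seed, {
    u <- matrix(stats::runif(K * L), K, L)
    a <- matrix(stats::rnorm(K * L), K, L)
    ok <- !is.na(lab)
    out <- matrix(0, K, L)
    out[ok] <- (u[ok] <= mu0[lab[ok]]) *
      pmax(0, mu1[lab[ok]] + sg0[lab[ok]] * a[ok])
    out
  })
  amp <- amp * tf$transmission^2
  if (psf) depth_psf_blur(amp, mp, tf$geom) else amp
}

depth_psf_blur <- function(amp, mp, geom, n_bands = 8L) {
  K <- nrow(amp)
  dd <- (seq_len(K) - 0.5) * geom$delta
  # pulse-envelope sd in mm, minimal at focus, linear growth off-focus
  sig_mm <- mp$psf_axial_mm * (0.5 + abs(dd - mp$focus_depth) / mp$focus_depth)
  sig <- pmax(sig_mm / geom$delta, 0.75)  # samples
  bands <- split(seq_len(K), cut(seq_len(K), n_bands, labels = FALSE))
  out <- amp
  for (b in bands) {
    s <- mean(sig[b])
    r <- ceiling(3 * s)
    w <- exp(-(-r:r)^2 / (2 * s^2)); w <- w / sum(w)
    acc <- matrix(0, length(b), ncol(amp))
    for (i in seq_along(w)) {
      rows <- pmin(pmax(b + (i - r - 1L), 1L), K)
      acc <- acc + w[i] * amp[rows, , drop = FALSE]
    }
    out[b, ] <- acc
  }
  out
}

#' Speckle scatter profile along a single ray
#'
#' Per axial sample, a scatterer fires with probability `mu0` of the local
#' tissue and amplitude `max(0, N(mu1, sigma0^2))`, weighted by the squared
#' cumulative transmission, then blurred axially by the depth-dependent
#' point-spread function. With all speckle parameters zero (the IR preset)
#' the profile is identically zero.
#'
#' @inheritParams trace_ray
#' @param seed Integer RNG seed; fixed seed gives identical profiles.
#' @param psf Apply the depth-dependent point-spread blur (disable to
#'   inspect raw scatterer amplitudes).
#' @return Numeric scatter profile of length `axial_samples`.
#' @export
scatter_profile <- function(slice, origin, direction, tt = tissue_table(),
                            mp = machine_params(), seed = 1L, psf = TRUE) {
  direction <- direction / sqrt(sum(direction^2))
  geom <- fan_geometry(mp)
  geom$phi <- 0
  geom$origin_x <- origin[1]; geom$origin_z <- origin[2]
  geom$dir_x <- direction[1]; geom$dir_z <- direction[2]
  tf <- trace_field(slice, tt, mp, geom)
  scatter_field(tf, tt, mp, seed, psf = psf)[, 1]
}

#' Compose the echo envelope from reflection and scatter terms
#'
#' Applies time-gain compensation per depth, raises the reflection term to
#' `scale_exp1` and the scatter term to `scale_exp2`, adds optional
#' Gaussian RF noise, clips at zero and normalizes so that the
#' `norm_quantile` quantile of the nonzero (echo) samples maps to 1, then
#' clips to \[0, 1\]. Referencing the echo population rather than the
#' whole frame keeps faint deep boundaries visible regardless of how
#' bright the strongest specular reflectors are.
#'
#' @param reflection,scatter Non-negative matrices
#'   (`axial_samples` x `scan_lines`).
#' @param mp A [machine_params()] list.
#' @param seed RNG seed for the additive noise (unused when
#'   `rf_noise = 0`).
#' @param norm_quantile Quantile of the nonzero envelope used as the
#'   normalization reference (default 0.9).
#' @param reject Display reject level: normalized values below it are set
#'   to zero (default 0.03, i.e. about -30 dB), the scanner's reject
#'   control that keeps the representation sparse.
#' @return Envelope matrix in \[0, 1\], same shape.
#' @export
compose_envelope <- function(reflection, scatter, mp = machine_params(),
                             seed = 1L, norm_quantile = 0.9, reject = 0.03) {
  if (!identical(dim(reflection), dim(scatter)))
    stop("reflection and scatter shapes differ")
  K <- nrow(reflection)
  g <- tgc_gain((seq_len(K) - 0.5) / K, mp)
  env <- (reflection * g)^mp$scale_exp1 + (scatter * g)^mp$scale_exp2
  if (mp$rf_noise > 0)
    env <- env + withr::with_seed(seed,
      matrix(stats::rnorm(length(env), sd = mp$rf_noise), K, ncol(env)))
  env <- pmax(env, 0)
  # normalize against the echo population (nonzero samples): a handful of
  # specular flashes (air, bone) must not push deep anatomy below
  # visibility, so the reference is a quantile of the echoes themselves
  nz <- env[env > 0]
  if (length(nz)) env <- env / stats::quantile(nz, norm_quantile, names = FALSE)
  env <- pmin(env, 1)
  env[env < reject] <- 0   # display reject: cut sub-threshold returns
  env
}

#' Scan-convert a beam-space field to a Cartesian fan image
#'
#' Inverse per-pixel mapping from the Cartesian window to beam space
#' (line angle, radius from the virtual apex) with bilinear interpolation;
#' pixels with no valid pre-image form the complement of the fan mask and
#' are exactly zero.
#'
#' @param env Beam-space matrix (`axial_samples` x `scan_lines`).
#' @param mp A [machine_params()] list.
#' @param out_size Output image side in pixels (>= 16).
#' @param mode Image mode tag.
#' @return An [ultrasound_image()].
#' @export
scan_convert <- function(env, mp = machine_params(), out_size = 256L,
                         mode = "IR") {
  if (out_size < 16) stop("out_size must be >= 16")
  geom <- fan_geometry(mp, out_size)
  px <- scan_convert_field(env, mp, geom, out_size, nearest = FALSE)
  ultrasound_image(px$img, geom$pixel_spacing, px$mask, mode = mode)
}

scan_convert_field <- function(env, mp, geom, out_size, nearest = FALSE) {
  K <- nrow(env); L <- ncol(env)
  ps <- geom$pixel_spacing
  xs <- (seq_len(out_size) - 0.5) * ps - geom$S / 2
  zs <- (seq_len(out_size) - 0.5) * ps
  Xc <- matrix(xs, out_size, out_size, byrow = TRUE)
  Zc <- matrix(zs, out_size, out_size)
  rx <- Xc - geom$apex[["x"]]
  rz <- Zc - geom$apex[["z"]]
  rr <- sqrt(rx^2 + rz^2)
  ph <- atan2(rx, rz)
  valid <- abs(ph) <= geom$half & rr >= geom$r0 &
    rr <= geom$r0 + mp$image_depth
  jf <- (ph + geom$half) / (2 * geom$half) * (L - 1) + 1
  kf <- (rr - geom$r0) / geom$delta + 0.5
  jf <- pmin(pmax(jf, 1), L); kf <- pmin(pmax(kf, 1), K)
  img <- matrix(0, out_size, out_size)
  if (nearest) {
    img[valid] <- env[cbind(round(kf[valid]), round(jf[valid]))]
  } else {
    j0 <- floor(jf[valid]); k0 <- floor(kf[valid])
    j1 <- pmin(j0 + 1, L); k1 <- pmin(k0 + 1, K)
    fj <- jf[valid] - j0; fk <- kf[valid] - k0
    img[valid] <-
      env[cbind(k0, j0)] * (1 - fk) * (1 - fj) +
      env[cbind(k1, j0)] * fk * (1 - fj) +
      env[cbind(k0, j1)] * (1 - fk) * fj +
      env[cbind(k1, j1)] * fk * fj
  }
  list(img = img, mask = valid)
}

#' Simulate an ultrasound image from a labelmap
#'
#' Full pipeline: (for volumes) slice extraction along the probe pose,
#' ray tracing of every scan line, optional speckle, envelope composition
#' with TGC and normalization, and scan conversion to a Cartesian fan
#' image. `mode = "IR"` forces all speckle parameters to zero (boundary-
#' only intermediate representation, deterministic when `rf_noise = 0`);
#' `mode = "realistic"` keeps the table's speckle and applies log
#' compression over `log_compression_db` dynamic range.
#'
#' @param x A [labelmap()] (2D slice or 3D volume).
#' @param pose A [probe_pose()] (required for 3D volumes).
#' @param tt A [tissue_table()].
#' @param mp A [machine_params()] list.
#' @param mode `"IR"` or `"realistic"`.
#' @param seed RNG seed for speckle/noise.
#' @param out_size Output image side in pixels.
#' @return An [ultrasound_image()].
#' @examples
#' ph <- generate_phantom(phantom_config(seed = 1))
#' img <- simulate_us(ph$labelmap, mp = machine_params(scan_lines = 64,
#'                 axial_samples = 256), out_size = 64)
#' @export
simulate_us <- function(x, pose = NULL, tt = tissue_table(),
                     mp = machine_params(), mode = c("IR", "realistic"),
                     seed = 1L, out_size = 256L) {
  mode <- match.arg(mode)
  if (mode == "IR") {
    tt$mu0 <- 0; tt$mu1 <- 0; tt$sigma0 <- 0
  }
  slices <- simulate_slices(x, pose, mp)
  geom <- fan_geometry(mp, out_size)
  K <- mp$axial_samples; L <- mp$scan_lines
  refl <- matrix(0, K, L); scat <- matrix(0, K, L)
  for (i in seq_along(slices)) {
    tf <- trace_field(slices[[i]], tt, mp, geom)
    refl <- refl + tf$reflection
    scat <- scat + scatter_field(tf, tt, mp, seed + i - 1L)
  }
  refl <- refl / length(slices); scat <- scat / length(slices)
  # the axial pulse envelope applies to specular echoes as well: without
  # it a boundary echo is a single 0.1 mm sample and scan conversion to
  # ~0.5-1 mm pixels would dilute it by an arbitrary factor
  refl <- depth_psf_blur(refl, mp, geom)
  env <- compose_envelope(refl, scat, mp, seed)
  if (mode == "realistic" && mp$log_compression_db > 0)
    env <- log_compress(env, mp$log_compression_db)
  px <- scan_convert_field(env, mp, geom, out_size)
  ultrasound_image(px$img, geom$pixel_spacing, px$mask,
                   mode = if (mode == "IR") "IR" else "realistic")
}

log_compress <- function(env, dr_db) {
  eps <- 10^(-dr_db / 20)
  pmin(pmax((20 * log10(pmax(env, eps)) + dr_db) / dr_db, 0), 1)
}

# slices entering the beam plane: a 2D slice as-is (elevational rays
# degenerate to identical rays); for volumes, elevational_rays parallel
# slices spread across elevational_thickness
simulate_slices <- function(x, pose, mp) {
  stopifnot(inherits(x, "labelmap"))
  if (length(dim(x$grid)) == 2L) return(list(x))
  if (is.null(pose)) stop("a probe pose is required for 3D volumes")
  nrm <- vcross(pose$direction, pose$in_plane)
  offs <- if (mp$elevational_rays > 1L)
    seq(-mp$elevational_thickness / 2, mp$elevational_thickness / 2,
        length.out = mp$elevational_rays) else 0
  lapply(offs, function(o) {
    p <- pose
    p$position <- p$position + o * nrm
    extract_slice(x, p, extent_mm = c(2 * (fan_geometry(mp)$S / 2),
                                      mp$image_depth + 5))
  })
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rasterize a slice-space mask through the imaging geometry
#'
#' Samples a binary mask (given on the slice grid) along every scan line
#' and scan-converts it with the identical fan geometry used by
#' [simulate_us()], yielding a ground-truth mask aligned with the simulated
#' image.
#'
#' @param mask Logical matrix on the slice grid.
#' @param slice The 2D [labelmap()] the mask lives on (for spacing/origin).
#' @param mp A [machine_params()] list.
#' @param out_size Output side in pixels.
#' @return Logical `out_size` x `out_size` matrix.
#' @export
simulate_mask <- function(mask, slice, mp = machine_params(),
                          out_size = 256L) {
  geom <- fan_geometry(mp, out_size)
  K <- mp$axial_samples; L <- mp$scan_lines
  dd <- (seq_len(K) - 0.5) * geom$delta
  Xp <- outer(dd, geom$dir_x) + matrix(geom$origin_x, K, L, byrow = TRUE)
  Zp <- outer(dd, geom$dir_z) + matrix(geom$origin_z, K, L, byrow = TRUE)
  d <- dim(mask)
  ri <- floor((Zp - slice$origin[1]) / slice$spacing[1]) + 1
  ci <- floor((Xp - slice$origin[2]) / slice$spacing[2]) + 1
  inside <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
  beam <- matrix(0, K, L)
  beam[inside] <- as.numeric(mask[cbind(ri[inside], ci[inside])])
  px <- scan_convert_field(beam, mp, geom, out_size)
  px$img > 0.5 & px$mask
}

split_even <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  rem <- n - base * k
  if (rem > 0) out[seq_len(rem)] <- out[seq_len(rem)] + 1L
  out
}

#' Simulate a dataset of IR images with aligned aorta masks
#'
#' Distributes `n` samples evenly across the input volumes (probe poses
#' sampled along each volume's control spline; 2D slices are imaged
#' directly), simulates each image and rasterizes the blood-labelled
#' aorta through the identical geometry. Deterministic for a fixed seed.
#'
#' @param volumes List of [labelmap()] objects (2D or 3D).
#' @param n Total number of samples (>= 1).
#' @param control_points Optional list (per volume) of [probe_pose()]
#'   control points for 3D volumes.
#' @param tt,mp,mode,seed,out_size As in [simulate_us()].
#' @param out_dir Optional directory; when given, images and masks are
#'   written as PNG and the manifest as CSV.
#' @return List with `images`, `masks` (lists) and `manifest` (tibble with
#'   volume, pose index, seed and aorta diameter per sample).
#' @export
simulate_dataset <- function(volumes, n, control_points = NULL,
                             tt = tissue_table(), mp = machine_params(),
                             mode = "IR", seed = 1L, out_size = 256L,
                             out_dir = NULL) {
  if (n < 1) stop("n must be >= 1")
  nv <- length(volumes)
  per <- split_even(n, nv)
  images <- list(); masks <- list()
  man <- list()
  s <- 0L
  for (v in seq_len(nv)) {
    vol <- volumes[[v]]
    is3d <- length(dim(vol$grid)) == 3L
    poses <- if (is3d) {
      if (is.null(control_points) || is.null(control_points[[v]]))
        stop("3D volumes need control points for pose sampling")
      sample_probe_poses(control_points[[v]], per[v])
    } else rep(list(NULL), per[v])
    for (i in seq_len(per[v])) {
      s <- s + 1L
      img <- simulate_us(vol, poses[[i]], tt, mp, mode = mode,
                      seed = seed + s, out_size = out_size)
      slice <- if (is3d) extract_slice(vol, poses[[i]]) else vol
      blood <- legend_label(slice$legend, "Blood")
      msk <- simulate_mask(slice$grid == blood, slice, mp, out_size)
      dia <- if (any(msk)) ap_diameter(msk, img$pixel_spacing) else NA_real_
      images[[s]] <- img
      masks[[s]] <- msk
      man[[s]] <- tibble::tibble(sample = s, volume = v, pose = i,
                                 seed = seed + s, diameter_mm = dia)
    }
  }
  manifest <- do.call(rbind, man)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(s)) {
      write_image(images[[i]], file.path(out_dir, sprintf("img_%04d.png", i)),
                  seed = manifest$seed[i])
      png::writePNG(masks[[i]] * 1,
                    file.path(out_dir, sprintf("msk_%04d.png", i)))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, masks = masks, manifest = manifest)
}

#' Select a volume-balanced subset of a dataset manifest
#'
#' Randomly selects `n` samples with an equal number drawn from each
#' volume.
#'
#' @param manifest Manifest tibble from [simulate_dataset()].
#' @param n Subset size (multiple of the number of volumes is exact;
#'   otherwise the first volumes contribute one extra).
#' @param seed RNG seed.
#' @return The selected manifest rows.
#' @export
select_balanced <- function(manifest, n, seed = 1L) {
  vols <- unique(manifest$volume)
  per <- split_even(n, length(vols))
  withr::with_seed(seed, {
    sel <- unlist(lapply(seq_along(vols), function(i) {
      rows <- which(manifest$volume == vols[i])
      sample(rows, min(per[i], length(rows)))
    }))
    manifest[sort(sel), ]
  })
}
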