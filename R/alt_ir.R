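#' Edge-detection intermediate representation
#'
#' Comparison baseline: the slice is rasterized into the Cartesian imaging
#' window (labelmaps are rendered as normalized acoustic impedance),
#' bilateral-filtered, passed through a Canny edge detector and masked by
#' the same convex fan as the simulated images. Unlike the physics-based
#' IR, this representation carries no attenuation information (no acoustic
#' shadows).
#'
#' @param x A 2D [labelmap()], or a numeric matrix already sized
#'   `out_size` x `out_size` covering the imaging window.
#' @param mp A [machine_params()] list.
#' @param out_size Output image side in pixels.
#' @param spatial_sigma Bilateral spatial sigma, px.
#' @param range_sigma Bilateral range sigma, fraction of the dynamic range.
#' @return An [ultrasound_image()] with `mode = "edge"`.
#' @export
edge_ir <- function(x, mp = machine_params(), out_size = 256L,
                    spatial_sigma = 3, range_sigma = 0.1) {
  geom <- fan_geometry(mp, out_size)
  if (inherits(x, "labelmap")) {
    if (length(dim(x$grid)) != 2L) stop("edge_ir needs a 2D input")
    tt <- tissue_table()
    Zv <- tissue_lookup(tt, "Z")
    intensity <- cartesian_rasterize(x, Zv, geom, out_size)
    intensity <- intensity / max(Zv[tt$label])
  } else {
    if (!is.matrix(x)) stop("edge_ir needs a 2D input")
    if (!all(dim(x) == out_size))
      x <- resize_bilinear(x, out_size, out_size)
    rng <- range(x)
    intensity <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0
  }
  sm <- bilateral_filter(intensity, spatial_sigma, range_sigma)
  edges <- canny_edges(sm)
  px <- edges * 1
  px[!geom_fan_mask(mp, geom, out_size)] <- 0
  ultrasound_image(px, geom$pixel_spacing,
                   geom_fan_mask(mp, geom, out_size), mode = "edge")
}

geom_fan_mask <- function(mp, geom, out_size) {
  scan_convert_field(matrix(0, 2, 2), mp, geom, out_size)$mask
}

# render a labelmap attribute (per-label values) into the Cartesian window
cartesian_rasterize <- function(lm, values_by_label, geom, out_size) {
  ps <- geom$pixel_spacing
  xs <- (seq_len(out_size) - 0.5) * ps - geom$S / 2
  zs <- (seq_len(out_size) - 0.5) * ps
  Xc <- matrix(xs, out_size, out_size, byrow = TRUE)
  Zc <- matrix(zs, out_size, out_size)
  d <- dim(lm$grid)
  ri <- floor((Zc - lm$origin[1]) / lm$spacing[1]) + 1
  ci <- floor((Xc - lm$origin[2]) / lm$spacing[2]) + 1
  inside <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
  out <- matrix(0, out_size, out_size)
  out[inside] <- values_by_label[lm$grid[cbind(ri[inside], ci[inside])]]
  out
}

# brute-force bilateral filter over a square window of radius 2*sigma_s
bilateral_filter <- function(img, sigma_s = 3, sigma_r = 0.1) {
  r <- ceiling(2 * sigma_s)
  d <- dim(img)
  num <- matrix(0, d[1], d[2])
  den <- matrix(0, d[1], d[2])
  for (dr in -r:r) for (dc in -r:r) {
    ws <- exp(-(dr^2 + dc^2) / (2 * sigma_s^2))
    rows <- pmin(pmax(seq_len(d[1]) + dr, 1L), d[1])
    cols <- pmin(pmax(seq_len(d[2]) + dc, 1L), d[2])
    sh <- img[rows, cols, drop = FALSE]
    w <- ws * exp(-(sh - img)^2 / (2 * sigma_r^2))
    num <- num + w * sh
    den <- den + w
  }
  num / den
}

# Canny: Sobel gradients, 4-direction non-maximum suppression, hysteresis
# with median-rule automatic thresholds
canny_edges <- function(img, low = NULL, high = NULL) {
  d <- dim(img)
  pad <- function(m, dr, dc) {
    rows <- pmin(pmax(seq_len(d[1]) + dr, 1L), d[1])
    cols <- pmin(pmax(seq_len(d[2]) + dc, 1L), d[2])
    m[rows, cols, drop = FALSE]
  }
  gz <- pad(img, 1, -1) + 2 * pad(img, 1, 0) + pad(img, 1, 1) -
        pad(img, -1, -1) - 2 * pad(img, -1, 0) - pad(img, -1, 1)
  gx <- pad(img, -1, 1) + 2 * pad(img, 0, 1) + pad(img, 1, 1) -
        pad(img, -1, -1) - 2 * pad(img, 0, -1) - pad(img, 1, -1)
  mag <- sqrt(gz^2 + gx^2)
  if (all(mag == 0)) return(matrix(FALSE, d[1], d[2]))
  ang <- atan2(gz, gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:E, 1:NE, 2:N, 3:NW
  n1 <- mag; n2 <- mag
  for (s in 0:3) {
    off <- switch(s + 1,
                  c(0L, 1L),    # horizontal gradient -> compare E/W
                  c(1L, 1L),    # diagonal
                  c(1L, 0L),    # vertical gradient -> compare N/S
                  c(1L, -1L))
    sel <- sector == s
    n1[sel] <- pad(mag, off[1], off[2])[sel]
    n2[sel] <- pad(mag, -off[1], -off[2])[sel]
  }
  keep <- mag >= n1 & mag >= n2
  nz <- mag[mag > 0]
  if (is.null(high)) high <- 1.33 * stats::median(nz)
  if (is.null(low)) low <- 0.67 * stats::median(nz)
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak)
  comp_ids <- unique(lab[strong])
  weak & (lab %in% comp_ids)
}

#' Realistic-simulation intermediate representation
#'
#' Comparison baseline: the same ray-traced pipeline as [simulate_us()],
#' but with speckle enabled (soft-tissue defaults of
#' `tissue_table("realistic")`) and log compression, approximating a
#' default-parameter B-mode simulation. Zeroing the speckle parameters
#' recovers the IR image.
#'
#' @param slice A 2D [labelmap()].
#' @param tt A [tissue_table()]; defaults to the realistic speckle preset.
#' @param mp A [machine_params()] list.
#' @param seed RNG seed for the speckle pattern.
#' @param out_size Output image side in pixels.
#' @return An [ultrasound_image()] with `mode = "realistic"`.
#' @export
realistic_ir <- function(slice, tt = tissue_table("realistic"),
                         mp = machine_params(), seed = 1L,
                         out_size = 256L) {
  simulate_us(slice, tt = tt, mp = mp, mode = "realistic", seed = seed,
              out_size = out_size)
}
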