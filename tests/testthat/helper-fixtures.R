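# shared fixtures: small machine parametrization and simple slices

small_mp <- function(...) {
  machine_params(scan_lines = 64L, axial_samples = 256L, ...)
}

# flat two-layer slice: tissue a over tissue b, interface at depth_mm,
# optionally tilted by tilt_deg about the slice center column
two_layer_slice <- function(a = 1L, b = 2L, depth_mm = 50, spacing = 0.5,
                            tilt_deg = 0, nrow_px = 220L, ncol_px = 40L) {
  Zm <- matrix((seq_len(nrow_px) - 0.5) * spacing, nrow_px, ncol_px)
  Xm <- matrix((seq_len(ncol_px) - 0.5) * spacing - ncol_px * spacing / 2,
               nrow_px, ncol_px, byrow = TRUE)
  g <- matrix(a, nrow_px, ncol_px)
  g[Zm - depth_mm - tan(tilt_deg * pi / 180) * Xm >= 0] <- b
  labelmap(g, spacing, origin = c(0, -ncol_px * spacing / 2))
}

homogeneous_slice <- function(label = 7L, spacing = 0.5, nrow_px = 220L,
                              ncol_px = 220L) {
  labelmap(matrix(label, nrow_px, ncol_px), spacing,
           origin = c(0, -ncol_px * spacing / 2))
}

# disc mask helper (pixel units)
disc_mask <- function(n, cz, cx, r) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rr - cz)^2 + (cc - cx)^2 <= r^2
}

# layered slice with several horizontal interfaces and an optional bone disc
layered_slice <- function(with_bone = FALSE, spacing = 0.5) {
  n <- 220L
  g <- matrix(7L, n, n)
  zc <- (seq_len(n) - 0.5) * spacing
  g[zc >= 60 & zc < 75, ] <- 3L   # liver band
  g[zc >= 90, ] <- 4L             # deep band
  if (with_bone) {
    d <- disc_mask(n, 40 / spacing, n / 2, 10 / spacing)
    g[d] <- 8L
  }
  labelmap(g, spacing, origin = c(0, -n * spacing / 2))
}
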