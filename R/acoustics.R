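#' Default tissue legend
#'
#' Fixed label coding for the nine abdominal tissues used throughout the
#' package. Labels are arbitrary integers; this default maps 1..9 to the
#' tissue names of the built-in acoustic table.
#'
#' @return Named character vector; names are label integers (as strings),
#'   values are tissue names.
#' @export
default_legend <- function() {
  c(`1` = "Fat", `2` = "Muscle", `3` = "Liver", `4` = "Kidney",
    `5` = "Blood", `6` = "Background", `7` = "SoftTissue", `8` = "Bone",
    `9` = "Air")
}

#' Tissue acoustic-parameter table
#'
#' Per-tissue acoustics used by the ray tracer: speed of sound `c` (m/s),
#' acoustic impedance `Z` (g cm^-2 s^-1), attenuation coefficient `alpha`
#' (dB cm^-1 MHz^-1), and speckle parameters: scatterer density `mu0` in
#' \[0,1\], scatter amplitude mean `mu1` and standard deviation `sigma0`.
#'
#' The default values model specular reflection of the nine abdominal
#' tissues; the `"ir"` speckle preset zeroes all speckle parameters so that
#' tissues render black and only boundaries echo (the intermediate
#' representation used to train segmenters), while `"realistic"` assigns a
#' generic speckle texture to all soft tissues (zero for Air and
#' Background).
#'
#' @param speckle One of `"ir"` (all speckle parameters zero) or
#'   `"realistic"` (generic soft-tissue speckle defaults).
#' @return A `tissue_table`: tibble with columns `label`, `tissue`, `c`,
#'   `Z`, `alpha`, `mu0`, `mu1`, `sigma0`.
#' @examples
#' tissue_table()
#' tissue_table("realistic")
#' @export
tissue_table <- function(speckle = c("ir", "realistic")) {
  speckle <- match.arg(speckle)
  tab <- tibble::tibble(
    label  = 1:9,
    tissue = c("Fat", "Muscle", "Liver", "Kidney", "Blood", "Background",
               "SoftTissue", "Bone", "Air"),
    c      = c(1470, 1568, 1540, 1540, 1492, 1590, 1540, 3600, 1300),
    Z      = c(0.82, 1.63, 2.86, 1.06, 1.49, 0.30, 0.63, 6.12, 0.10) * 1e5,
    alpha  = c(0.48, 0.49, 0.40, 0.50, 0.20, 0.54, 0.54, 0.48, 2.00),
    mu0    = 0, mu1 = 0, sigma0 = 0
  )
  if (speckle == "realistic") {
    soft <- !(tab$tissue %in% c("Air", "Background"))
    tab$mu0[soft]    <- 0.5
    tab$mu1[soft]    <- 0.6
    tab$sigma0[soft] <- 0.2
  }
  class(tab) <- c("tissue_table", class(tab))
  tab
}

#' @export
print.tissue_table <- function(x, ...) {
  cat("<tissue_table> ", nrow(x), " tissues\n", sep = "")
  NextMethod()
}

validate_tissue_table <- function(tt) {
  stopifnot(is.data.frame(tt),
            all(c("label", "tissue", "c", "Z", "alpha",
                  "mu0", "mu1", "sigma0") %in% names(tt)))
  if (any(tt$c <= 0) || any(tt$Z <= 0))
    stop("tissue table: c and Z must be positive")
  if (any(tt$alpha < 0) || any(tt$sigma0 < 0))
    stop("tissue table: alpha and sigma0 must be non-negative")
  if (any(tt$mu0 < 0 | tt$mu0 > 1))
    stop("tissue table: mu0 must lie in [0, 1]")
  invisible(tt)
}

# fast lookup vectors indexed by label integer (labels need not be 1..n)
tissue_lookup <- function(tt, what) {
  v <- rep(NA_real_, max(tt$label))
  v[tt$label] <- tt[[what]]
  v
}

#' Machine parameters of the simulated ultrasound probe
#'
#' Characteristics of the simulated convex-array machine: geometry
#' (`probe_width` mm, `probe_angle` degrees, `image_depth` mm,
#' `focus_depth` mm), sampling (`scan_lines`, `axial_samples`,
#' `elevational_rays`), post-processing (`rf_noise` additive-noise sd,
#' `scale_exp1` applied to the reflection term, `scale_exp2` to the
#' scattering term, `tgc_alpha`/`tgc_scale` of the time-gain-compensation
#' curve), plus `center_frequency` (MHz), `elevational_thickness` (mm) and
#' the specular exponent `specular_p` of the cosine boundary weighting.
#'
#' @param ... Named overrides of any default.
#' @return A `machine_params` list.
#' @examples
#' machine_params()
#' machine_params(scan_lines = 64, axial_samples = 256)
#' @export
machine_params <- function(...) {
  mp <- list(
    probe_width   = 59,    # mm
    probe_angle   = 40,    # degrees, full fan opening
    image_depth   = 100,   # mm
    focus_depth   = 50,    # mm
    scan_lines    = 196L,
    axial_samples = 1024L,
    elevational_rays = 10L,
    rf_noise      = 0,
    scale_exp1    = 1.0,
    scale_exp2    = 0.2,
    tgc_alpha     = 0.65,
    tgc_scale     = 0.2,
    center_frequency      = 2.5,  # MHz
    elevational_thickness = 2.0,  # mm
    specular_p    = 1,
    psf_axial_mm  = 0.5,   # axial pulse envelope width (sd, mm) at focus
    log_compression_db    = 60    # realistic mode only
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(mp))
  if (length(unknown))
    stop("unknown machine parameter(s): ", paste(unknown, collapse = ", "))
  mp[names(over)] <- over
  mp$scan_lines <- as.integer(mp$scan_lines)
  mp$axial_samples <- as.integer(mp$axial_samples)
  mp$elevational_rays <- as.integer(mp$elevational_rays)
  with(mp, {
    if (probe_width <= 0 || probe_angle <= 0 || image_depth <= 0 ||
        focus_depth <= 0 || center_frequency <= 0)
      stop("machine parameters must be positive")
    if (rf_noise < 0) stop("rf_noise must be >= 0")
    if (scan_lines < 2 || axial_samples < 2)
      stop("scan_lines and axial_samples must be integers >= 2")
  })
  structure(mp, class = "machine_params")
}

#' @export
print.machine_params <- function(x, ...) {
  cat("<machine_params>\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Intensity reflection coefficient at a tissue interface
#'
#' Fraction of the incident intensity reflected at a planar interface
#' between media of acoustic impedance `Za` and `Zb`:
#' `R = ((Zb - Za) / (Zb + Za))^2`. Symmetric in its arguments.
#'
#' @param Za,Zb Acoustic impedances (same units, > 0). Vectorized.
#' @return Reflected fraction in \[0, 1\].
#' @examples
#' reflection_coefficient(1.49e5, 6.12e5)  # blood | bone
#' @export
reflection_coefficient <- function(Za, Zb) {
  if (any(Za <= 0) || any(Zb <= 0))
    stop("acoustic impedances must be positive")
  ((Zb - Za) / (Zb + Za))^2
}

#' One-way amplitude attenuation factor
#'
#' Amplitude retained after travelling `dist` cm through a medium with
#' attenuation coefficient `alpha` (dB cm^-1 MHz^-1) at frequency `f` MHz:
#' `10^(-alpha * f * dist / 20)`.
#'
#' @param alpha Attenuation coefficient, dB cm^-1 MHz^-1 (>= 0). Vectorized.
#' @param f Center frequency, MHz (>= 0).
#' @param dist Path length, cm (>= 0).
#' @return Amplitude factor in (0, 1\].
#' @examples
#' attenuation_factor(0.54, 1, 1)  # soft tissue, 1 MHz, 1 cm
#' @export
attenuation_factor <- function(alpha, f, dist) {
  if (any(alpha < 0) || any(f < 0) || any(dist < 0))
    stop("attenuation inputs must be non-negative")
  10^(-alpha * f * dist / 20)
}

#' Time-gain-compensation gain
#'
#' Depth-dependent gain countering attenuation,
#' `g(d) = 1 + tgc_scale * (exp(tgc_alpha * d) - 1)` for normalized depth
#' `d` in \[0, 1\]: monotone non-decreasing with `g(0) = 1`.
#'
#' @param d_norm Normalized depth in \[0, 1\]. Vectorized.
#' @param mp A [machine_params()] list (uses `tgc_alpha`, `tgc_scale`).
#' @return Gain >= 1.
#' @examples
#' tgc_gain(c(0, 0.5, 1), machine_params())
#' @export
tgc_gain <- function(d_norm, mp = machine_params()) {
  if (any(d_norm < 0 | d_norm > 1))
    stop("d_norm must lie in [0, 1]")
  1 + mp$tgc_scale * (exp(mp$tgc_alpha * d_norm) - 1)
}
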