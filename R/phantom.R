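#' Configuration for the synthetic abdominal phantom
#'
#' Defines a 2D axial abdominal cross-section: layered skin/fat and muscle
#' bands over a soft-tissue cavity containing a liver region, two kidneys,
#' a rigid spine (bone) posterior-central, a circular aorta (blood)
#' anterior-left of the spine, and optional bowel-gas pockets. All
#' placements are jittered deterministically from `seed`.
#'
#' @param extent_mm Length-2 numeric, depth x width of the slice in mm.
#' @param spacing Pixel size in mm.
#' @param standoff_mm Background (gel) margin above the skin, mm.
#' @param fat_range,muscle_range Layer thickness ranges, mm.
#' @param jitter_mm Maximum absolute placement jitter, mm.
#' @param aorta_diameter_range Healthy aorta diameter range, mm
#'   (default 15-25).
#' @param include_air Add small air pockets (bowel gas).
#' @param seed Integer seed driving all random placements.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(extent_mm = c(130, 130), spacing = 0.5,
                           standoff_mm = 4, fat_range = c(8, 15),
                           muscle_range = c(8, 16), jitter_mm = 4,
                           aorta_diameter_range = c(15, 25),
                           include_air = TRUE, seed = 1L) {
  stopifnot(all(extent_mm > 0), spacing > 0,
            diff(range(fat_range)) >= 0, diff(range(muscle_range)) >= 0,
            aorta_diameter_range[2] >= aorta_diameter_range[1])
  structure(list(extent_mm = extent_mm, spacing = spacing,
                 standoff_mm = standoff_mm, fat_range = fat_range,
                 muscle_range = muscle_range, jitter_mm = jitter_mm,
                 aorta_diameter_range = aorta_diameter_range,
                 include_air = include_air, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a synthetic abdominal phantom
#'
#' Rasterizes the cross-section described by a [phantom_config()] and
#' returns the labelmap together with the exact aorta mask and its true
#' anterior-posterior diameter. Same seed, same phantom.
#'
#' @param cfg A [phantom_config()].
#' @return List with `labelmap` (2D [labelmap()]), `aorta_mask` (logical
#'   matrix), `diameter_mm` (AP diameter measured on the rasterized mask)
#'   and `target_diameter` (the sampled diameter).
#' @examples
#' ph <- generate_phantom(phantom_config(seed = 7))
#' ph$diameter_mm
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  withr::with_seed(cfg$seed, generate_phantom_impl(cfg))
}

generate_phantom_impl <- function(cfg) {
  sp <- cfg$spacing
  nr <- round(cfg$extent_mm[1] / sp)
  nc <- round(cfg$extent_mm[2] / sp)
  zc <- (seq_len(nr) - 0.5) * sp                       # depth, mm
  xc <- (seq_len(nc) - 0.5) * sp - cfg$extent_mm[2] / 2  # lateral, mm
  Z <- matrix(zc, nr, nc)
  X <- matrix(xc, nr, nc, byrow = TRUE)
  leg <- default_legend()
  lab <- function(t) legend_label(leg, t)
  jit <- function() stats::runif(1, -cfg$jitter_mm, cfg$jitter_mm)

  grid <- matrix(lab("Background"), nr, nc)
  t_fat <- stats::runif(1, cfg$fat_range[1], cfg$fat_range[2])
  t_mus <- stats::runif(1, cfg$muscle_range[1], cfg$muscle_range[2])
  z0 <- cfg$standoff_mm
  cavity_bottom <- min(cfg$extent_mm[1] - 10, 118)
  grid[Z >= z0 & Z < z0 + t_fat] <- lab("Fat")
  grid[Z >= z0 + t_fat & Z < z0 + t_fat + t_mus] <- lab("Muscle")
  grid[Z >= z0 + t_fat + t_mus & Z < cavity_bottom] <- lab("SoftTissue")

  ellipse <- function(cx, cz, ax, az)
    ((X - cx) / ax)^2 + ((Z - cz) / az)^2 <= 1
  soft <- grid == lab("SoftTissue")

  liver <- ellipse(28 + jit(), 42 + jit(), 26, 16)
  grid[liver & soft] <- lab("Liver")
  k1 <- ellipse(-42 + jit(), 80 + jit(), 9, 14)
  k2 <- ellipse(42 + jit(), 78 + jit(), 9, 14)
  grid[(k1 | k2) & soft] <- lab("Kidney")
  if (cfg$include_air) {
    a1 <- ellipse(-25 + jit(), 36 + jit(), r <- stats::runif(1, 2.5, 4.5), r)
    a2 <- ellipse(18 + jit(), 40 + jit(), r <- stats::runif(1, 2.5, 4.5), r)
    grid[(a1 | a2) & soft] <- lab("Air")
  }

  spine_r <- 11
  spine_c <- c(14 + jit() / 2, 100 + jit() / 2)   # (x, z)
  spine <- ellipse(spine_c[1], spine_c[2], spine_r, spine_r)
  grid[spine & Z < cavity_bottom & Z >= z0 + t_fat] <- lab("Bone")

  # aorta: circular blood cross-section anterior-left of the spine; retry
  # jitters until it clears the bone, then give up
  placed <- FALSE
  for (attempt in 1:25) {
    D <- stats::runif(1, cfg$aorta_diameter_range[1], cfg$aorta_diameter_range[2])
    ac <- c(-18 + jit(), 58 + jit())
    clearance <- sqrt(sum((ac - spine_c)^2)) - spine_r - D / 2
    if (clearance > 1) { placed <- TRUE; break }
  }
  if (!placed) stop("could not place the aorta without overlapping bone")
  aorta <- ellipse(ac[1], ac[2], D / 2, D / 2)
  grid[aorta] <- lab("Blood")

  lm <- labelmap(grid, spacing = sp, origin = c(0, -cfg$extent_mm[2] / 2),
                 legend = leg)
  list(labelmap = lm, aorta_mask = aorta,
       diameter_mm = ap_diameter(aorta, sp), target_diameter = D)
}
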