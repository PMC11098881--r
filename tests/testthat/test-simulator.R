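test_that("flat-interface echoes match the closed-form two-layer oracle", {
  mp <- machine_params()
  delta <- mp$image_depth / mp$axial_samples
  tt <- tissue_table()
  # a handful of tissue pairs; the full ordered sweep runs in the
  # acceptance suite
  for (pair in list(c(1L, 2L), c(7L, 8L), c(5L, 3L))) {
    depth <- 512 * delta  # interface aligned with the marching grid
    sl <- two_layer_slice(pair[1], pair[2], depth_mm = depth)
    prof <- trace_ray(sl, c(0, 0), c(0, 1), tt, mp)
    k <- which(prof > 0)
    expect_length(k, 1)
    Za <- tt$Z[tt$label == pair[1]]; Zb <- tt$Z[tt$label == pair[2]]
    al <- tt$alpha[tt$label == pair[1]]
    expected <- attenuation_factor(al, mp$center_frequency, depth / 10)^2 *
      reflection_coefficient(Za, Zb)
    expect_equal(prof[k], expected, tolerance = 1e-6)
  }
})

test_that("homogeneous media are anechoic", {
  mp <- small_mp()
  sl <- homogeneous_slice(7L)
  expect_true(all(trace_ray(sl, c(0, 0), c(0, 1), mp = mp) == 0))
  img <- simulate_us(sl, mp = mp, out_size = 64)
  expect_true(all(img$pixels == 0))
})

test_that("echo strength decreases with interface obliquity", {
  e <- sapply(c(0, 30, 60), function(t)
    sum(trace_ray(two_layer_slice(tilt_deg = t), c(0, 0), c(0, 1))))
  expect_true(all(diff(e) < 0))
})

test_that("missing tissues are reported by label", {
  sl <- two_layer_slice(1L, 2L)
  tt <- tissue_table()[tissue_table()$label != 2L, ]
  expect_error(trace_ray(sl, c(0, 0), c(0, 1), tt, small_mp()), "2")
})

test_that("cumulative transmission never increases along a ray", {
  tf <- ultrasim:::trace_field(layered_slice(with_bone = TRUE),
                               tissue_table(), small_mp(),
                               ultrasim:::fan_geometry(small_mp()))
  expect_true(all(apply(tf$transmission, 2, function(x) all(diff(x) <= 1e-12))))
})

test_that("speckle honors the scatterer model and the IR preset", {
  mp <- small_mp()
  sl <- homogeneous_slice(7L, nrow_px = 220L, ncol_px = 60L)
  # IR preset: identically zero
  expect_true(all(scatter_profile(sl, c(0, 0), c(0, 1),
                                  tissue_table(), mp) == 0))
  # degenerate distribution (mu0 = 1, sigma0 = 0, mu1 = 0.5), no
  # attenuation, no PSF: constant 0.5 along the in-tissue samples
  tt <- tissue_table()
  tt$alpha[] <- 0
  tt$mu0[tt$label == 7L] <- 1
  tt$mu1[tt$label == 7L] <- 0.5
  prof <- scatter_profile(sl, c(0, 0), c(0, 1), tt, mp, seed = 3, psf = FALSE)
  expect_true(all(abs(prof - 0.5) < 1e-12))  # every sample lies in-tissue
  # seeded determinism
  tt$sigma0[tt$label == 7L] <- 0.2
  p1 <- scatter_profile(sl, c(0, 0), c(0, 1), tt, mp, seed = 11)
  p2 <- scatter_profile(sl, c(0, 0), c(0, 1), tt, mp, seed = 11)
  expect_identical(p1, p2)
  expect_false(identical(p1, scatter_profile(sl, c(0, 0), c(0, 1), tt, mp,
                                             seed = 12)))
})

test_that("envelope composition applies TGC, exponents and normalization", {
  mp <- small_mp()
  K <- mp$axial_samples
  refl <- matrix(0, K, 4)
  refl[c(40, 120, 200), ] <- c(0.2, 0.1, 0.05)
  zero <- matrix(0, K, 4)
  env <- compose_envelope(refl, zero, mp)
  # with scale_exp1 = 1 and no noise, env is proportional to refl * gain
  g <- tgc_gain((seq_len(K) - 0.5) / K, mp)
  expected <- refl * g
  expected <- expected /
    stats::quantile(expected[expected > 0], 0.9, names = FALSE)
  expect_equal(env, pmin(expected, 1), tolerance = 1e-12)
  # both terms zero: zero envelope
  expect_true(all(compose_envelope(zero, zero, mp) == 0))
  # rf_noise = 0 (the default): bit-identical across runs
  expect_identical(compose_envelope(refl, zero, mp, seed = 1),
                   compose_envelope(refl, zero, mp, seed = 2))
  expect_error(compose_envelope(refl, matrix(0, 2, 2), mp), "shape")
})

test_that("scan conversion fills the fan and matches the analytic area", {
  mp <- machine_params()
  env <- matrix(1, mp$axial_samples, mp$scan_lines)
  img <- scan_convert(env, mp, out_size = 256)
  expect_equal(dim(img$pixels), c(256L, 256L))
  expect_true(all(img$pixels[img$fan_mask] >= 0.99))
  expect_true(all(img$pixels[!img$fan_mask] == 0))
  frac <- mean(img$fan_mask)
  expect_lt(abs(frac - fan_geometry(mp)$analytic_fan_fraction) /
              fan_geometry(mp)$analytic_fan_fraction, 0.02)
  expect_error(scan_convert(env, mp, out_size = 8), ">= 16")
})

test_that("IR simulation is bit-reproducible and boundary-sparse", {
  mp <- small_mp()
  ph <- generate_phantom(phantom_config(seed = 31))
  a <- simulate_us(ph$labelmap, mp = mp, mode = "IR", seed = 1, out_size = 128)
  b <- simulate_us(ph$labelmap, mp = mp, mode = "IR", seed = 2, out_size = 128)
  expect_identical(a$pixels, b$pixels)
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))
  expect_lt(mean(a$pixels[a$fan_mask] > 0), 0.10)
})

test_that("bone casts an acoustic shadow", {
  mp <- small_mp()
  no_bone <- simulate_us(layered_slice(FALSE), mp = mp, out_size = 128)
  bone <- simulate_us(layered_slice(TRUE), mp = mp, out_size = 128)
  # region under the disc (disc at 40 mm depth, center column)
  ps <- no_bone$pixel_spacing
  rows <- round(55 / ps):round(100 / ps)
  cols <- round(ncol(no_bone$fan_mask) / 2) + (-8:8)
  below_no <- mean(no_bone$pixels[rows, cols])
  below_yes <- mean(bone$pixels[rows, cols])
  expect_lt(below_yes, 0.5 * below_no)
})

test_that("direction dependence: rotating the anatomy changes the echoes", {
  mp <- small_mp()
  n <- 200L
  g <- matrix(1L, n, n)
  g[101:n, ] <- 2L                       # horizontal interface
  sl_h <- labelmap(g, 0.5, origin = c(0, -50))
  sl_v <- labelmap(t(g), 0.5, origin = c(0, -50))  # rotated 90 degrees
  e_h <- sum(simulate_us(sl_h, mp = mp, out_size = 64)$pixels)
  e_v <- sum(simulate_us(sl_v, mp = mp, out_size = 64)$pixels)
  expect_gt(e_h / max(e_v, 1e-9), 10)
})

test_that("exported masks align with the aorta boundary echoes", {
  mp <- small_mp()
  ph <- generate_phantom(phantom_config(seed = 17))
  # isolate the aorta: everything but blood becomes soft tissue, so every
  # echo in the image belongs to the aorta boundary
  g <- ph$labelmap$grid
  g[g != 5L] <- 7L
  iso <- labelmap(g, ph$labelmap$spacing, origin = ph$labelmap$origin)
  img <- simulate_us(iso, mp = mp, out_size = 128)
  msk <- simulate_mask(ph$aorta_mask, iso, mp, 128)
  contour <- which(ultrasim:::contour_pixels(msk), arr.ind = TRUE)
  echo <- which(img$pixels > 0, arr.ind = TRUE)
  expect_gt(nrow(echo), 20)
  # every aorta echo pixel sits on (or next to) the exported mask contour
  dmin <- vapply(seq_len(nrow(echo)), function(i) {
    sqrt(min((contour[, 1] - echo[i, 1])^2 + (contour[, 2] - echo[i, 2])^2))
  }, numeric(1))
  expect_lte(mean(dmin), 2)
})

test_that("datasets split evenly across volumes with a stable manifest", {
  expect_equal(ultrasim:::split_even(5000, 8), rep(625, 8))
  expect_equal(ultrasim:::split_even(10, 3), c(4, 3, 3))
  mp <- small_mp()
  vols <- lapply(c(41, 42), function(s)
    generate_phantom(phantom_config(seed = s))$labelmap)
  ds <- simulate_dataset(vols, 6, mp = mp, seed = 7, out_size = 64)
  expect_equal(nrow(ds$manifest), 6)
  expect_equal(as.integer(table(ds$manifest$volume)), c(3L, 3L))
  ds2 <- simulate_dataset(vols, 6, mp = mp, seed = 7, out_size = 64)
  expect_identical(ds$manifest, ds2$manifest)
  sub <- select_balanced(ds$manifest, 4, seed = 1)
  expect_equal(as.integer(table(sub$volume)), c(2L, 2L))
})
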