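test_that("labelmap enforces legend coverage and integer labels", {
  expect_error(labelmap(matrix(c(1L, 99L), 2, 2), 1), "99")
  expect_error(labelmap(matrix(1.5, 2, 2), 1), "integer")
  expect_error(labelmap(matrix(1L, 2, 2), c(1, -1)), "positive")
  lm <- labelmap(matrix(c(1L, 5L, 8L, 6L), 2, 2), 0.7)
  expect_s3_class(lm, "labelmap")
})

test_that("labelmaps round-trip through NIfTI and MetaImage", {
  g <- array(sample(c(1L, 5L, 6L, 8L), 16 * 16 * 4, replace = TRUE),
             c(16, 16, 4))
  lm <- labelmap(g, spacing = c(0.5, 0.5, 2.0))
  for (ext in c("roundtrip.nii.gz", "roundtrip.mhd", "roundtrip.mha")) {
    path <- file.path(withr::local_tempdir(), ext)
    write_labelmap(lm, path)
    back <- read_labelmap(path)
    expect_identical(back$grid, lm$grid, label = ext)
    expect_equal(back$spacing, lm$spacing, tolerance = 1e-6, label = ext)
  }
})

test_that("reading a file with labels outside the legend fails loudly", {
  path <- file.path(withr::local_tempdir(), "bad.nii.gz")
  lm <- labelmap(matrix(c(1L, 2L), 4, 4), 1,
                 legend = c(`1` = "Fat", `2` = "Muscle", `99` = "Odd"))
  lm$grid[2, 2] <- 99L
  write_labelmap(lm, path)
  expect_error(read_labelmap(path), "99")  # default legend lacks 99
})

test_that("images quantize to 8-bit PNG within half a grey level", {
  n <- 32L
  fan <- matrix(TRUE, n, n)
  dir <- withr::local_tempdir()

  zero <- ultrasound_image(matrix(0, n, n), 0.5, fan, "IR")
  write_image(zero, file.path(dir, "zero.png"))
  expect_true(all(png::readPNG(file.path(dir, "zero.png")) == 0))

  one <- ultrasound_image(matrix(1, n, n), 0.5, fan, "IR")
  write_image(one, file.path(dir, "one.png"))
  expect_true(all(png::readPNG(file.path(dir, "one.png")) == 1))

  set.seed(4)
  rnd <- ultrasound_image(matrix(runif(n * n), n, n), 0.5, fan, "IR")
  write_image(rnd, file.path(dir, "rnd.png"), seed = 4L)
  back <- png::readPNG(file.path(dir, "rnd.png"))
  expect_lte(max(abs(back - rnd$pixels)), 1 / 255)
  meta <- jsonlite::read_json(file.path(dir, "rnd.png.json"))
  expect_equal(meta$pixel_spacing, 0.5)
  expect_equal(meta$seed, 4L)
})

test_that("ultrasound images zero everything outside the fan", {
  fan <- disc_mask(32, 16, 16, 10)
  img <- ultrasound_image(matrix(0.7, 32, 32), 0.4, fan, "IR")
  expect_true(all(img$pixels[!fan] == 0))
  expect_error(ultrasound_image(matrix(0, 16, 32), 0.4,
                                matrix(TRUE, 16, 32), "IR"), "square")
})

test_that("probe poses interpolate deterministically along the spline", {
  p1 <- probe_pose(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  # single control point: constant
  ps <- sample_probe_poses(list(p1), 5)
  expect_length(ps, 5)
  for (p in ps) expect_equal(p$position, p1$position)
  # two control points: linear, middle pose at the midpoint
  p2 <- probe_pose(c(10, 4, 0), c(0, 0, 1), c(1, 0, 0))
  ps <- sample_probe_poses(list(p1, p2), 3)
  expect_equal(ps[[2]]$position, c(5, 2, 0))
  # deterministic
  expect_identical(sample_probe_poses(list(p1, p2), 7),
                   sample_probe_poses(list(p1, p2), 7))
  expect_error(sample_probe_poses(list(p1), 0), ">= 1")
  # orientation axes stay orthonormal after interpolation
  p3 <- probe_pose(c(20, 0, 5), c(0.3, 0.1, 1), c(1, 0, 0))
  for (p in sample_probe_poses(list(p1, p3), 5)) {
    expect_equal(sum(p$direction^2), 1, tolerance = 1e-12)
    expect_equal(sum(p$direction * p$in_plane), 0, tolerance = 1e-12)
  }
})

test_that("slice extraction matches stored slices and a brute-force oracle", {
  set.seed(11)
  g <- array(sample(c(1L, 2L, 6L, 7L), 16 * 16 * 8, replace = TRUE),
             c(16, 16, 8))
  vol <- labelmap(g, spacing = 1)
  # 2D input with no pose: unchanged
  sl2 <- labelmap(g[, , 1], 1)
  expect_identical(extract_slice(sl2), sl2)
  # axis-aligned pose reproduces the stored slice
  pose <- probe_pose(c(0, 8, 4.5), c(1, 0, 0), c(0, 1, 0))
  sl <- extract_slice(vol, pose, extent_mm = c(16, 16), resolution = 1)
  expect_identical(sl$grid, g[, , 5])
  # oblique pose: compare every pixel against a direct nearest-neighbour
  # lookup computed independently
  th <- 30 * pi / 180
  pose_o <- probe_pose(c(2, 8, 2), c(cos(th), sin(th), 0),
                       c(-sin(th), cos(th), 0))
  sl_o <- extract_slice(vol, pose_o, extent_mm = c(10, 10), resolution = 0.7)
  oracle <- matrix(6L, nrow(sl_o$grid), ncol(sl_o$grid))
  for (r in seq_len(nrow(oracle))) {
    for (cc in seq_len(ncol(oracle))) {
      x <- (cc - 0.5) * 0.7 - 5
      z <- (r - 0.5) * 0.7
      p <- pose_o$position + x * pose_o$in_plane + z * pose_o$direction
      ijk <- floor(p) + 1
      if (all(ijk >= 1) && all(ijk <= dim(g)))
        oracle[r, cc] <- g[ijk[1], ijk[2], ijk[3]]
    }
  }
  expect_identical(sl_o$grid, oracle)
  # only input labels plus Background appear
  expect_true(all(unique(as.integer(sl_o$grid)) %in% c(unique(as.integer(g)), 6L)))
  # plane outside the volume
  far <- probe_pose(c(500, 500, 500), c(1, 0, 0), c(0, 1, 0))
  expect_error(extract_slice(vol, far, c(5, 5), 1), "intersect")
})
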