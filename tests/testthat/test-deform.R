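test_that("aorta dilation scales to the target diameter about the centroid", {
  ph <- generate_phantom(phantom_config(seed = 9))
  lm <- ph$labelmap
  d0 <- ap_diameter(ph$aorta_mask, lm$spacing[1])
  # target equal to the current diameter: identical mask
  same <- dilate_aorta_mask(lm, d0)
  expect_identical(unname(same), unname(ph$aorta_mask))
  # a small-class target lands in the small interval
  m35 <- dilate_aorta_mask(lm, 35)
  expect_gte(ap_diameter(m35, lm$spacing[1]), 30)
  expect_lte(ap_diameter(m35, lm$spacing[1]), 45)
  expect_lte(abs(ap_diameter(m35, lm$spacing[1]) - 35), lm$spacing[1])
  # mask area strictly increases with the target
  areas <- sapply(c(30, 42, 55), function(t)
    sum(dilate_aorta_mask(lm, t)))
  expect_true(all(diff(areas) > 0))
  expect_error(dilate_aorta_mask(lm, 5), "dilation")
})

test_that("deformation interpolant honors its control constraints", {
  ph <- generate_phantom(phantom_config(seed = 9))
  lm <- ph$labelmap
  src <- ph$aorta_mask
  rigid <- lm$grid == 8L
  # src = dst: zero field everywhere
  f0 <- estimate_deformation(src, src, rigid, lm)
  expect_lt(max(abs(f0$dz)), 1e-6)
  expect_lt(max(abs(f0$dx)), 1e-6)
  # a genuine dilation
  dst <- dilate_aorta_mask(lm, 48)
  f <- estimate_deformation(src, dst, rigid, lm)
  # boundary control points reproduce their prescribed displacement
  d_at_ctrl <- eval_deformation(f, f$controls$pts, exact = TRUE)
  expect_lt(max(abs(d_at_ctrl - f$controls$disp)), 1e-6)
  # rigid and border constraints are zero
  d_at_zero <- eval_deformation(f, f$controls$zero_pts, exact = TRUE)
  expect_lt(max(abs(d_at_zero)), 1e-6)
  # rasterized field is exactly zero on every rigid voxel
  expect_true(all(f$dz[rigid] == 0 & f$dx[rigid] == 0))
  expect_true(all(is.finite(f$dz)) && all(is.finite(f$dx)))
  # inconsistent constraints are refused
  expect_error(estimate_deformation(src, dst, dst, lm), "rigid")
  expect_error(estimate_deformation(dst, src, rigid, lm), "contained")
})

test_that("warping is exact for zero and uniform-translation fields", {
  ph <- generate_phantom(phantom_config(seed = 4))
  lm <- ph$labelmap
  d <- dim(lm$grid)
  zero <- structure(list(dz = matrix(0, d[1], d[2]),
                         dx = matrix(0, d[1], d[2]),
                         spacing = lm$spacing, origin = lm$origin),
                    class = "deformation_field")
  expect_identical(apply_deformation(lm, zero)$grid, lm$grid)
  # uniform 5 mm downward displacement = shift by 10 rows (0.5 mm spacing)
  shift <- zero
  shift$dz <- matrix(5, d[1], d[2])
  warped <- apply_deformation(lm, shift)
  oracle <- matrix(6L, d[1], d[2])
  oracle[11:d[1], ] <- lm$grid[1:(d[1] - 10), ]
  expect_identical(warped$grid, oracle)
  # nearest-neighbour lookup cannot invent labels
  expect_true(all(unique(as.integer(warped$grid)) %in%
                    unique(as.integer(lm$grid))))
  bad <- zero
  bad$dz <- matrix(0, 10, 10); bad$dx <- matrix(0, 10, 10)
  expect_error(apply_deformation(lm, bad), "shape")
})

test_that("synthesized aneurysms hit their class interval with a rigid spine", {
  ph <- generate_phantom(phantom_config(seed = 12))
  lm <- ph$labelmap
  bone_before <- lm$grid == 8L
  res <- synthesize_aaa(lm, "medium", seed = 30)
  expect_gte(res$diameter_mm, 45 - lm$spacing[1])
  expect_lte(res$diameter_mm, 55 + lm$spacing[1])
  expect_lte(abs(res$diameter_mm - res$target_diameter), lm$spacing[1])
  expect_equal(dsc(bone_before, res$labelmap$grid == 8L), 1.0)
  expect_true(all(abs(res$field$dz[bone_before]) < 0.1))
  # deterministic
  res2 <- synthesize_aaa(lm, "medium", seed = 30)
  expect_identical(res$labelmap$grid, res2$labelmap$grid)
  expect_equal(res$diameter_mm, res2$diameter_mm)
  # no labels invented
  expect_true(all(unique(as.integer(res$labelmap$grid)) %in%
                    unique(as.integer(lm$grid))))
})

test_that("displacement decays with distance from the aorta boundary", {
  ph <- generate_phantom(phantom_config(seed = 8, include_air = FALSE))
  lm <- ph$labelmap
  res <- synthesize_aaa(lm, "medium", seed = 2)
  f <- res$field
  mag <- sqrt(f$dz^2 + f$dx^2)
  d <- dim(mag)
  ctr <- which(ph$aorta_mask, arr.ind = TRUE)
  cz <- mean(ctr[, 1]); cx <- mean(ctr[, 2])
  rr <- sqrt((matrix(seq_len(d[1]), d[1], d[2]) - cz)^2 +
             (matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cx)^2)
  r_b <- max(rr[res$aorta_mask])  # dilated boundary radius, px
  sel <- rr > r_b & rr < r_b + 80
  bins <- cut(rr[sel], breaks = seq(r_b, r_b + 80, by = 8))
  bin_mean <- tapply(mag[sel], bins, mean)
  rho <- stats::cor(seq_along(bin_mean), bin_mean, method = "spearman")
  expect_lt(rho, 0)
})
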