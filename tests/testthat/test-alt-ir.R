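test_that("edge IR finds no edges in a constant image", {
  mp <- small_mp()
  e <- edge_ir(matrix(0.4, 128, 128), mp, out_size = 128)
  expect_true(all(e$pixels == 0))
  expect_equal(e$mode, "edge")
})

test_that("edge IR traces a bright disc as a thin closed ring", {
  mp <- small_mp()
  n <- 128L
  img <- matrix(0, n, n)
  ctr <- c(60, 64); r <- 22
  img[disc_mask(n, ctr[1], ctr[2], r)] <- 1
  e <- edge_ir(img, mp, out_size = n)
  # analytic circle rasterization: pixels at radius r (within the fan)
  th <- seq(0, 2 * pi, length.out = 720)
  ring <- unique(cbind(pmin(pmax(round(ctr[1] + r * cos(th)), 1), n),
                       pmin(pmax(round(ctr[2] + r * sin(th)), 1), n)))
  fan <- e$fan_mask
  ring <- ring[fan[ring], , drop = FALSE]
  # each analytic ring pixel has a detected edge within 1 px
  hit <- vapply(seq_len(nrow(ring)), function(i) {
    rr <- ring[i, 1]; cc <- ring[i, 2]
    any(e$pixels[max(1, rr - 1):min(n, rr + 1),
                 max(1, cc - 1):min(n, cc + 1)] > 0)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  expect_true(all(e$pixels[!fan] == 0))
})

test_that("all IR variants of a slice share one fan mask", {
  mp <- small_mp()
  ph <- generate_phantom(phantom_config(seed = 19))
  ir <- simulate_us(ph$labelmap, mp = mp, out_size = 64)
  re <- realistic_ir(ph$labelmap, mp = mp, seed = 2, out_size = 64)
  ed <- edge_ir(ph$labelmap, mp, out_size = 64)
  expect_identical(ir$fan_mask, re$fan_mask)
  expect_identical(ir$fan_mask, ed$fan_mask)
})

test_that("speckle fills tissue that the IR leaves black", {
  mp <- small_mp()
  ph <- generate_phantom(phantom_config(seed = 23))
  ir <- simulate_us(ph$labelmap, mp = mp, out_size = 64)
  re <- realistic_ir(ph$labelmap, mp = mp, seed = 5, out_size = 64)
  expect_gt(sum(re$pixels > 0), sum(ir$pixels > 0))
  # reproducible for a fixed seed
  re2 <- realistic_ir(ph$labelmap, mp = mp, seed = 5, out_size = 64)
  expect_identical(re$pixels, re2$pixels)
})

test_that("zeroing speckle recovers the IR image from the realistic path", {
  mp <- small_mp(log_compression_db = 0)
  ph <- generate_phantom(phantom_config(seed = 23))
  ir <- simulate_us(ph$labelmap, mp = mp, mode = "IR", out_size = 64)
  re <- realistic_ir(ph$labelmap, tt = tissue_table("ir"), mp = mp,
                     seed = 5, out_size = 64)
  expect_equal(re$pixels, ir$pixels, tolerance = 1e-12)
})

test_that("edge IR preserves no acoustic shadow, the physics IR does", {
  mp <- small_mp()
  sl <- layered_slice(with_bone = TRUE)
  ir <- simulate_us(sl, mp = mp, out_size = 128)
  ed <- edge_ir(sl, mp, out_size = 128)
  ir_nb <- simulate_us(layered_slice(FALSE), mp = mp, out_size = 128)
  ed_nb <- edge_ir(layered_slice(FALSE), mp, out_size = 128)
  # deep-interface band under the disc columns
  ps <- ir$pixel_spacing
  rows <- round(86 / ps):round(96 / ps)
  cols <- 64 + (-6:6)
  shadow_ir <- mean(ir$pixels[rows, cols]) /
    max(mean(ir_nb$pixels[rows, cols]), 1e-9)
  shadow_ed <- mean(ed$pixels[rows, cols]) /
    max(mean(ed_nb$pixels[rows, cols]), 1e-9)
  expect_lt(shadow_ir, 0.5)   # attenuation suppresses the deep echo
  expect_gt(shadow_ed, 0.5)   # edge detection keeps it
})
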