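noisy_map <- function(seed = 4) {
  net <- generate_network(ras_minus_params(rng_seed = seed, n_isv = 5,
                                           isv_length_px = 60))
  vesselquant:::normalize01(
    add_map_noise(rasterize_network(net, "all"), 0.8, 0.02, seed)$pixels)
}

test_that("SSIM is exactly 1 for identical maps and symmetric in its arguments", {
  img <- noisy_map()
  r <- ssim(img, img)
  expect_identical(r$global, 1)
  expect_true(all(r$local == 1))
  shifted <- img + 0.3
  expect_identical(ssim(img, shifted)$global, ssim(shifted, img)$global)
})

test_that("local SSIM is bounded and the luminance term isolates constant offsets", {
  set.seed(2)
  a <- matrix(runif(60 * 50), 60, 50)
  b <- matrix(runif(60 * 50), 60, 50)
  r <- ssim(a, b)
  expect_true(all(abs(r$local) <= 1 + 1e-12))
  expect_lt(r$global, 1)
  # constant images offset by a constant: structure term 1, luminance < 1
  ca <- matrix(0.2, 40, 40); cb <- matrix(0.7, 40, 40)
  rc <- ssim(ca, cb, dynamic_range = 1)
  c1 <- (0.01 * 1)^2
  lum <- (2 * 0.2 * 0.7 + c1) / (0.2^2 + 0.7^2 + c1)
  expect_equal(rc$global, lum, tolerance = 1e-12)
  expect_error(ssim(ca, cb, window_size = 51), "window")
  expect_error(ssim(ca, matrix(0, 10, 10)), "shape")
})

test_that("SSIM separates matched RAS- pairs from partially perfused RAS+ pairs", {
  score <- function(params_fn, seed) {
    net <- generate_network(params_fn(rng_seed = seed))
    gfp <- vesselquant:::normalize01(
      add_map_noise(rasterize_network(net, "all"), 0.5, 0.02, seed)$pixels)
    flow <- vesselquant:::normalize01(
      add_map_noise(rasterize_network(net, "perfused"), 0.5, 0.02,
                    seed + 1)$pixels)
    ssim(flow, gfp)$global
  }
  minus <- vapply(1:4, function(s) score(ras_minus_params, s), numeric(1))
  plus <- vapply(1:4, function(s) score(ras_plus_params, s), numeric(1))
  expect_true(all(outer(minus, plus, `>`)))
})

test_that("co-registration recovers known shifts and rotations", {
  img <- noisy_map()
  r0 <- coregister(img, img, rotations = 0)
  expect_equal(unname(r0$transform), c(0, 0, 0, 1), tolerance = 0.05)
  expect_gt(r0$correlation, 0.999)
  shifted <- matrix(0, nrow(img), ncol(img))
  shifted[6:nrow(img), 4:ncol(img)] <-
    img[1:(nrow(img) - 5), 1:(ncol(img) - 3)]
  r1 <- coregister(shifted, img, rotations = 0)
  expect_equal(unname(r1$transform[1:2]), c(-5, -3), tolerance = 0.5)
  rot <- vesselquant:::apply_similarity(img, 0, 0, 2, 1)
  rot[!is.finite(rot)] <- 0
  r2 <- coregister(rot, img, rotations = seq(-4, 4, by = 1))
  expect_equal(unname(r2$transform[3]), -2, tolerance = 0.25)
  # hopeless input: warn and fall back to identity
  expect_warning(rlow <- coregister(matrix(runif(400), 20, 20),
                                    matrix(runif(400), 20, 20),
                                    rotations = 0, floor = 0.9),
                 "identity")
  expect_equal(unname(rlow$transform), c(0, 0, 0, 1))
})

test_that("red-green merge encodes perfusion overlap as yellow", {
  octa <- matrix(0, 10, 10); octa[3, 3] <- 1
  gfp <- matrix(0, 10, 10); gfp[3, 3] <- 1; gfp[7, 7] <- 1
  rgb <- merge_red_green(octa, gfp)
  expect_identical(dim(rgb), c(10L, 10L, 3L))
  expect_equal(rgb[3, 3, ], c(1, 1, 0))   # perfused vessel: yellow
  expect_equal(rgb[7, 7, ], c(0, 1, 0))   # structure only: green
  expect_equal(rgb[1, 1, ], c(0, 0, 0))   # background: black
  expect_true(all(rgb[, , 3] == 0))
  expect_error(merge_red_green(octa, matrix(0, 5, 5)), "shape")
})
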