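make_series <- function(v = 0, n_repeats = 4, dt = 0.16, bulk = 0,
                        noise = 0, seed = 1, nz = 8, nx = 10) {
  ph <- flow_phantom(matrix(1, nz, nx), matrix(v, nz, nx),
                     bulk_offsets_rad = bulk, phase_noise_sd = noise)
  simulate_bm_series(ph, n_repeats = n_repeats, dt_s = dt, seed = seed)
}

test_that("phase differences are wrapped, counted, and validated", {
  s <- make_series(v = 100)
  fr <- phase_difference(s, 1)
  expect_identical(dim(fr$phase)[1], 3L)
  expect_true(all(fr$phase > -pi & fr$phase <= pi))
  expect_error(phase_difference(s, 0), "pair_separation")
  expect_error(phase_difference(s, 4), "pair_separation")
  # doubling the separation doubles the noiseless Doppler phase mod 2pi
  expect_equal(max(abs(phase_difference(s, 2)$phase -
                         doppler_phase(100, 0.32))), 0, tolerance = 1e-9)
  expect_equal(phase_difference(s, 2)$dt_eff_s, 0.32)
})

test_that("bulk removal cancels common-mode offsets exactly and masks dim pixels", {
  s <- make_series(bulk = c(0, 1.3, -0.8, 0.5))
  fr <- unwrap_and_debulk(phase_difference(s, 1))
  expect_lt(max(abs(fr$phase)), 1e-12)
  # Doppler + bulk equals pure Doppler after correction on a mixed phantom
  nz <- 8; nx <- 10
  vel <- matrix(0, nz, nx); vel[4:5, 6:7] <- 40  # static majority
  mk <- function(bulk) {
    ph <- flow_phantom(matrix(1, nz, nx), vel, bulk_offsets_rad = bulk)
    simulate_bm_series(ph, n_repeats = 3, dt_s = 0.16, seed = 4)
  }
  a <- unwrap_and_debulk(phase_difference(mk(c(0, 0.9, -0.6)), 1))
  b <- unwrap_and_debulk(phase_difference(mk(0), 1))
  expect_equal(a$phase, b$phase, tolerance = 1e-9)
  # sub-threshold pixels contribute zero contrast
  intens <- matrix(1, nz, nx); intens[, 1:3] <- 0.01
  phm <- flow_phantom(intens, phase_noise_sd = 0.5)
  s2 <- simulate_bm_series(phm, n_repeats = 3, dt_s = 0.16, seed = 5)
  fr2 <- unwrap_and_debulk(phase_difference(s2, 1), mask_threshold = 0.5)
  ct <- aggregate_contrast(fr2)
  expect_true(all(ct[, 1:3] == 0))
  expect_false(all(fr2$mask[, 1:3]))
})

test_that("contrast aggregation distinguishes mean-absolute and variance rules", {
  s <- make_series(v = 30)
  # raw frames: a uniformly moving phantom has no static reference, so the
  # bulk stage stays out of the aggregation contract being tested
  fr <- phase_difference(s, 1)
  dphi <- abs(doppler_phase(30, 0.16))
  # constant Doppler across frames: mean |dphi| keeps it, variance kills it
  expect_equal(max(abs(aggregate_contrast(fr, "mean_abs") - dphi)), 0,
               tolerance = 1e-9)
  expect_equal(max(aggregate_contrast(fr, "variance")), 0, tolerance = 1e-9)
  # all-zero frames aggregate to zero
  s0 <- make_series()
  expect_true(all(aggregate_contrast(phase_difference(s0, 1)) == 0))
  # uniform random phases approach the uniform variance pi^2/3
  fr_u <- structure(
    list(phase = array(runif(1e4 * 4, -pi, pi), dim = c(1e4, 2, 2)),
         intensity = matrix(1, 2, 2)), class = "octa_frames")
  expect_equal(mean(aggregate_contrast(fr_u, "variance")), pi^2 / 3,
               tolerance = 0.05)
})

test_that("median filtering removes salt noise but preserves wide vessels", {
  img <- matrix(0, 40, 60)
  img[18:24, ] <- 1                       # 7-px-wide vessel
  salt <- rbind(c(5, 10), c(9, 40), c(33, 22))
  img[salt] <- 1
  avol <- structure(list(contrast = array(t(img), dim = c(1, 60, 40)),
                         pair_separation = 1L, dt_eff_s = 0.16,
                         method = "mean_abs", pixel_size_um = 1.4),
                    class = "angiogram_volume")
  ef <- denoise_and_project(avol, median_radius_px = 3)
  expect_true(all(ef$pixels[salt] == 0))
  expect_true(all(ef$pixels[20:22, 10:50] > 0))
  # brute-force median check at one interior vessel pixel
  w <- img[(21 - 3):(21 + 3), (30 - 3):(30 + 3)]
  expect_equal(ef$pixels[21, 30], median(w))
})

test_that("projection is idempotent and all-zero volumes stay zero", {
  z1 <- structure(list(contrast = array(runif(1 * 30 * 20),
                                        dim = c(1, 30, 20)),
                       pair_separation = 1L, dt_eff_s = 0.16,
                       method = "mean_abs", pixel_size_um = 1.4),
                  class = "angiogram_volume")
  ef <- denoise_and_project(z1, median_radius_px = 0)
  expect_equal(ef$pixels, vesselquant:::normalize01(t(z1$contrast[1, , ])))
  z0 <- z1; z0$contrast[] <- 0
  expect_true(all(denoise_and_project(z0)$pixels == 0))
})

test_that("the final en-face map is invariant to per-repeat bulk offsets", {
  net <- generate_network(ras_minus_params(rng_seed = 8, n_isv = 4,
                                           isv_length_px = 60))
  base <- simulate_network_volume(net, n_repeats = 3, seed = 2,
                                  bulk_sd_rad = 0)
  bulk <- simulate_network_volume(net, n_repeats = 3, seed = 2,
                                  bulk_sd_rad = 0.8)
  a <- reconstruct_enface(base, threshold = 0.15)
  b <- reconstruct_enface(bulk, threshold = 0.15)
  expect_lt(max(abs(a$pixels - b$pixels)), 1e-6)
})

test_that("measured phase contrast is linear in v * dt below the wrap", {
  vs <- c(0.05, 0.1, 0.15, 0.2)  # um/s at 160 ms: well below wrap
  got <- vapply(vs, function(v) {
    s <- make_series(v = v, n_repeats = 3)
    mean(aggregate_contrast(phase_difference(s, 1)))
  }, numeric(1))
  slope <- coef(lm(got ~ I(vs * 1e-6 * 0.16) - 1))[[1]]
  expect_equal(slope, 4 * pi * 1.33 / 800e-9, tolerance = 0.02)
})

test_that("interscan-time comparison peaks at the intermediate preset for slow flow with jitter", {
  mk_vol <- function(v, brown, noise) {
    nz <- 8; nx <- 50; ny <- 16
    vel <- matrix(0, nz, nx); vel[4:5, 21:30] <- v
    build_volume(lapply(seq_len(ny), function(y) {
      phm <- flow_phantom(matrix(0.4, nz, nx) + (vel > 0) * 0.6, vel,
                          phase_noise_sd = noise,
                          brownian_sd_rad_sqrt_s = brown)
      simulate_bm_series(phm, n_repeats = 12, dt_s = 0.030, seed = 500 + y)
    }))
  }
  vmask <- matrix(FALSE, 16, 50); vmask[, 21:30] <- TRUE
  bmask <- matrix(FALSE, 16, 50); bmask[, 1:15] <- TRUE
  rep1 <- select_interscan(mk_vol(0.75, 0.35, 0.02), c(1, 5, 11),
                           vmask, bmask)
  expect_identical(rep1$pair_separation[which.max(rep1$contrast_ratio)], 5L)
  # no-noise limit: vessel contrast is monotone in j until the wrap
  rep2 <- select_interscan(mk_vol(0.3, 0, 0), c(1, 5, 11), vmask, bmask)
  expect_true(all(diff(rep2$vessel_contrast) > 0))
  expect_error(select_interscan(mk_vol(0.3, 0, 0), 2, vmask, bmask),
               "two")
})
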