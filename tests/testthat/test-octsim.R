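test_that("static noiseless phantoms give identical repeats and zero phase difference", {
  ph <- flow_phantom(matrix(1, 10, 12))
  s <- simulate_bm_series(ph, n_repeats = 4, dt_s = 0.16, seed = 3)
  for (r in 2:4) expect_equal(s$data[r, , ], s$data[1, , ])
  fr <- phase_difference(s, 1)
  expect_true(all(fr$phase == 0))
})

test_that("Doppler phase follows the closed form across velocities and interscan times", {
  for (v in c(10, 100, 230, 580)) for (dt in c(0.030, 0.160, 0.330)) {
    ph <- flow_phantom(matrix(1, 8, 8), matrix(v, 8, 8))
    s <- simulate_bm_series(ph, n_repeats = 3, dt_s = dt, seed = 1)
    fr <- phase_difference(s, 1)
    want <- doppler_phase(v, dt)  # wrapped to (-pi, pi]
    expect_equal(max(abs(fr$phase - want)), 0, tolerance = 1e-9)
  }
})

test_that("velocities beyond the wrap alias exactly per the modulo rule", {
  # one-interval phase > pi: 100 um/s at 160 ms -> 334 rad
  raw <- 4 * pi * 1.33 * 100e-6 * 0.16 / 800e-9
  expect_gt(raw, pi)
  wrapped <- doppler_phase(100, 0.16)
  expect_lt(abs(wrapped), pi + 1e-12)
  expect_equal((raw - wrapped) %% (2 * pi), 0, tolerance = 1e-6)
})

test_that("constant bulk offsets add to the Doppler term", {
  ph <- flow_phantom(matrix(1, 6, 6), matrix(50, 6, 6),
                     bulk_offsets_rad = c(0, 0.8, -0.4))
  s <- simulate_bm_series(ph, n_repeats = 3, dt_s = 0.16, seed = 2)
  fr <- phase_difference(s, 1)
  dop <- doppler_phase(50, 0.16, wrap = FALSE)
  expect_equal(fr$phase[1, , ],
               matrix(vesselquant:::wrap_phase(dop + 0.8), 6, 6))
  expect_equal(fr$phase[2, , ],
               matrix(vesselquant:::wrap_phase(dop - 1.2), 6, 6))
})

test_that("bm series validate their inputs", {
  ph <- flow_phantom(matrix(1, 4, 4))
  expect_error(simulate_bm_series(ph, dt_s = 0), "dt_s")
  expect_error(simulate_bm_series(ph, n_repeats = 1), "n_repeats")
  expect_error(flow_phantom(matrix(-1, 2, 2)))
})

test_that("volumes assemble consistently and round-trip bit-exactly through the container", {
  mk <- function(seed) simulate_bm_series(flow_phantom(matrix(1, 4, 6)),
                                          n_repeats = 3, dt_s = 0.16,
                                          seed = seed)
  vol <- build_volume(lapply(1:5, mk))
  expect_identical(dim(vol$data), c(5L, 3L, 4L, 6L))
  expect_identical(vol$data[2, , , ], mk(2)$data)
  bad <- simulate_bm_series(flow_phantom(matrix(1, 5, 6)), n_repeats = 3,
                            dt_s = 0.16, seed = 9)
  expect_error(build_volume(list(mk(1), bad)), "identical")
  f <- withr::local_tempfile(fileext = ".octvol")
  write_oct_volume(vol, f)
  expect_identical(read_oct_volume(f), vol)
})

test_that("network volumes mark flow only where perfused vessels lie", {
  net <- generate_network(ras_plus_params(rng_seed = 6))
  vol <- simulate_network_volume(net, n_repeats = 2, seed = 3,
                                 phase_noise_sd = 0, amp_noise_sd = 0)
  fr_all <- Arg(vol$data[, 2, , ] * Conj(vol$data[, 1, , ]))
  moving <- apply(abs(fr_all) > 1e-9, c(1, 3), any)  # (y, x)
  perf <- rasterize_network(net, "perfused")$pixels > 0
  expect_true(all(moving == perf))
})
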