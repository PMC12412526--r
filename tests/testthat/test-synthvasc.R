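test_that("a regular phenotype yields straight, evenly spaced ISVs with forced junction count", {
  p <- phenotype_params(n_isv = 6, rng_seed = 2)
  net <- generate_network(p)
  # each ISV meets the ventral axis and the DLAV exactly once
  expect_identical(nrow(net$junctions), 12L)
  # zero wiggle / zero bend: every chain is straight
  expect_equal(net$vessels$arc_length / net$vessels$chord_length,
               rep(1, nrow(net$vessels)), tolerance = 1e-9)
  # ISVs are evenly spaced and parallel
  isv_x <- vapply(net$vessels$points[net$vessels$kind == "isv"],
                  function(ch) mean(ch$x), numeric(1))
  expect_equal(diff(sort(isv_x)), rep(p$isv_spacing_px, 5))
})

test_that("every junction lies on at least two centerlines", {
  for (seed in c(1, 9)) {
    net <- generate_network(ras_plus_params(rng_seed = seed))
    for (i in seq_len(nrow(net$junctions))) {
      j <- net$junctions[i, ]
      d <- vapply(j$vessel_ids[[1]], function(vid) {
        m <- as.matrix(net$vessels$points[[vid]][, c("x", "y")])
        min(sqrt((m[, 1] - j$x)^2 + (m[, 2] - j$y)^2))
      }, numeric(1))
      expect_length(d, 2)
      expect_lt(max(d), 0.6)
    }
  }
})

test_that("wiggled ISV arc lengths match a dense independent polyline integral", {
  net <- generate_network(ras_plus_params(rng_seed = 3))
  isvs <- net$vessels[net$vessels$kind == "isv", ]
  for (i in seq_len(nrow(isvs))) {
    ch <- isvs$points[[i]]
    # independent oracle: resample the recorded sub-pixel curve at 1e4
    # points through plain linear interpolation and sum segment lengths
    t_in <- seq(0, 1, length.out = nrow(ch))
    t_out <- seq(0, 1, length.out = 1e4)
    x <- stats::approx(t_in, ch$x, xout = t_out)$y
    y <- stats::approx(t_in, ch$y, xout = t_out)$y
    oracle <- sum(sqrt(diff(x)^2 + diff(y)^2))
    expect_equal(isvs$arc_length[i], oracle, tolerance = 1e-4)
    expect_gte(isvs$arc_length[i], isvs$chord_length[i])
  }
})

test_that("analytic tortuosity strictly increases with wiggle amplitude", {
  torts <- vapply(c(0, 1, 2, 4), function(a) {
    net <- generate_network(phenotype_params(wiggle_amplitude_px = a,
                                             rng_seed = 4))
    ground_truth_metrics(net)$tortuosity
  }, numeric(1))
  expect_true(all(diff(torts) > 0))
  expect_equal(torts[1], 1, tolerance = 1e-9)
})

test_that("junction count and density never decrease with added hyperbranches", {
  res <- lapply(c(0, 2, 4, 6), function(k) {
    net <- generate_network(ras_plus_params(rng_seed = 5,
                                            n_hyperbranches = k))
    c(nrow(net$junctions), mean(rasterize_network(net, "all")$pixels > 0))
  })
  juncs <- vapply(res, `[`, numeric(1), 1)
  dens <- vapply(res, `[`, numeric(1), 2)
  expect_true(all(diff(juncs) >= 0))
  expect_true(all(diff(dens) >= 0))
  # each bridge adds exactly two junctions
  expect_equal(juncs, 16 + 2 * c(0, 2, 4, 6))
})

test_that("generation is deterministic and rejects impossible hyperbranch requests", {
  a <- generate_network(ras_plus_params(rng_seed = 11))
  b <- generate_network(ras_plus_params(rng_seed = 11))
  expect_identical(rasterize_network(a, "all")$pixels,
                   rasterize_network(b, "all")$pixels)
  expect_error(generate_network(phenotype_params(n_isv = 3,
                                                 n_hyperbranches = 7)),
               "slots")
  expect_error(phenotype_params(n_isv = 1), "n_isv")
  expect_error(phenotype_params(perfused_fraction = 1.2),
               "perfused_fraction")
})

test_that("rasterization obeys the subset law and matches a per-pixel distance oracle", {
  for (seed in 1:5) {
    net <- generate_network(ras_plus_params(rng_seed = seed))
    all_r <- rasterize_network(net, "all")$pixels
    per_r <- rasterize_network(net, "perfused")$pixels
    expect_true(all(per_r <= all_r))
  }
  # perfused_fraction = 1 makes the two rasters identical
  net1 <- generate_network(ras_plus_params(rng_seed = 2,
                                           perfused_fraction = 1))
  expect_identical(rasterize_network(net1, "all")$pixels,
                   rasterize_network(net1, "perfused")$pixels)
  # single straight vessel: pixel count equals brute-force disk sweep
  net <- straight_vessel_network(length_px = 100, radius = 2)
  img <- rasterize_network(net, "all")$pixels
  seg <- list(a = c(10, 30), b = c(110, 30))  # (x, y)
  count <- 0L
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    ab <- seg$b - seg$a
    t <- max(0, min(1, sum((c(c, r) - seg$a) * ab) / sum(ab^2)))
    d <- sqrt(sum((c(c, r) - seg$a - t * ab)^2))
    if (d <= 2) count <- count + 1L
  }
  expect_identical(sum(img > 0), count)
})

test_that("truth metrics errors on a non-intersecting ROI", {
  net <- generate_network(phenotype_params(rng_seed = 1))
  expect_error(ground_truth_metrics(net, roi = c(1, 4, 1, 4)), "ROI")
})
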