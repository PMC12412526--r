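test_that("simple shapes skeletonize to the expected graphs", {
  skb <- skeleton_graph(bar_mask())
  expect_identical(nrow(skb$edges), 1L)
  expect_identical(sum(skb$nodes$kind == "endpoint"), 2L)
  expect_identical(sum(skb$nodes$kind == "junction"), 0L)
  skt <- skeleton_graph(t_mask(), pre_skeletonized = TRUE)
  expect_identical(sum(skt$nodes$kind == "junction"), 1L)
  expect_identical(sum(skt$nodes$kind == "endpoint"), 3L)
  expect_error(skeletonize_mask(matrix(FALSE, 5, 5)), "empty")
})

test_that("tortuosity is exactly 1 for straight vessels and pi/2 for a semicircle", {
  expect_identical(tortuosity(skeleton_graph(bar_mask())), 1)
  # windowed oracle on a dense semicircular arc spanning the full window
  arc <- semicircle_chain(r = 40)
  L <- vesselquant:::chain_length(arc)
  ratios <- vesselquant:::windowed_arc_chord(arc, window_px = L)
  expect_equal(ratios, pi / 2, tolerance = 0.01)
  expect_error(tortuosity(skeleton_graph(bar_mask()), segment_len_px = 20,
                          short_edges = "drop", step_px = 1e6), NA)
})

test_that("skeleton-based tortuosity matches the analytic windowed oracle within 2%", {
  for (seed in c(2, 7)) {
    net <- generate_network(ras_plus_params(rng_seed = seed))
    m <- vessel_metrics(rasterize_network(net, "all")$pixels > 0)
    truth <- ground_truth_metrics(net)
    expect_equal(m$tortuosity, truth$tortuosity, tolerance = 0.02)
  }
})

test_that("orientation sigma recovers the axis-bend scale", {
  # all-horizontal vessels: essentially a delta histogram
  expect_lte(orientation_sigma(skeleton_graph(bar_mask())), 1)
  # 5-degree bend, axis-dominated phantom (no wiggle, no bridges)
  sig <- vapply(1:4, function(s) {
    net <- generate_network(phenotype_params(axis_bend_sigma_deg = 5,
                                             rng_seed = s))
    vessel_metrics(rasterize_network(net, "all")$pixels > 0)$orientation_sigma_deg
  }, numeric(1))
  expect_equal(mean(sig), 5, tolerance = 1)
  # bent RAS+-style axis always exceeds straight RAS--style axis
  s_plus <- vessel_metrics(rasterize_network(
    generate_network(phenotype_params(axis_bend_sigma_deg = 8,
                                      wiggle_amplitude_px = 3,
                                      rng_seed = 3)), "all")$pixels > 0)
  s_minus <- vessel_metrics(rasterize_network(
    generate_network(phenotype_params(rng_seed = 3)), "all")$pixels > 0)
  expect_gt(s_plus$orientation_sigma_deg, s_minus$orientation_sigma_deg)
})

test_that("vessel density counts ROI pixels exactly and respects translation", {
  m <- bar_mask()
  roi <- c(1, 20, 1, 120)
  expect_equal(vessel_density(m, roi), sum(m) / (20 * 120))
  expect_identical(vessel_density(matrix(TRUE, 5, 5)), 1)
  expect_identical(vessel_density(matrix(FALSE, 5, 5)), 0)
  shifted <- matrix(FALSE, 20, 120)
  shifted[9:13 + 2, 11:110] <- TRUE
  expect_identical(vessel_density(shifted, roi), vessel_density(m, roi))
})

test_that("mean vessel diameter follows the area-over-length identity", {
  m <- bar_mask(rows = 9:13)  # 5 px wide, pixel pitch 1.4 um
  sk <- skeleton_graph(m)
  d <- mean_vessel_diameter(m, sk)
  expect_equal(d / 1.4, 5, tolerance = 0.12)
  # two equal-length bars of widths 3 and 7: length-weighted mean 5 px
  m2 <- matrix(FALSE, 40, 120)
  m2[9:11, 11:110] <- TRUE
  m2[29:35, 11:110] <- TRUE
  sk2 <- skeleton_graph(m2)
  expect_equal(mean_vessel_diameter(m2, sk2) / 1.4, 5, tolerance = 0.12)
  # generator raster: diameter within 1 px of twice the class radius
  net <- generate_network(ras_minus_params(rng_seed = 5,
                                           radius_jitter_px = 0))
  mm <- vessel_metrics(rasterize_network(net, "all")$pixels > 0)
  expect_equal(mm$mean_vessel_diameter_um / 1.4, 5, tolerance = 1)
})

test_that("diameter in um is invariant to consistent rescaling within 5%", {
  net <- generate_network(ras_minus_params(rng_seed = 2,
                                           radius_jitter_px = 0))
  m1 <- vessel_metrics(rasterize_network(net, "all")$pixels > 0,
                       pixel_size_um = 1.4)
  net2 <- generate_network(ras_minus_params(
    rng_seed = 2, radius_jitter_px = 0,
    isv_spacing_px = 63, isv_length_px = 120, wiggle_period_px = 60,
    margin_px = c(30, 45),
    vessel_radius_px = c(axis = 3.75, isv = 3.75, bridge = 3.75)))
  m2 <- vessel_metrics(rasterize_network(net2, "all")$pixels > 0,
                       pixel_size_um = 1.4 / 1.5)
  expect_equal(m2$mean_vessel_diameter_um, m1$mean_vessel_diameter_um,
               tolerance = 0.05)
})

test_that("bifurcation density counts junctions over ROI-normalized length", {
  roi <- c(1, 20, 1, 120)
  expect_identical(bifurcations_per_length(skeleton_graph(bar_mask()), roi),
                   0)
  skt <- skeleton_graph(t_mask(), pre_skeletonized = TRUE)
  roi_t <- c(1, 25, 1, 25)
  expect_equal(bifurcations_per_length(skt, roi_t),
               1 / (skt$total_length_px / (25 * 25)))
  # each added bridge contributes exactly two junctions
  base <- vessel_metrics(rasterize_network(
    generate_network(ras_plus_params(rng_seed = 9, n_hyperbranches = 0)),
    "all")$pixels > 0)
  plus3 <- vessel_metrics(rasterize_network(
    generate_network(ras_plus_params(rng_seed = 9, n_hyperbranches = 3)),
    "all")$pixels > 0)
  expect_identical(plus3$n_junctions - base$n_junctions, 6L)
})

test_that("automatic binarization recovers generator vessels and its symmetries", {
  net <- generate_network(ras_minus_params(rng_seed = 3))
  truth <- rasterize_network(net, "all")$pixels > 0
  noisy <- add_map_noise(rasterize_network(net, "all"), 0.8, 0.05, 3)
  mask <- binarize_auto(noisy)
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice, 0.85)
  inv_mask <- binarize_auto(1 - vesselquant:::normalize01(noisy$pixels),
                            invert = TRUE)
  expect_identical(inv_mask, mask)
  expect_error(binarize_auto(matrix(1, 10, 10)), "constant")
})

test_that("fitted orientation sigma survives a 90-degree rotation", {
  net <- generate_network(phenotype_params(axis_bend_sigma_deg = 6,
                                           rng_seed = 4))
  m <- rasterize_network(net, "all")$pixels > 0
  s1 <- vessel_metrics(m)$orientation_sigma_deg
  s2 <- vessel_metrics(t(m))$orientation_sigma_deg
  expect_equal(s1, s2, tolerance = 0.5)
})

test_that("the metric orchestrator is deterministic and mode-aware", {
  net <- generate_network(ras_plus_params(rng_seed = 12))
  map <- add_map_noise(rasterize_network(net, "all"), 0.5, 0.02, 12)
  a <- vessel_metrics(map)
  b <- vessel_metrics(map)
  expect_identical(a, b)
  roi <- c(11, 110, 31, 300)
  r <- vessel_metrics(rasterize_network(net, "all")$pixels > 0, roi = roi)
  expect_true(all(is.finite(unlist(r[1:5]))))
  expect_gte(r$tortuosity, 1)
  expect_true(r$vessel_density >= 0 && r$vessel_density <= 1)
  expect_error(vessel_metrics(matrix(FALSE, 30, 30)), "vessel")
})
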