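# Shared fixtures, built in code at test time.

bar_mask <- function(nrow = 20, ncol = 120, rows = 9:13, cols = 11:110) {
  m <- matrix(FALSE, nrow, ncol)
  m[rows, cols] <- TRUE
  m
}

t_mask <- function() {
  m <- matrix(FALSE, 25, 25)
  m[13, 3:23] <- TRUE
  m[13:23, 13] <- TRUE
  m
}

# dense semicircular arc of radius r (sub-pixel polyline)
semicircle_chain <- function(r = 40, n = 4001) {
  th <- seq(0, pi, length.out = n)
  cbind(x = 50 + r * cos(th), y = 50 + r * sin(th))
}

# a single straight horizontal vessel, drawn through the generator's
# swept-disk rasterizer
straight_vessel_network <- function(length_px = 200, radius = 2.5) {
  net <- generate_network(phenotype_params(n_isv = 2, rng_seed = 1))
  v <- net$vessels[1, ]
  v$points[[1]] <- tibble::tibble(x = seq(10, 10 + length_px, by = 0.5),
                                  y = 30)
  v$radius_px <- radius
  net$vessels <- v
  net$junctions <- net$junctions[0, ]
  net$image_shape <- c(rows = 60L, cols = as.integer(length_px + 20))
  net
}

# small, fast study configuration for smoke tests
tiny_study_config <- function(n = 2, seed = 5) {
  study_config(
    groups = list(
      ras_minus = list(params_fn = function(rng_seed)
        ras_minus_params(rng_seed = rng_seed, n_isv = 4, isv_length_px = 60)),
      ras_plus = list(params_fn = function(rng_seed)
        ras_plus_params(rng_seed = rng_seed, n_isv = 4, isv_length_px = 60,
                        n_hyperbranches = 3))
    ),
    n_per_group = n, seed = seed,
    acquisition = list(n_repeats = 2, n_z = 6)
  )
}
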