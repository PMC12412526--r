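# Complex-valued BM-scan OCT simulation with closed-form Doppler phase.

#' Closed-form Doppler phase shift
#'
#' Phase advance accumulated by an axially moving scatterer between two
#' B-scans separated by `dt_s`: `4 * pi * n * v * dt / lambda`, wrapped to
#' `(-pi, pi]` when `wrap = TRUE`.
#'
#' @param v_um_s axial velocity in µm/s (positive = towards the beam).
#' @param dt_s effective interscan time in seconds.
#' @param wavelength_m center wavelength in meters (default 800 nm).
#' @param refractive_index sample group refractive index (default 1.33).
#' @param wrap wrap to the principal interval?
#' @export
doppler_phase <- function(v_um_s, dt_s, wavelength_m = 800e-9,
                          refractive_index = 1.33, wrap = TRUE) {
  phi <- 4 * pi * refractive_index * (v_um_s * 1e-6) * dt_s / wavelength_m
  if (wrap) wrap_phase(phi) else phi
}

#' Define a flow phantom for the BM-scan simulator
#'
#' A cross-sectional phantom at one slow-axis position: reflectivity and
#' axial-velocity maps over (depth z, fast axis x), per-repeat global bulk
#' phase offsets, and noise levels. `brownian_sd_rad_sqrt_s` adds a per-pixel
#' diffusive phase random walk (sd grows as sqrt of elapsed time), emulating
#' Brownian/bulk micro-motion of nominally static tissue; it is what makes
#' long interscan times progressively noisier.
#'
#' @param intensity matrix (z, x) of backscattered amplitudes, >= 0.
#' @param velocity_um_s matrix (z, x) of axial speeds in µm/s (0 = static).
#' @param bulk_offsets_rad numeric vector of per-repeat global phase offsets
#'   (recycled/padded with 0), emulating whole-sample axial motion.
#' @param phase_noise_sd per-pixel, per-repeat random phase noise sd (rad).
#' @param amp_noise_sd additive amplitude noise sd.
#' @param brownian_sd_rad_sqrt_s diffusive phase jitter in rad per sqrt(s).
#' @export
flow_phantom <- function(intensity, velocity_um_s = NULL,
                         bulk_offsets_rad = 0,
                         phase_noise_sd = 0, amp_noise_sd = 0,
                         brownian_sd_rad_sqrt_s = 0) {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)),
            all(intensity >= 0))
  if (is.null(velocity_um_s)) velocity_um_s <- intensity * 0
  stopifnot(identical(dim(intensity), dim(velocity_um_s)))
  stopifnot(phase_noise_sd >= 0, amp_noise_sd >= 0,
            brownian_sd_rad_sqrt_s >= 0)
  structure(
    list(intensity = intensity, velocity_um_s = velocity_um_s,
         bulk_offsets_rad = bulk_offsets_rad,
         phase_noise_sd = phase_noise_sd, amp_noise_sd = amp_noise_sd,
         brownian_sd_rad_sqrt_s = brownian_sd_rad_sqrt_s),
    class = "flow_phantom"
  )
}

#' Simulate a BM-scan series (repeated complex B-scans)
#'
#' Repeat `r` (0-based in the phase model) accumulates, per pixel, the phase
#' `r * 4*pi*n*v*dt/lambda + bulk_r + noise` on top of a random static
#' speckle phase; the amplitude is the phantom reflectivity plus amplitude
#' noise. Deterministic for a fixed seed.
#'
#' @param phantom a [flow_phantom()].
#' @param n_repeats number of repeated B-scans (>= 2).
#' @param dt_s inter-repeat time in seconds (> 0). Presets used throughout
#'   are 0.030, 0.160 and 0.330 s.
#' @param wavelength_m,refractive_index optical constants (800 nm, 1.33).
#' @param axial_pixel_um,lateral_pixel_um pixel pitches carried as metadata.
#' @param seed integer RNG seed.
#' @return object of class `bm_series`: complex array `data[repeat, z, x]`
#'   plus acquisition metadata.
#' @export
simulate_bm_series <- function(phantom, n_repeats = 4, dt_s = 0.160,
                               wavelength_m = 800e-9, refractive_index = 1.33,
                               axial_pixel_um = 2.9, lateral_pixel_um = 1.4,
                               seed = 1L) {
  stopifnot(inherits(phantom, "flow_phantom"))
  if (dt_s <= 0) abort("`dt_s` must be > 0")
  if (n_repeats < 2) abort("`n_repeats` must be >= 2")
  old <- .Random.seed_store(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  nz <- nrow(phantom$intensity); nx <- ncol(phantom$intensity)
  bulk <- rep_len(c(phantom$bulk_offsets_rad,
                    rep(0, n_repeats)), n_repeats)
  dphi <- doppler_phase(phantom$velocity_um_s, dt_s,
                        wavelength_m, refractive_index, wrap = FALSE)
  static_phase <- matrix(runif(nz * nx, -pi, pi), nz, nx)

  data <- array(complex(real = 0), dim = c(n_repeats, nz, nx))
  brown <- matrix(0, nz, nx)
  for (r in seq_len(n_repeats)) {
    if (r > 1 && phantom$brownian_sd_rad_sqrt_s > 0) {
      brown <- brown + matrix(
        rnorm(nz * nx, 0, phantom$brownian_sd_rad_sqrt_s * sqrt(dt_s)), nz, nx)
    }
    ph <- static_phase + (r - 1) * dphi + bulk[r] + brown
    if (phantom$phase_noise_sd > 0) {
      ph <- ph + matrix(rnorm(nz * nx, 0, phantom$phase_noise_sd), nz, nx)
    }
    amp <- phantom$intensity
    if (phantom$amp_noise_sd > 0) {
      amp <- amp + matrix(rnorm(nz * nx, 0, phantom$amp_noise_sd), nz, nx)
    }
    data[r, , ] <- amp * exp(1i * ph)
  }
  structure(
    list(data = data, n_repeats = n_repeats, dt_s = dt_s,
         wavelength_m = wavelength_m, refractive_index = refractive_index,
         axial_pixel_um = axial_pixel_um, lateral_pixel_um = lateral_pixel_um,
         slow_axis_index = NA_integer_),
    class = "bm_series"
  )
}

#' @export
print.bm_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bm_series> %d repeats x %d depth x %d lateral px, dt = %g ms\n",
              d[1], d[2], d[3], x$dt_s * 1e3))
  invisible(x)
}

#' Assemble BM-scan series from successive slow-axis positions into a volume
#'
#' @param series_list list of [simulate_bm_series()] results with identical
#'   shapes and acquisition metadata; element i becomes slow-axis position i.
#' @return object of class `oct_volume`: complex array
#'   `data[y, repeat, z, x]` plus shared metadata.
#' @export
build_volume <- function(series_list) {
  stopifnot(length(series_list) >= 1,
            all(map_lgl(series_list, inherits, "bm_series")))
  dims <- map(series_list, function(s) dim(s$data))
  if (length(unique(map_chr0(dims))) != 1) {
    abort("all BM-scan series must have identical (repeat, z, x) shapes")
  }
  meta <- series_list[[1]][c("n_repeats", "dt_s", "wavelength_m",
                             "refractive_index", "axial_pixel_um",
                             "lateral_pixel_um")]
  if (!all(map_lgl(series_list, function(s) {
    isTRUE(all.equal(s$dt_s, meta$dt_s)) &&
      isTRUE(all.equal(s$wavelength_m, meta$wavelength_m))
  }))) abort("BM-scan series have inconsistent acquisition metadata")
  d <- dims[[1]]
  data <- array(complex(real = 0), dim = c(length(series_list), d))
  for (i in seq_along(series_list)) data[i, , , ] <- series_list[[i]]$data
  structure(c(list(data = data, n_slow = length(series_list)), meta),
            class = "oct_volume")
}

map_chr0 <- function(dims) vapply(dims, paste, character(1), collapse = "x")

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<oct_volume> %d slow x %d repeats x %d depth x %d lateral px, dt = %g ms\n",
    d[1], d[2], d[3], d[4], x$dt_s * 1e3))
  invisible(x)
}

#' Simulate an OCT volume for a rasterized vascular network
#'
#' Embeds the 2-D en-face vasculature into a thin 3-D slab: static tissue
#' fills a depth band, vessel pixels (from the structural raster) get higher
#' reflectivity at the vessel depth, and perfused pixels carry the axial
#' velocity of their vessel class (from the velocity raster). One BM-scan
#' series is simulated per image row (slow-axis position).
#'
#' @param network a [generate_network()] result.
#' @param n_repeats,dt_s,seed acquisition settings (see
#'   [simulate_bm_series()]).
#' @param n_z depth pixels of the slab.
#' @param tissue_intensity,vessel_intensity reflectivity levels.
#' @param phase_noise_sd,amp_noise_sd,brownian_sd_rad_sqrt_s noise levels
#'   passed to every [flow_phantom()].
#' @param bulk_sd_rad sd of the per-repeat, per-row global bulk phase offset
#'   (0 = no bulk motion).
#' @param ... further arguments to [simulate_bm_series()].
#' @return an `oct_volume` whose slow axis matches the raster rows.
#' @export
simulate_network_volume <- function(network, n_repeats = 3, dt_s = 0.160,
                                    n_z = 8, tissue_intensity = 0.35,
                                    vessel_intensity = 1,
                                    phase_noise_sd = 0.08, amp_noise_sd = 0.02,
                                    brownian_sd_rad_sqrt_s = 0,
                                    bulk_sd_rad = 0, seed = 1L,
                                    wavelength_m = 800e-9,
                                    refractive_index = 1.33,
                                    axial_pixel_um = 2.9,
                                    lateral_pixel_um = NULL) {
  struct <- rasterize_network(network, "all")$pixels
  vel <- rasterize_network(network, "perfused", value = "velocity")$pixels
  ny <- nrow(struct); nx <- ncol(struct)
  z_band <- max(2L, floor(n_z / 2)):min(n_z - 1L, floor(n_z / 2) + 1L)
  old <- .Random.seed_store(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 77L))

  intensity <- array(tissue_intensity, dim = c(ny, n_z, nx))  # (y, z, x)
  velocity <- array(0, dim = c(ny, n_z, nx))
  vmask <- struct > 0
  for (z in z_band) {
    plane <- intensity[, z, ]
    plane[vmask] <- vessel_intensity
    intensity[, z, ] <- plane
    velocity[, z, ] <- vel
  }
  dphi <- doppler_phase(velocity, dt_s, wavelength_m, refractive_index,
                        wrap = FALSE)
  npx <- ny * n_z * nx
  static_phase <- array(runif(npx, -pi, pi), dim = c(ny, n_z, nx))
  # always consume the bulk draws so switching bulk motion on or off never
  # reshuffles the downstream noise realizations
  bulk_draws <- matrix(rnorm(ny * n_repeats), ny, n_repeats) * bulk_sd_rad

  data <- array(complex(real = 0), dim = c(ny, n_repeats, n_z, nx))
  brown <- 0
  for (r in seq_len(n_repeats)) {
    if (r > 1 && brownian_sd_rad_sqrt_s > 0) {
      brown <- brown + array(rnorm(npx, 0, brownian_sd_rad_sqrt_s *
                                     sqrt(dt_s)), dim = c(ny, n_z, nx))
    }
    ph <- static_phase + (r - 1) * dphi + brown +
      array(bulk_draws[, r], dim = c(ny, n_z, nx))
    if (phase_noise_sd > 0) ph <- ph + array(rnorm(npx, 0, phase_noise_sd),
                                             dim = c(ny, n_z, nx))
    amp <- intensity
    if (amp_noise_sd > 0) amp <- amp + array(rnorm(npx, 0, amp_noise_sd),
                                             dim = c(ny, n_z, nx))
    data[, r, , ] <- amp * exp(1i * ph)
  }
  structure(
    list(data = data, n_slow = ny, n_repeats = n_repeats, dt_s = dt_s,
         wavelength_m = wavelength_m, refractive_index = refractive_index,
         axial_pixel_um = axial_pixel_um,
         lateral_pixel_um = lateral_pixel_um %||%
           network$params$pixel_size_um),
    class = "oct_volume"
  )
}
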