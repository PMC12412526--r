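#' Parameters of the synthetic trunk-vasculature generator
#'
#' Describes a parametric 2-D model of the zebrafish trunk vasculature between
#' roughly 72 and 120 hpf: a ventral axial vessel pair (dorsal aorta / caudal
#' artery, drawn as one centerline), a dorsal longitudinal anastomotic vessel
#' (DLAV), and evenly spaced intersegmental vessels (ISVs) joining the two.
#' The oncogene-driven (RAS+) phenotype is emulated by extra "hyperbranch"
#' bridges between adjacent ISVs (each only perfused with probability
#' `perfused_fraction`), sinusoidal ISV wiggle raising tortuosity, and a
#' low-frequency bend of the axial vessels controlled by
#' `axis_bend_sigma_deg`.
#'
#' @param n_isv number of intersegmental vessels (>= 2).
#' @param isv_spacing_px horizontal spacing between ISVs in pixels.
#' @param isv_length_px dorsoventral extent of the ISVs in pixels.
#' @param axis_bend_sigma_deg standard deviation (degrees) of the local
#'   tangent angle of the DA/CA and DLAV centerlines. 0 gives straight axes.
#' @param wiggle_amplitude_px amplitude of the sinusoidal transverse
#'   perturbation of ISV centerlines (0 gives straight ISVs).
#' @param wiggle_period_px period of that sinusoid along the ISV.
#' @param n_hyperbranches number of extra bridges connecting adjacent ISVs.
#' @param hyperbranch_slots number of height bands available per adjacent ISV
#'   pair (bounds the number of bridges that fit).
#' @param vessel_radius_px named vector of half-diameters in pixels for the
#'   vessel classes `axis`, `isv`, `bridge`.
#' @param radius_jitter_px standard deviation of a per-larva radius offset
#'   added to every vessel class (animal-to-animal size variation; the
#'   paper-scale biological spread of mean vessel diameter is of order 1 µm,
#'   far larger than any digitization effect). Default 0.
#' @param perfused_fraction probability in `[0, 1]` that a hyperbranch
#'   carries flow (trunk vessels are always perfused).
#' @param velocity_um_s named vector of axial blood speeds (µm/s) per vessel
#'   class used by the OCT simulator: `axis_da`, `axis_dlav`, `isv`, `bridge`.
#' @param pixel_size_um physical pixel pitch in µm.
#' @param margin_px border kept free of vasculature, c(row, col) or scalar.
#' @param rng_seed integer seed; identical parameters and seed give
#'   bit-identical networks and rasters.
#' @return an object of class `phenotype_params` (a named list).
#' @seealso [ras_minus_params()], [ras_plus_params()], [generate_network()]
#' @export
phenotype_params <- function(n_isv = 8,
                             isv_spacing_px = 42,
                             isv_length_px = 80,
                             axis_bend_sigma_deg = 0,
                             wiggle_amplitude_px = 0,
                             wiggle_period_px = 40,
                             n_hyperbranches = 0,
                             hyperbranch_slots = 3,
                             vessel_radius_px = c(axis = 3, isv = 2, bridge = 2),
                             radius_jitter_px = 0,
                             perfused_fraction = 1,
                             velocity_um_s = c(axis_da = 580, axis_dlav = 230,
                                               isv = 8, bridge = 4),
                             pixel_size_um = 1.4,
                             margin_px = c(20, 30),
                             rng_seed = 1L) {
  stopifnot_scalar_number(n_isv, "n_isv", lower = 2)
  stopifnot_scalar_number(perfused_fraction, "perfused_fraction", 0, 1)
  stopifnot_scalar_number(wiggle_amplitude_px, "wiggle_amplitude_px", lower = 0)
  stopifnot_scalar_number(axis_bend_sigma_deg, "axis_bend_sigma_deg", lower = 0)
  stopifnot_scalar_number(wiggle_period_px, "wiggle_period_px", lower = 1)
  stopifnot_scalar_number(n_hyperbranches, "n_hyperbranches", lower = 0)
  if (!all(c("axis", "isv", "bridge") %in% names(vessel_radius_px))) {
    abort("`vessel_radius_px` needs entries named axis, isv, bridge")
  }
  if (isv_spacing_px <= 2 * max(vessel_radius_px)) {
    abort("`isv_spacing_px` must exceed twice the largest vessel radius")
  }
  if (length(margin_px) == 1) margin_px <- rep(margin_px, 2)
  p <- list(
    n_isv = as.integer(n_isv), isv_spacing_px = isv_spacing_px,
    isv_length_px = isv_length_px,
    axis_bend_sigma_deg = axis_bend_sigma_deg,
    wiggle_amplitude_px = wiggle_amplitude_px,
    wiggle_period_px = wiggle_period_px,
    n_hyperbranches = as.integer(n_hyperbranches),
    hyperbranch_slots = as.integer(hyperbranch_slots),
    vessel_radius_px = vessel_radius_px,
    radius_jitter_px = radius_jitter_px,
    perfused_fraction = perfused_fraction,
    velocity_um_s = velocity_um_s,
    pixel_size_um = pixel_size_um,
    margin_px = margin_px,
    rng_seed = as.integer(rng_seed)
  )
  p$image_shape <- c(
    rows = as.integer(ceiling(2 * margin_px[1] + isv_length_px)),
    cols = as.integer(ceiling(2 * margin_px[2] + (n_isv - 1) * isv_spacing_px))
  )
  structure(p, class = "phenotype_params")
}

#' Preset: healthy (RAS-) trunk phenotype
#'
#' Regular, mildly wiggly ISVs, nearly straight axial vessels, no
#' hyperbranches, fully perfused network. The mild residual wiggle and bend
#' emulate the biological variability visible in healthy larvae rather than a
#' mathematically perfect grid.
#'
#' @param rng_seed integer seed.
#' @param ... overrides passed to [phenotype_params()].
#' @export
ras_minus_params <- function(rng_seed = 1L, ...) {
  args <- utils::modifyList(
    list(axis_bend_sigma_deg = 2.5, wiggle_amplitude_px = 1,
         n_hyperbranches = 0, perfused_fraction = 1,
         vessel_radius_px = c(axis = 2.5, isv = 2.5, bridge = 2.5),
         radius_jitter_px = 0.15,
         rng_seed = rng_seed),
    list(...)
  )
  do.call(phenotype_params, args)
}

#' Preset: oncogene-expressing (RAS+) trunk phenotype
#'
#' Hyperbranched bridges between adjacent ISVs (mostly non-perfused),
#' stronger ISV wiggle (higher tortuosity) and a pronounced bend of the
#' axial vessels.
#'
#' @inheritParams ras_minus_params
#' @export
ras_plus_params <- function(rng_seed = 1L, ...) {
  args <- utils::modifyList(
    list(axis_bend_sigma_deg = 8, wiggle_amplitude_px = 3,
         n_hyperbranches = 6, perfused_fraction = 0.3,
         vessel_radius_px = c(axis = 2.5, isv = 2.5, bridge = 2.5),
         radius_jitter_px = 0.15,
         rng_seed = rng_seed),
    list(...)
  )
  do.call(phenotype_params, args)
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat("<phenotype_params>\n")
  cat(sprintf("  %d ISVs, spacing %.0f px, length %.0f px; image %d x %d px\n",
              x$n_isv, x$isv_spacing_px, x$isv_length_px,
              x$image_shape[1], x$image_shape[2]))
  cat(sprintf("  wiggle %.1f px / period %.0f px; axis bend sigma %.1f deg\n",
              x$wiggle_amplitude_px, x$wiggle_period_px, x$axis_bend_sigma_deg))
  cat(sprintf("  hyperbranches %d (perfused fraction %.2f); seed %d\n",
              x$n_hyperbranches, x$perfused_fraction, x$rng_seed))
  invisible(x)
}
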