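# Analytic ground-truth topology metrics for generated networks. These are
# computed from the continuous centerlines (and an exact raster for density),
# independently of the skeleton pipeline, so parameter-recovery tests can
# compare the image-analysis estimates against them.

# Clip a chain to an ROI, splitting it wherever it leaves the box.
clip_chain_roi <- function(pts, roi) {
  m <- chain_matrix(pts)
  inside <- m[, 2] >= roi[1] & m[, 2] <= roi[2] &
    m[, 1] >= roi[3] & m[, 1] <= roi[4]
  if (!any(inside)) return(list())
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(k) m[starts[k]:ends[k], , drop = FALSE])
}

#' Analytic topology metrics of a generated network
#'
#' Computes the five vessel-network descriptors directly from the generator's
#' continuous centerlines: tortuosity as the mean windowed arc/chord ratio
#' (20-px windows, 1-px stride, matching [tortuosity()]), orientation sigma
#' from the Gaussian fit to the centerline tangent-angle histogram, vessel
#' density from the exact swept-disk raster, mean diameter as vessel pixel
#' count over centerline length, and bifurcations per ROI-normalized length
#' from the exact junction count.
#'
#' @param network a [generate_network()] result.
#' @param roi optional ROI `c(r0, r1, c0, c1)`; default full image.
#' @param which `"all"` (structural/GFP channel) or `"perfused"` (flow
#'   channel): which subset of vessels the truth refers to.
#' @param window_px,step_px tortuosity window and stride, in pixels.
#' @return one-row tibble of class `topology_metrics`.
#' @export
ground_truth_metrics <- function(network, roi = NULL,
                                 which = c("all", "perfused"),
                                 window_px = 20, step_px = 1) {
  stopifnot(inherits(network, "vessel_network"))
  which <- match.arg(which)
  roi <- check_roi(roi, network$image_shape)
  vs <- network$vessels
  if (which == "perfused") vs <- vs[vs$perfused, ]
  keep_ids <- vs$id

  chains <- unlist(lapply(vs$points, clip_chain_roi, roi = roi),
                   recursive = FALSE)
  if (length(chains) == 0) abort("ROI does not intersect the vessel network")

  ratios <- unlist(lapply(chains, windowed_arc_chord,
                          window_px = window_px, step_px = step_px))
  tort <- mean(ratios)

  angles <- unlist(lapply(chains, chain_tangent_angles))
  sigma <- fit_angle_sigma(angles)

  rast <- rasterize_network(network, which = which)
  mask <- crop_roi(rast$pixels, roi) > 0
  density <- mean(mask)

  total_len <- sum(map_dbl(chains, chain_length))
  area <- roi_area(roi)
  diameter_px <- sum(mask) / total_len
  diameter_um <- diameter_px * network$params$pixel_size_um

  jt <- network$junctions
  j_in <- jt$y >= roi[1] & jt$y <= roi[2] & jt$x >= roi[3] & jt$x <= roi[4]
  j_in <- j_in & map_lgl(jt$vessel_ids, function(ids) all(ids %in% keep_ids))
  n_junctions <- sum(j_in)
  bif <- n_junctions / (total_len / area)

  new_topology_metrics(
    tortuosity = tort,
    orientation_sigma_deg = sigma,
    vessel_density = density,
    mean_vessel_diameter_um = diameter_um,
    bifurcations_per_length = bif,
    n_junctions = n_junctions,
    total_length_px = total_len,
    n_windows = length(ratios),
    source = "analytic-truth"
  )
}

new_topology_metrics <- function(...) {
  out <- tibble(...)
  class(out) <- c("topology_metrics", class(out))
  out
}
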