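# The five vessel-network descriptors: tortuosity, axis-orientation sigma,
# vessel density, mean vessel diameter, bifurcations per vessel length.

# Multiscale Hessian ridge (vesselness) response for bright curvilinear
# structures: at each Gaussian scale the response is the scale-normalized
# magnitude of the most negative Hessian eigenvalue (zero where it is
# positive); the maximum over scales is returned.
ridge_filter <- function(img, scales = c(1, 2, 3)) {
  resp <- img * 0
  for (s in scales) {
    sm <- as.matrix(EBImage::gblur(img, sigma = s))
    dxx <- sm * 0; dyy <- sm * 0; dxy <- sm * 0
    n <- nrow(sm); m <- ncol(sm)
    dyy[2:(n - 1), ] <- sm[1:(n - 2), ] - 2 * sm[2:(n - 1), ] + sm[3:n, ]
    dxx[, 2:(m - 1)] <- sm[, 1:(m - 2)] - 2 * sm[, 2:(m - 1)] + sm[, 3:m]
    dy <- sm * 0
    dy[2:(n - 1), ] <- (sm[3:n, ] - sm[1:(n - 2), ]) / 2
    dxy[, 2:(m - 1)] <- (dy[, 3:m] - dy[, 1:(m - 2)]) / 2
    tr <- dxx + dyy
    det_h <- dxx * dyy - dxy^2
    disc <- sqrt(pmax(tr^2 / 4 - det_h, 0))
    lam2 <- tr / 2 - disc  # more negative eigenvalue
    resp <- pmax(resp, s^2 * pmax(-lam2, 0))
  }
  resp
}

# CLAHE wrapper tolerant of image sizes not divisible by the tile grid.
clahe_pad <- function(img, nx = 8, ny = 8, ...) {
  nr <- nrow(img); nc <- ncol(img)
  nr2 <- ceiling(nr / nx) * nx
  nc2 <- ceiling(nc / ny) * ny
  pad <- matrix(0, nr2, nc2)
  pad[seq_len(nr), seq_len(nc)] <- img
  if (nr2 > nr) pad[(nr + 1):nr2, seq_len(nc)] <-
    img[rev(seq_len(nr2 - nr)), , drop = FALSE]
  if (nc2 > nc) pad[, (nc + 1):nc2] <-
    pad[, rev(seq_len(nc2 - nc)), drop = FALSE]
  out <- as.matrix(EBImage::clahe(EBImage::Image(clamp(pad, 0, 1)),
                                  nx = nx, ny = ny, ...))
  out[seq_len(nr), seq_len(nc)]
}

#' Automatic vessel binarization
#'
#' Pipeline: multiscale Hessian ridge filter for curvilinear structures,
#' contrast-limited adaptive histogram equalization, then a global Otsu
#' threshold extended by hysteresis: pixels above `hysteresis_fraction`
#' times the Otsu value are kept when their connected component touches an
#' above-threshold pixel. Hysteresis retains faint but contiguous vessels
#' (slow flow barely above background) that a single global cut would drop;
#' `hysteresis_fraction = 1` reduces to the plain Otsu threshold. With
#' `invert = TRUE` dark-vessel images are inverted first.
#'
#' @param map an [en_face_map()] or numeric matrix (vessels bright).
#' @param scales ridge-filter Gaussian scales in px, matched to expected
#'   vessel half-widths.
#' @param clahe apply adaptive histogram equalization before thresholding?
#' @param hysteresis_fraction weak-threshold fraction of the Otsu value.
#' @param invert vessels darker than background?
#' @return logical matrix mask with attribute `threshold` (the Otsu value).
#' @export
binarize_auto <- function(map, scales = c(1, 2, 3), clahe = TRUE,
                          hysteresis_fraction = 0.45, invert = FALSE) {
  img <- as_pixels(map)
  if (diff(range(img)) == 0) abort("cannot Otsu-threshold a constant image")
  img <- normalize01(img)
  if (invert) img <- 1 - img
  resp <- normalize01(ridge_filter(img, scales))
  if (clahe) resp <- clahe_pad(resp)
  thr <- EBImage::otsu(EBImage::Image(clamp(resp, 0, 1)))
  strong <- resp > thr
  if (hysteresis_fraction < 1) {
    weak <- resp > hysteresis_fraction * thr
    lab <- EBImage::bwlabel(weak)
    keep <- setdiff(unique(lab[strong]), 0)
    mask <- matrix(lab %in% keep, nrow(lab))
  } else {
    mask <- strong
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Vessel tortuosity (windowed arc/chord ratio)
#'
#' For every skeleton edge, a window of fixed path length slides along the
#' (smoothed) pixel chain with the given stride; each window contributes the
#' ratio of its path length to the Euclidean distance between its endpoints.
#' The metric is the unweighted mean over all windows of all edges; 1.0
#' corresponds to perfectly straight segments. Edges shorter than the window
#' contribute a single whole-edge ratio (configurable via `short_edges`).
#'
#' @param skel a [skeleton_graph()] result.
#' @param segment_len_px window path length (default 20 px).
#' @param step_px window stride (default 1 px, maximally overlapping).
#' @param short_edges `"whole"` (default) to keep sub-window edges as one
#'   ratio each, `"drop"` to ignore them.
#' @return scalar tortuosity >= 1.
#' @export
tortuosity <- function(skel, segment_len_px = 20, step_px = 1,
                       short_edges = c("whole", "drop")) {
  stopifnot(inherits(skel, "vessel_skeleton"))
  short_edges <- match.arg(short_edges)
  w <- skel$settings$smooth_window
  ratios <- unlist(lapply(skel$edges$points, function(p) {
    sm <- smooth_chain(p, w)
    if (short_edges == "drop" && chain_length(sm) < segment_len_px) {
      return(numeric(0))
    }
    windowed_arc_chord(sm, segment_len_px, step_px)
  }))
  if (length(ratios) == 0) {
    abort("no edge long enough for a tortuosity window")
  }
  mean(ratios)
}

#' Orientation sigma of the vascular axis
#'
#' Local orientation (degrees, folded to `[-90, 90)`) is measured for every
#' skeleton chain position by central differences over +/- 2 px; a Gaussian
#' is fitted to the 1-degree histogram around its dominant mode (the axial
#' DA/CA peak) and the fitted sigma returned. Larger sigma = more randomly
#' oriented vessels / a more bent axis.
#'
#' @param skel a [skeleton_graph()] result.
#' @param smooth_window chain-smoothing window for the tangent measurement.
#'   Orientation needs a longer smoothing scale (default 15 px) than length
#'   measurement: on digitized chains of gently sloped vessels the tangent
#'   otherwise collapses onto the exact-0-degree runs between staircase
#'   jogs, biasing the fitted sigma low.
#' @return sigma in degrees.
#' @export
orientation_sigma <- function(skel, smooth_window = 15L) {
  stopifnot(inherits(skel, "vessel_skeleton"))
  angles <- unlist(lapply(skel$edges$points, function(p) {
    chain_tangent_angles(smooth_chain(p, smooth_window))
  }))
  fit_angle_sigma(angles)
}

#' Vessel density within an ROI
#'
#' Fraction of ROI pixels classified as vessel.
#'
#' @param mask logical vessel mask.
#' @param roi ROI `c(r0, r1, c0, c1)`; default full image.
#' @export
vessel_density <- function(mask, roi = NULL) {
  roi <- check_roi(roi, dim(mask))
  mean(crop_roi(mask, roi) > 0)
}

#' Mean vessel diameter
#'
#' Vessel area over centerline length: density divided by skeleton length
#' normalized to the ROI area, which reduces to vessel pixel count divided
#' by skeleton length, converted to µm.
#'
#' @param mask logical vessel mask.
#' @param skel matching [skeleton_graph()].
#' @param roi ROI; default full image.
#' @param pixel_size_um pixel pitch (default from the skeleton).
#' @export
mean_vessel_diameter <- function(mask, skel, roi = NULL,
                                 pixel_size_um = skel$pixel_size_um) {
  roi <- check_roi(roi, dim(mask))
  len <- skel$total_length_px
  if (len <= 0) abort("zero skeleton length")
  sum(crop_roi(mask, roi) > 0) / len * pixel_size_um
}

#' Bifurcations per vessel length
#'
#' Junction-node count divided by skeleton length normalized to the ROI
#' area (a.u.). The normalization convention is recorded with the result;
#' only ratios and directions between groups are comparable across setups.
#'
#' @param skel a [skeleton_graph()] result.
#' @param roi ROI the skeleton was computed over.
#' @export
bifurcations_per_length <- function(skel, roi) {
  if (skel$total_length_px <= 0) abort("zero skeleton length")
  nj <- sum(skel$nodes$kind == "junction")
  nj / (skel$total_length_px / roi_area(roi))
}

#' All five topology metrics of an en-face map or mask
#'
#' Orchestrates binarization (unless a mask is supplied), skeletonization
#' and the five descriptors over an ROI. Identical inputs and settings give
#' identical outputs.
#'
#' @param x an [en_face_map()], numeric matrix (auto-binarized) or logical
#'   matrix (used as the mask directly, emulating manual segmentation).
#' @param roi ROI `c(r0, r1, c0, c1)`; default full image.
#' @param pixel_size_um pixel pitch in µm.
#' @param segment_len_px tortuosity window (default 20 px).
#' @param merge_radius_px,prune_px skeleton graph settings.
#' @param ... passed to [binarize_auto()] when auto-binarizing.
#' @return one-row tibble of class `topology_metrics`.
#' @export
vessel_metrics <- function(x, roi = NULL, pixel_size_um = NULL,
                           segment_len_px = 20, merge_radius_px = 2,
                           prune_px = 3, ...) {
  if (inherits(x, "en_face_map")) {
    pixel_size_um <- pixel_size_um %||% x$pixel_size_um
    roi <- roi %||% x$roi
    px <- x$pixels
    mask <- if (is.logical(px)) px else binarize_auto(x, ...)
  } else if (is.logical(x)) {
    mask <- x
  } else {
    mask <- binarize_auto(x, ...)
  }
  pixel_size_um <- pixel_size_um %||% 1.4
  roi <- check_roi(roi, dim(mask))
  sub <- crop_roi(mask, roi)
  if (!any(sub)) abort("ROI contains no vessel pixels")
  skel <- skeleton_graph(sub, pixel_size_um = pixel_size_um,
                         merge_radius_px = merge_radius_px,
                         prune_px = prune_px)
  roi_local <- c(1L, nrow(sub), 1L, ncol(sub))
  new_topology_metrics(
    tortuosity = tortuosity(skel, segment_len_px),
    orientation_sigma_deg = orientation_sigma(skel),
    vessel_density = vessel_density(sub, roi_local),
    mean_vessel_diameter_um = mean_vessel_diameter(sub, skel, roi_local),
    bifurcations_per_length = bifurcations_per_length(skel, roi_local),
    n_junctions = sum(skel$nodes$kind == "junction"),
    total_length_px = skel$total_length_px,
    n_windows = NA_integer_,
    source = "image-pipeline"
  )
}
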