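# Swept-disk rasterization of vessel centerlines, and the en-face map type.

#' Construct an en-face map
#'
#' A thin container for a 2-D non-negative image: the axial maximum
#' projection of an angiography volume (channel `"OCTA-flow"`), a fluorescence
#' z-projection (`"GFP-structure"`), or their merge. Pixels are indexed
#' `[row, col]`, 1-based (see R/io.R for conventions).
#'
#' @param pixels numeric matrix, finite and non-negative.
#' @param pixel_size_um physical pixel pitch in µm.
#' @param channel one of `"OCTA-flow"`, `"GFP-structure"`, `"merged"`.
#' @param roi optional ROI `c(r0, r1, c0, c1)` (1-based, inclusive).
#' @export
en_face_map <- function(pixels, pixel_size_um = 1.4,
                        channel = c("OCTA-flow", "GFP-structure", "merged"),
                        roi = NULL) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !all(is.finite(pixels))) {
    abort("`pixels` must be a finite numeric matrix")
  }
  if (any(pixels < 0)) abort("`pixels` must be non-negative")
  if (!is.null(roi)) roi <- check_roi(roi, dim(pixels))
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel = channel, roi = roi),
    class = "en_face_map"
  )
}

#' @export
print.en_face_map <- function(x, ...) {
  cat(sprintf("<en_face_map> %s, %d x %d px (%.2f um/px), range [%.3g, %.3g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_pixels <- function(x) {
  if (inherits(x, "en_face_map")) x$pixels else x
}

# Exact squared distance from every pixel center in a bounding box to a
# polyline, computed segment by segment (vectorized over pixels).
polyline_min_dist2 <- function(m, rows, cols) {
  px <- rep(cols, each = length(rows))   # x = column
  py <- rep(rows, times = length(cols))  # y = row
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(m) - 1)) {
    ax <- m[i, 1]; ay <- m[i, 2]
    bx <- m[i + 1, 1]; by <- m[i + 1, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- pmin(d2, (px - ax)^2 + (py - ay)^2)
    } else {
      t <- clamp(((px - ax) * dx + (py - ay) * dy) / len2, 0, 1)
      d2 <- pmin(d2, (px - ax - t * dx)^2 + (py - ay - t * dy)^2)
    }
  }
  matrix(d2, nrow = length(rows))
}

#' Rasterize a vessel network into an en-face map
#'
#' Draws every vessel as a disk of its class radius swept along the
#' centerline: a pixel is vessel iff the distance from its center to the
#' centerline polyline is at most the radius. No anti-aliasing, so pixel
#' counts are exactly reproducible. The `"perfused"` raster (the OCTA flow
#' channel analogue) is by construction a pixelwise subset of the `"all"`
#' raster (the GFP structural channel analogue).
#'
#' @param network a [generate_network()] result.
#' @param which `"all"` for every vessel, `"perfused"` for flowing ones only.
#' @param image_shape c(rows, cols); defaults to the network's own shape.
#' @param value what to write into vessel pixels: `"binary"` writes 1,
#'   `"velocity"` writes the per-class axial speed in µm/s (pixels covered by
#'   several vessels take the maximum).
#' @param chain_step resampling step (px) of the centerline polyline before
#'   distance evaluation.
#' @return an [en_face_map()] (channel `GFP-structure` for `"all"`, channel
#'   `OCTA-flow` otherwise).
#' @export
rasterize_network <- function(network,
                              which = c("all", "perfused"),
                              image_shape = NULL,
                              value = c("binary", "velocity"),
                              chain_step = 1) {
  stopifnot(inherits(network, "vessel_network"))
  which <- match.arg(which)
  value <- match.arg(value)
  shape <- image_shape %||% network$image_shape
  img <- matrix(0, shape[[1]], shape[[2]])
  vs <- network$vessels
  if (which == "perfused") vs <- vs[vs$perfused, ]
  for (i in seq_len(nrow(vs))) {
    m <- resample_chain(vs$points[[i]], step = chain_step)
    r <- vs$radius_px[i]
    if (any(m[, 1] < 1 - r) || any(m[, 1] > shape[[2]] + r) ||
        any(m[, 2] < 1 - r) || any(m[, 2] > shape[[1]] + r)) {
      abort("vessel centerline exceeds image bounds; enlarge `image_shape`")
    }
    rows <- max(1, floor(min(m[, 2]) - r)):min(shape[[1]], ceiling(max(m[, 2]) + r))
    cols <- max(1, floor(min(m[, 1]) - r)):min(shape[[2]], ceiling(max(m[, 1]) + r))
    d2 <- polyline_min_dist2(m, rows, cols)
    hit <- d2 <= r^2
    val <- if (value == "binary") 1 else vs$velocity_um_s[i]
    sub <- img[rows, cols, drop = FALSE]
    sub[hit] <- pmax(sub[hit], val)
    img[rows, cols] <- sub
  }
  en_face_map(img, pixel_size_um = network$params$pixel_size_um,
              channel = if (which == "all") "GFP-structure" else "OCTA-flow")
}

#' Add post-raster imaging noise to an en-face map
#'
#' Optional Gaussian blur followed by additive Gaussian background noise,
#' clipped at zero. Both default off in the generator itself; study configs
#' switch them on to emulate detector noise and the finite PSF.
#'
#' @param map an [en_face_map()] or matrix.
#' @param blur_sigma_px Gaussian blur sigma (0 = none).
#' @param noise_sd additive Gaussian noise sd (0 = none).
#' @param seed integer seed for the noise draw.
#' @export
add_map_noise <- function(map, blur_sigma_px = 0, noise_sd = 0, seed = 1L) {
  px <- as_pixels(map)
  if (blur_sigma_px > 0) {
    px <- as.matrix(EBImage::gblur(px, sigma = blur_sigma_px))
  }
  if (noise_sd > 0) {
    old <- .Random.seed_store(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    px <- px + matrix(rnorm(length(px), 0, noise_sd), nrow(px))
  }
  px <- pmax(px, 0)
  if (inherits(map, "en_face_map")) {
    en_face_map(px, map$pixel_size_um, map$channel, map$roi)
  } else px
}
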