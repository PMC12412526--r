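# File I/O and the package-wide coordinate conventions.
#
# Conventions (used by every module):
#   * images are numeric matrices indexed [row, col], 1-based;
#   * rows run dorsal -> ventral (top -> bottom of the en-face map), columns
#     run rostral -> caudal; chain coordinates use x = column, y = row and
#     may be sub-pixel;
#   * an ROI is c(r0, r1, c0, c1), 1-based and INCLUSIVE on both ends;
#   * complex OCT volumes are arrays data[slow y, repeat r, depth z, fast x].

#' Write / read an en-face map as 16-bit grayscale TIFF
#'
#' Pixel values are rescaled to `[0, 1]` on write (the scale factor is the
#' caller's concern; a JSON sidecar can carry provenance).
#'
#' @param map an [en_face_map()] or numeric matrix.
#' @param path output path (`.tiff`).
#' @export
write_enface_tiff <- function(map, path) {
  px <- as_pixels(map)
  tiff::writeTIFF(normalize01(px), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_enface_tiff
#' @param pixel_size_um,channel metadata for the returned [en_face_map()].
#' @export
read_enface_tiff <- function(path, pixel_size_um = 1.4,
                             channel = "OCTA-flow") {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  en_face_map(px, pixel_size_um = pixel_size_um, channel = channel)
}

#' Write / read a complex OCT volume container
#'
#' On-disk container for [build_volume()] results: a single serialized file
#' holding the complex data cube `data[y, r, z, x]` and its acquisition
#' metadata (interscan time, wavelength, refractive index, pixel pitches).
#' The round trip is bit-exact.
#'
#' @param volume an `oct_volume`.
#' @param path output path (conventionally `.octvol`).
#' @export
write_oct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  saveRDS(volume, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_oct_volume
#' @export
read_oct_volume <- function(path) {
  v <- readRDS(path)
  if (!inherits(v, "oct_volume")) abort("not an oct_volume container")
  v
}

#' Write a JSON sidecar / report
#'
#' @param x a list (or tibble) of provenance or results.
#' @param path output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a generated network's ground truth to JSON
#'
#' Centerlines (rounded to 1e-3 px), junctions, per-vessel analytic lengths
#' and the generator parameters, as a plain-text record alongside the raster
#' outputs.
#'
#' @param network a [generate_network()] result.
#' @param path output path (`.json`).
#' @export
write_truth_json <- function(network, path) {
  v <- network$vessels
  out <- list(
    image_shape = as.integer(network$image_shape),
    params = network$params[setdiff(names(network$params), "image_shape")],
    vessels = lapply(seq_len(nrow(v)), function(i) list(
      id = v$id[i], kind = v$kind[i], perfused = v$perfused[i],
      radius_px = v$radius_px[i],
      arc_length = v$arc_length[i], chord_length = v$chord_length[i],
      x = round(chain_matrix(v$points[[i]])[, 1], 3),
      y = round(chain_matrix(v$points[[i]])[, 2], 3)
    )),
    junctions = list(x = network$junctions$x, y = network$junctions$y)
  )
  write_json_report(out, path)
}
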