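#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number
#' @importFrom purrr map map_dbl map_lgl map2 pmap imap
#' @importFrom stats rnorm runif rbinom sd var t.test shapiro.test spline
#'   quantile fft optim coef nls median
NULL

# Wrap an angle (radians) to the principal interval (-pi, pi].
wrap_phase <- function(x) {
  out <- x - 2 * pi * floor(x / (2 * pi) + 0.5)
  # floor(.+0.5) rounds half up, which maps +pi -> +pi and -pi -> +pi
  out[out <= -pi] <- out[out <= -pi] + 2 * pi
  out
}

# Clamp values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Rescale a matrix to [0, 1]; constant input maps to 0.
normalize01 <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(x * 0)
  (x - rng[1]) / diff(rng)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Inclusive 1-based ROI c(r0, r1, c0, c1); NULL means the full image.
# See R/io.R for the coordinate conventions used throughout the package.
check_roi <- function(roi, dim_img) {
  if (is.null(roi)) roi <- c(1L, dim_img[1], 1L, dim_img[2])
  roi <- as.integer(round(roi))
  if (length(roi) != 4L || roi[1] < 1L || roi[3] < 1L ||
      roi[2] > dim_img[1] || roi[4] > dim_img[2] ||
      roi[1] > roi[2] || roi[3] > roi[4]) {
    abort("`roi` must be c(r0, r1, c0, c1), 1-based inclusive, inside the image")
  }
  roi
}

roi_area <- function(roi) (roi[2] - roi[1] + 1) * (roi[4] - roi[3] + 1)

crop_roi <- function(mat, roi) mat[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]

# Derive a child RNG seed from a master seed and a counter, staying < 2^31.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 7919 + as.numeric(counter) * 104729) %% 2147483629)
}
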