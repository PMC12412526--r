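# OCTA-fluorescence fusion: similarity-transform co-registration, red-green
# merge, and structural similarity (SSIM) scoring.

# Bilinear sampling of img at (continuous) row/col positions; NA outside.
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  out <- rep(NA_real_, length(rows))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i11] * fr[ok] * fc[ok]
  }
  out
}

# Resample `moving` on the fixed grid under a similarity transform
# (rotation theta_deg about the image center, isotropic scale, then
# translation by (dr, dc) rows/cols). Returns matrix with NA outside.
apply_similarity <- function(moving, dr = 0, dc = 0, theta_deg = 0, scale = 1,
                             out_dim = dim(moving)) {
  th <- theta_deg * pi / 180
  ctr_out <- (out_dim + 1) / 2
  ctr_in <- (dim(moving) + 1) / 2
  rr <- rep(seq_len(out_dim[1]), times = out_dim[2]) - ctr_out[1] - dr
  cc <- rep(seq_len(out_dim[2]), each = out_dim[1]) - ctr_out[2] - dc
  # inverse rotation/scale back into moving-image coordinates
  r_in <- (cos(th) * rr - sin(th) * cc) / scale + ctr_in[1]
  c_in <- (sin(th) * rr + cos(th) * cc) / scale + ctr_in[2]
  matrix(bilinear_sample(moving, r_in, c_in), out_dim[1], out_dim[2])
}

ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 16) return(-1)
  a <- a[ok]; b <- b[ok]
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

# Integer-shift cross-correlation peak via FFT (zero-padded, mean-removed).
fft_shift_peak <- function(fixed, moving, max_shift) {
  nr <- nrow(fixed) + nrow(moving)
  nc <- ncol(fixed) + ncol(moving)
  pad <- function(m) {
    out <- matrix(0, nr, nc)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m - mean(m)
    out
  }
  xc <- Re(fft(fft(pad(fixed)) * Conj(fft(pad(moving))), inverse = TRUE))
  sr <- c(0:(nr - 1)); sr[sr > nr / 2] <- sr[sr > nr / 2] - nr
  sc <- c(0:(nc - 1)); sc[sc > nc / 2] <- sc[sc > nc / 2] - nc
  keep_r <- abs(sr) <= max_shift; keep_c <- abs(sc) <= max_shift
  sub <- xc[keep_r, keep_c, drop = FALSE]
  idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  c(dr = sr[keep_r][idx[1]], dc = sc[keep_c][idx[2]])
}

#' Co-register two en-face maps by a similarity transform
#'
#' Finds the translation, rotation and isotropic scale that maximize the
#' normalized cross-correlation between the moving map resampled on the
#' fixed grid and the fixed map. Search is coarse-to-fine: per candidate
#' rotation/scale, the best integer translation comes from an FFT
#' cross-correlation, then a Nelder-Mead refinement polishes all parameters.
#' Ties break toward the smaller transform. If even the best correlation is
#' below `floor`, a warning is raised and the identity transform returned.
#'
#' @param moving,fixed [en_face_map()]s or matrices with overlapping fields
#'   of view.
#' @param rotations candidate rotations (degrees) for the coarse search.
#' @param scales candidate isotropic scales.
#' @param max_shift_px translation search radius.
#' @param floor correlation below which registration is abandoned.
#' @return list of class `coregistration`: `transform` (dr, dc, theta_deg,
#'   scale), `correlation`, and `resampled` (the moving map on the fixed
#'   grid, NA-free: unseen pixels set to 0).
#' @export
coregister <- function(moving, fixed, rotations = seq(-6, 6, by = 1),
                       scales = 1, max_shift_px = 20, floor = 0.1) {
  mv <- as_pixels(moving); fx <- as_pixels(fixed)
  best <- list(par = c(0, 0, 0, 1), corr = -Inf)
  for (sc in scales) for (th in rotations) {
    rot <- apply_similarity(mv, 0, 0, th, sc, out_dim = dim(fx))
    rot[!is.finite(rot)] <- 0
    sh <- fft_shift_peak(fx, rot, max_shift_px)
    cand <- apply_similarity(mv, sh[1], sh[2], th, sc, out_dim = dim(fx))
    cc <- ncc(cand, fx)
    better <- cc > best$corr + 1e-9 ||
      (abs(cc - best$corr) <= 1e-9 &&
         sum(c(sh, th, 0)^2) < sum(c(best$par[1:3], 0)^2))
    if (better) best <- list(par = c(sh[1], sh[2], th, sc), corr = cc)
  }
  # local refinement (subpixel translation + rotation; scale refined only
  # when a scale range was searched)
  refine_scale <- length(scales) > 1
  obj <- function(p) {
    sc <- if (refine_scale) p[4] else best$par[4]
    -ncc(apply_similarity(mv, p[1], p[2], p[3], sc, out_dim = dim(fx)), fx)
  }
  p0 <- if (refine_scale) best$par else best$par[1:3]
  opt <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-7))
  par <- if (refine_scale) opt$par else c(opt$par, best$par[4])
  corr <- -opt$value
  if (corr < best$corr) { par <- best$par; corr <- best$corr }
  if (corr < floor) {
    warn(sprintf("registration correlation %.3f below floor %.3f; %s",
                 corr, floor, "returning identity transform"))
    par <- c(0, 0, 0, 1)
    corr <- ncc(apply_similarity(mv, out_dim = dim(fx)), fx)
  }
  res <- apply_similarity(mv, par[1], par[2], par[3], par[4],
                          out_dim = dim(fx))
  res[!is.finite(res)] <- 0
  structure(
    list(transform = c(dr = par[1], dc = par[2], theta_deg = par[3],
                       scale = par[4]),
         correlation = corr, resampled = res),
    class = "coregistration"
  )
}

#' @export
print.coregistration <- function(x, ...) {
  cat(sprintf(
    "<coregistration> shift (%.2f, %.2f) px, rotation %.2f deg, %s%.3f\n",
    x$transform[1], x$transform[2], x$transform[3],
    sprintf("scale %.3f, correlation ", x$transform[4]), x$correlation))
  invisible(x)
}

#' Merge OCTA and GFP maps into a red-green image
#'
#' Red = normalized OCTA flow contrast, green = normalized GFP structure,
#' blue = 0; perfused vessels visible in both channels appear yellow,
#' non-perfused (structure-only) vessels green, flow-only signal red.
#'
#' @param octa,gfp co-registered same-shape maps or matrices.
#' @return numeric array `[rows, cols, 3]` in `[0, 1]`.
#' @export
merge_red_green <- function(octa, gfp) {
  r <- as_pixels(octa); g <- as_pixels(gfp)
  if (!identical(dim(r), dim(g))) abort("maps must have identical shape")
  out <- array(0, dim = c(dim(r), 3))
  out[, , 1] <- normalize01(r)
  out[, , 2] <- normalize01(g)
  out
}

gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable "same" convolution with mirror padding.
conv_sep <- function(img, k) {
  half <- (length(k) - 1) %/% 2
  reflect_idx <- function(n) c(rev(seq_len(half) + 1L), seq_len(n),
                               n - seq_len(half))
  p <- img[reflect_idx(nrow(img)), , drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) {
    out <- out + k[i] * p[i:(i + nrow(img) - 1L), , drop = FALSE]
  }
  p <- out[, reflect_idx(ncol(img)), drop = FALSE]
  out2 <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) {
    out2 <- out2 + k[i] * p[, i:(i + ncol(img) - 1L), drop = FALSE]
  }
  out2
}

#' Structural similarity index between two en-face maps
#'
#' Standard SSIM with a Gaussian weighting window: local luminance, contrast
#' and structure comparisons combined per pixel, the global score being the
#' mean of the local map over the ROI. 1 means structurally identical, 0 no
#' similarity, -1 perfect anti-correlation.
#'
#' @param a,b same-shape [en_face_map()]s or matrices.
#' @param window_size Gaussian window support (default 11 x 11).
#' @param sigma Gaussian window sigma (default 1.5).
#' @param k1,k2 stabilization constants (defaults 0.01, 0.03).
#' @param dynamic_range value range `L`; default the joint data range (1 is
#'   substituted for constant inputs).
#' @param roi ROI over which the global score is averaged (default full).
#' @return object of class `ssim_result`: `global`, `local` (matrix),
#'   window settings and ROI.
#' @export
ssim <- function(a, b, window_size = 11L, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03, dynamic_range = NULL, roi = NULL) {
  am <- as_pixels(a); bm <- as_pixels(b)
  if (!identical(dim(am), dim(bm))) abort("maps must have identical shape")
  roi <- check_roi(roi, dim(am))
  if (window_size > min(roi[2] - roi[1], roi[4] - roi[3]) + 1) {
    abort("SSIM window larger than the ROI")
  }
  L <- dynamic_range %||% {
    rng <- range(c(am, bm)); if (diff(rng) > 0) diff(rng) else 1
  }
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  k <- gaussian_kernel_1d(window_size, sigma)
  mu_a <- conv_sep(am, k); mu_b <- conv_sep(bm, k)
  var_a <- conv_sep(am * am, k) - mu_a^2
  var_b <- conv_sep(bm * bm, k) - mu_b^2
  cov_ab <- conv_sep(am * bm, k) - mu_a * mu_b
  local <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  structure(
    list(global = mean(crop_roi(local, roi)), local = local,
         window_size = window_size, sigma = sigma, k1 = k1, k2 = k2,
         dynamic_range = L, roi = roi),
    class = "ssim_result"
  )
}

#' @export
print.ssim_result <- function(x, ...) {
  cat(sprintf("<ssim_result> global = %.4f (window %d, sigma %.2f)\n",
              x$global, x$window_size, x$sigma))
  invisible(x)
}

#' @export
tidy.ssim_result <- function(x, ...) {
  tibble(global = x$global, window_size = x$window_size, sigma = x$sigma,
         k1 = x$k1, k2 = x$k2, dynamic_range = x$dynamic_range)
}

#' @export
glance.ssim_result <- function(x, ...) tidy(x, ...)
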