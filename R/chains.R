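# Polyline ("chain") geometry shared by the synthetic generator, the analytic
# ground-truth metrics and the skeleton-based metrics. A chain is a tibble (or
# matrix) with columns x (image column) and y (image row), ordered along the
# vessel, in pixel units with sub-pixel precision allowed.

chain_matrix <- function(pts) {
  if (is.matrix(pts)) return(pts)
  cbind(x = pts$x, y = pts$y)
}

# Total polyline length.
chain_length <- function(pts) {
  m <- chain_matrix(pts)
  if (nrow(m) < 2) return(0)
  sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2))
}

# Cumulative arc length from the first vertex (length nrow).
chain_cumlen <- function(m) {
  c(0, cumsum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)))
}

# Resample a chain at equal arc-length steps (keeps both endpoints).
resample_chain <- function(pts, step = 1) {
  m <- chain_matrix(pts)
  s <- chain_cumlen(m)
  L <- s[length(s)]
  if (L == 0) return(m[1, , drop = FALSE])
  t_out <- unique(c(seq(0, L, by = step), L))
  keep <- !duplicated(s)
  cbind(
    x = stats::approx(s[keep], m[keep, 1], xout = t_out)$y,
    y = stats::approx(s[keep], m[keep, 2], xout = t_out)$y
  )
}

# Moving-average smoothing of vertex coordinates, endpoints pinned. Removes
# the digitization bias of 8-connected pixel chains, whose raw staircase
# otherwise inflates path length of oblique straight runs by up to ~8%.
smooth_chain <- function(pts, window = 5L) {
  m <- chain_matrix(pts)
  n <- nrow(m)
  if (n <= 2 || window <= 1) return(m)
  half <- window %/% 2
  sm <- m
  for (j in 1:2) {
    cs <- cumsum(c(0, m[, j]))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    sm[, j] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  sm[1, ] <- m[1, ]
  sm[n, ] <- m[n, ]
  sm
}

# Point on a chain at arc-length position s0 (linear interpolation).
chain_point_at <- function(m, s, s0) {
  if (s0 <= 0) return(m[1, ])
  L <- s[length(s)]
  if (s0 >= L) return(m[nrow(m), ])
  i <- findInterval(s0, s)
  f <- (s0 - s[i]) / (s[i + 1] - s[i])
  m[i, ] + f * (m[i + 1, ] - m[i, ])
}

#' Windowed arc-to-chord ratios along a chain
#'
#' Slides a window of fixed path length along a polyline and returns, for each
#' window, the ratio of path length to the Euclidean distance between the
#' window endpoints. This is the elementary tortuosity measurement; chains
#' shorter than the window contribute a single whole-chain ratio.
#'
#' @param pts chain (tibble or matrix with columns x, y).
#' @param window_px window path length in pixels (default 20).
#' @param step_px stride between window starts in pixels (default 1,
#'   i.e. maximally overlapping windows).
#' @return numeric vector of arc/chord ratios (possibly length 0 when the
#'   chain is degenerate, e.g. a closed loop shorter than the window).
#' @keywords internal
windowed_arc_chord <- function(pts, window_px = 20, step_px = 1) {
  m <- chain_matrix(pts)
  if (nrow(m) < 2) return(numeric(0))
  s <- chain_cumlen(m)
  L <- s[length(s)]
  if (L < window_px) {
    chord <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
    if (chord < .Machine$double.eps^0.5) return(numeric(0))
    return(L / chord)
  }
  starts <- seq(0, L - window_px, by = step_px)
  vapply(starts, function(t0) {
    p0 <- chain_point_at(m, s, t0)
    p1 <- chain_point_at(m, s, t0 + window_px)
    chord <- sqrt(sum((p1 - p0)^2))
    if (chord < .Machine$double.eps^0.5) return(NA_real_)
    window_px / chord
  }, numeric(1)) |> (\(r) r[is.finite(r)])()
}

# Tangent angles (degrees, folded to [-90, 90)) along a chain, central
# difference over +/- `spacing` vertices of the 1-px-resampled chain. The
# default +/- 4 px baseline keeps the angular quantization of digitized
# chains below the 1-degree histogram bin.
chain_tangent_angles <- function(pts, spacing = 4L) {
  m <- resample_chain(pts, step = 1)
  n <- nrow(m)
  if (n < 2) return(numeric(0))
  i0 <- pmax(seq_len(n) - spacing, 1L)
  i1 <- pmin(seq_len(n) + spacing, n)
  ang <- atan2(m[i1, 2] - m[i0, 2], m[i1, 1] - m[i0, 1]) * 180 / pi
  ((ang + 90) %% 180) - 90
}

# Fit a Gaussian to the 1-degree histogram of folded angles, around the
# dominant mode, within +/- halfwidth degrees. Returns the fitted sigma.
# Degenerate (near-delta) histograms fall back to the moment estimate, which
# is what a vanishing-width Gaussian converges to anyway.
fit_angle_sigma <- function(angles_deg, bin_deg = 1, halfwidth = 45) {
  angles_deg <- angles_deg[is.finite(angles_deg)]
  if (length(angles_deg) < 50) {
    abort("need at least 50 vessel positions to fit an orientation histogram")
  }
  breaks <- seq(-90, 90, by = bin_deg)
  h <- graphics::hist(angles_deg, breaks = breaks, plot = FALSE)
  sm3 <- function(x) stats::filter(x, rep(1 / 3, 3), circular = TRUE) |>
    as.numeric()
  mode_deg <- h$mids[which.max(sm3(h$counts))]
  # recentre so the dominant mode sits at 0 and the fold seam is far away
  d <- ((angles_deg - mode_deg + 90) %% 180) - 90
  d <- d[abs(d) <= halfwidth]
  hd <- graphics::hist(d, breaks = seq(-halfwidth, halfwidth, by = bin_deg),
                       plot = FALSE)
  mid <- hd$mids
  # degeneracy check on the raw histogram: a (near-)delta spike means the
  # chains are essentially parallel and the spread is below the bin width
  w_raw <- hd$counts / sum(hd$counts)
  mu_raw <- sum(w_raw * mid)
  sig_raw <- sqrt(max(sum(w_raw * (mid - mu_raw)^2), 1e-6))
  if (sum(hd$counts > 0) < 3 || sig_raw < 0.75 * bin_deg) {
    return(max(sd(d), 0.25 * bin_deg))
  }
  cnt <- sm3(hd$counts)  # light smoothing suppresses quantization spikes
  w <- cnt / sum(cnt)
  mu0 <- sum(w * mid)
  sig0 <- sqrt(max(sum(w * (mid - mu0)^2), 1e-4))
  # trimmed initialization: moments within +/- 2 sig0 of the mode resist
  # heavy shoulders from secondary vessel populations
  core <- abs(mid - mu0) <= 2 * sig0
  w2 <- cnt[core] / sum(cnt[core])
  mu1 <- sum(w2 * mid[core])
  sig1 <- sqrt(max(sum(w2 * (mid[core] - mu1)^2), 0.25 * bin_deg^2))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      cnt ~ A * exp(-(mid - mu)^2 / (2 * sig^2)),
      start = list(A = max(cnt), mu = mu1, sig = sig1),
      lower = c(A = 0, mu = -halfwidth, sig = 0.5 * bin_deg),
      upper = c(A = Inf, mu = halfwidth, sig = halfwidth),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("orientation Gaussian fit did not converge; using moment estimate")
    return(sig1)
  }
  abs(coef(fit)[["sig"]])
}
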