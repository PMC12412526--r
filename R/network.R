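# Synthetic vascular network generation (the "synthvasc" stage).

# Smooth low-frequency bend of an axial vessel: tangent angles are sampled at
# coarse control points, spline-interpolated to a dense grid, and rescaled so
# that the realized tangent-angle standard deviation equals sigma_deg exactly.
# Integrating tan(theta) yields the centerline; recentering keeps the mean row.
make_axis_chain <- function(y0, x_min, x_max, sigma_deg, step = 0.5,
                            ctrl_spacing = 60) {
  xs <- seq(x_min, x_max, by = step)
  if (sigma_deg <= 0) {
    return(tibble(x = xs, y = rep(y0, length(xs))))
  }
  xc <- seq(x_min - ctrl_spacing, x_max + ctrl_spacing, by = ctrl_spacing)
  theta_c <- rnorm(length(xc), 0, sigma_deg)
  theta <- spline(xc, theta_c, xout = xs)$y
  theta <- theta - mean(theta)
  s <- sd(theta)
  if (s > 0) theta <- theta * (sigma_deg / s)
  theta <- clamp(theta, -60, 60)  # keep the centerline a function of x
  dy <- tan(theta * pi / 180) * step
  y <- y0 + cumsum(dy) - mean(cumsum(dy))
  tibble(x = xs, y = y)
}

# y-position of an axis chain at arbitrary x (linear interpolation).
axis_y_at <- function(chain, x) {
  stats::approx(chain$x, chain$y, xout = x, rule = 2)$y
}

# ISV centerline from the ventral axis up to the DLAV at column x0, with a
# sinusoidal transverse wiggle tapered to zero near both junctions so the
# chain endpoints stay exactly on the axial centerlines.
make_isv_chain <- function(x0, y_bottom, y_top, amplitude, period, phase,
                           taper_px = 8, step = 0.25) {
  L <- abs(y_bottom - y_top)
  t <- seq(0, L, by = step)
  if (t[length(t)] != L) t <- c(t, L)
  y <- y_bottom - t  # rows decrease towards dorsal
  taper <- pmin(1, t / taper_px, (L - t) / taper_px)
  taper <- (1 - cos(pi * clamp(taper, 0, 1))) / 2
  x <- x0 + amplitude * sin(2 * pi * t / period + phase) * taper
  tibble(x = x, y = y)
}

# Quadratic Bezier bridge between two points with a perpendicular sag.
make_bridge_chain <- function(p0, p1, sag, n = 200) {
  mid <- (p0 + p1) / 2
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  perp <- c(-d[2], d[1]) / len
  ctrl <- mid + perp * sag
  t <- seq(0, 1, length.out = n)
  x <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * ctrl[1] + t^2 * p1[1]
  y <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * ctrl[2] + t^2 * p1[2]
  tibble(x = x, y = y)
}

#' Generate a synthetic trunk vascular network with exact ground truth
#'
#' Builds the parametric trunk vasculature described by a
#' [phenotype_params()] object: ventral DA/CA axis, dorsal DLAV, `n_isv`
#' evenly spaced ISVs, and optional hyperbranch bridges between adjacent
#' ISVs. All centerlines are dense sub-pixel polylines; per-vessel arc and
#' chord lengths and all junction coordinates are recorded, so downstream
#' metric recovery can be checked against analytic truth.
#'
#' The construction is deterministic for a fixed `rng_seed`. With zero
#' wiggle, zero bend and zero hyperbranches the network is a perfect grid of
#' straight, parallel, evenly spaced ISVs joining two straight axial vessels.
#'
#' @param params a [phenotype_params()] object.
#' @return an object of class `vessel_network`: list with `vessels` (tibble:
#'   id, kind, perfused, arc_length, chord_length, radius_px, velocity_um_s,
#'   points list-column), `junctions` (tibble: x, y, vessel_ids),
#'   `image_shape`, and `params`.
#' @export
generate_network <- function(params) {
  stopifnot(inherits(params, "phenotype_params"))
  p <- params
  n_slots <- (p$n_isv - 1L) * p$hyperbranch_slots
  if (p$n_hyperbranches > n_slots) {
    abort(sprintf(
      "cannot place %d hyperbranches: only %d slots (%d ISV pairs x %d bands)",
      p$n_hyperbranches, n_slots, p$n_isv - 1L, p$hyperbranch_slots))
  }
  withr_seed <- p$rng_seed
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  radius_offset <- if (p$radius_jitter_px > 0) {
    rnorm(1, 0, p$radius_jitter_px)
  } else 0

  rows <- p$image_shape[["rows"]]; cols <- p$image_shape[["cols"]]
  y_da <- rows - p$margin_px[1]
  y_dlav <- p$margin_px[1]
  x_min <- 1 + max(2, p$vessel_radius_px[["axis"]])
  x_max <- cols - max(2, p$vessel_radius_px[["axis"]])

  da <- make_axis_chain(y_da, x_min, x_max, p$axis_bend_sigma_deg)
  dlav <- make_axis_chain(y_dlav, x_min, x_max, p$axis_bend_sigma_deg)

  x_isv <- p$margin_px[2] + (seq_len(p$n_isv) - 1) * p$isv_spacing_px
  phases <- runif(p$n_isv, 0, 2 * pi)

  vessels <- list(
    list(kind = "axis_da", points = da),
    list(kind = "axis_dlav", points = dlav)
  )
  junctions <- list()
  isv_chains <- vector("list", p$n_isv)
  for (i in seq_len(p$n_isv)) {
    yb <- axis_y_at(da, x_isv[i])
    yt <- axis_y_at(dlav, x_isv[i])
    ch <- make_isv_chain(x_isv[i], yb, yt, p$wiggle_amplitude_px,
                         p$wiggle_period_px, phases[i])
    isv_chains[[i]] <- ch
    vessels[[length(vessels) + 1L]] <- list(kind = "isv", points = ch)
    junctions[[length(junctions) + 1L]] <-
      list(x = x_isv[i], y = yb, vessel_ids = c(1L, length(vessels)))
    junctions[[length(junctions) + 1L]] <-
      list(x = x_isv[i], y = yt, vessel_ids = c(2L, length(vessels)))
  }

  # hyperbranch slots: (adjacent ISV pair) x (height band)
  if (p$n_hyperbranches > 0) {
    bands <- (seq_len(p$hyperbranch_slots)) / (p$hyperbranch_slots + 1)
    slots <- expand.grid(pair = seq_len(p$n_isv - 1L),
                         band = bands, KEEP.OUT.ATTRS = FALSE)
    pick <- sample(nrow(slots), p$n_hyperbranches)
    for (k in seq_len(p$n_hyperbranches)) {
      pair <- slots$pair[pick[k]]
      f <- slots$band[pick[k]] + runif(1, -0.01, 0.01)
      attach_pt <- function(ch, frac) {
        m <- chain_matrix(ch)
        s <- chain_cumlen(m)
        idx <- which.min(abs(s - frac * s[length(s)]))
        m[idx, ]
      }
      # a bridge leaves the left ISV slightly above where a bridge of the
      # neighboring pair arrives, so junctions on one ISV never collide
      p0 <- attach_pt(isv_chains[[pair]], clamp(f + 0.08, 0.1, 0.9))
      p1 <- attach_pt(isv_chains[[pair + 1L]], clamp(f - 0.08, 0.1, 0.9))
      sag <- sample(c(-1, 1), 1) * runif(1, 2, 5)
      br <- make_bridge_chain(p0, p1, sag)
      vessels[[length(vessels) + 1L]] <- list(kind = "bridge", points = br)
      vid <- length(vessels)
      junctions[[length(junctions) + 1L]] <-
        list(x = p0[[1]], y = p0[[2]], vessel_ids = c(2L + pair, vid))
      junctions[[length(junctions) + 1L]] <-
        list(x = p1[[1]], y = p1[[2]], vessel_ids = c(3L + pair, vid))
    }
  }

  vtab <- tibble(
    id = seq_along(vessels),
    kind = map_chr2(vessels, "kind"),
    points = map(vessels, "points")
  )
  vtab$radius_px <- pmax(unname(p$vessel_radius_px[
    c(axis_da = "axis", axis_dlav = "axis", isv = "isv",
      bridge = "bridge")[vtab$kind]]) + radius_offset, 1)
  vel_key <- c(axis_da = "axis_da", axis_dlav = "axis_dlav",
               isv = "isv", bridge = "bridge")[vtab$kind]
  vtab$velocity_um_s <- unname(p$velocity_um_s[vel_key])
  vtab$perfused <- TRUE
  is_bridge <- vtab$kind == "bridge"
  if (any(is_bridge)) {
    vtab$perfused[is_bridge] <- runif(sum(is_bridge)) < p$perfused_fraction
  }
  vtab$arc_length <- map_dbl(vtab$points, chain_length)
  vtab$chord_length <- map_dbl(vtab$points, function(ch) {
    m <- chain_matrix(ch)
    sqrt(sum((m[nrow(m), ] - m[1, ])^2))
  })

  jtab <- tibble(
    x = map_dbl(junctions, "x"),
    y = map_dbl(junctions, "y"),
    vessel_ids = map(junctions, "vessel_ids")
  )

  structure(
    list(vessels = vtab, junctions = jtab,
         image_shape = p$image_shape, params = p),
    class = "vessel_network"
  )
}

map_chr2 <- function(x, f) vapply(x, function(e) e[[f]], character(1))

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("<vessel_network>\n")
  cat(sprintf("  %d vessels (%s), %d junctions, image %d x %d px\n",
              nrow(x$vessels),
              paste(names(table(x$vessels$kind)), table(x$vessels$kind),
                    sep = ":", collapse = " "),
              nrow(x$junctions), x$image_shape[1], x$image_shape[2]))
  cat(sprintf("  total centerline length %.1f px; %d/%d vessels perfused\n",
              sum(x$vessels$arc_length), sum(x$vessels$perfused),
              nrow(x$vessels)))
  invisible(x)
}

#' Tidy a vessel network into one row per vessel
#'
#' @param x a `vessel_network`.
#' @param ... unused.
#' @export
tidy.vessel_network <- function(x, ...) {
  dplyr::select(x$vessels, -"points") |>
    mutate(arc_chord_ratio = .data$arc_length / .data$chord_length)
}
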