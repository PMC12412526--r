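# Binary-mask skeletonization (Zhang-Suen thinning) and conversion of the
# 1-px skeleton into a node/edge graph with pixel chains.

map_int2 <- function(x, f) vapply(x, f, integer(1))

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighborhood stack in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
neighbor_stack <- function(m) {
  list(
    p2 = shift_mat(m, 1, 0),  p3 = shift_mat(m, 1, -1),
    p4 = shift_mat(m, 0, -1), p5 = shift_mat(m, -1, -1),
    p6 = shift_mat(m, -1, 0), p7 = shift_mat(m, -1, 1),
    p8 = shift_mat(m, 0, 1),  p9 = shift_mat(m, 1, 1)
  )
  # pK = TRUE where the neighbor in direction K of the pixel is set:
  # shifting by (dr,dc) moves neighbor values onto the center pixel.
}

#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels while preserving connectivity until a
#' 1-px-wide skeleton remains.
#'
#' @param mask logical matrix (TRUE = vessel).
#' @return logical matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask > 0
  if (!any(m)) abort("cannot skeletonize an empty mask")
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- neighbor_stack(m)
      b <- Reduce(`+`, nb)
      seq9 <- nb[c(1:8, 1)]
      a <- 0
      for (i in 1:8) a <- a + (!seq9[[i]] & seq9[[i + 1]])
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (sub == 1) {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Degree (number of set 8-neighbors) of every skeleton pixel.
skeleton_degree <- function(m) {
  nb <- neighbor_stack(m)
  d <- Reduce(`+`, nb)
  d[!m] <- 0L
  d
}

# Lookup table over the 256 possible 8-neighborhood configurations: number
# of 8-connected components formed by the set neighbor cells (adjacency of
# the cells themselves, not just ring runs). Bit k of the code corresponds
# to ring position k in (N, NE, E, SE, S, SW, W, NW) order.
neighbor_component_lut <- local({
  lut <- NULL
  function() {
    if (!is.null(lut)) return(lut)
    pos <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
    out <- integer(256)
    for (code in 0:255) {
      on <- which(bitwAnd(code, bitwShiftL(1L, 0:7)) > 0)
      if (length(on) == 0) { out[code + 1] <- 0L; next }
      parent <- seq_along(on)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in seq_along(on)) for (j in seq_along(on)) {
        if (i < j && max(abs(pos[on[i], ] - pos[on[j], ])) <= 1) {
          parent[find(j)] <- find(i)
        }
      }
      out[code + 1] <- length(unique(vapply(seq_along(on), find, integer(1))))
    }
    lut <<- out
    lut
  }
})

neighborhood_code <- function(m) {
  nb <- neighbor_stack(m)
  # nb order p2..p9 = N, NE, E, SE, S, SW, W, NW = bits 0..7
  code <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:8) code <- code + bitwShiftL(1L, k - 1L) * nb[[k]]
  code
}

# Remove redundant pixels: non-endpoint skeleton pixels whose set neighbors
# form a single 8-connected component (removal cannot disconnect anything).
# Thinning leaves such pixels on oblique runs, where they masquerade as
# spurious branch pixels. Four-phase sweep so pixels removed within a pass
# are never 8-adjacent to each other.
remove_staircase <- function(m) {
  lut <- neighbor_component_lut()
  repeat {
    changed <- FALSE
    for (pr in 0:1) for (pc in 0:1) {
      b <- skeleton_degree(m)
      ncomp <- matrix(lut[neighborhood_code(m) + 1L], nrow(m))
      cond <- m & b >= 2L & ncomp == 1L
      cond[row(m) %% 2L != pr | col(m) %% 2L != pc] <- FALSE
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Single-linkage clustering of points within `radius` (Chebyshev distance),
# used to merge blobs of adjacent junction pixels into one node.
cluster_points <- function(pts, radius = 2) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  id <- seq_len(n)
  find <- function(i) { while (id[i] != i) { id[i] <<- id[id[i]]; i <- id[i] }; i }
  for (i in seq_len(n - 1)) {
    close_j <- which(
      abs(pts[(i + 1):n, 1] - pts[i, 1]) <= radius &
        abs(pts[(i + 1):n, 2] - pts[i, 2]) <= radius) + i
    for (j in close_j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) id[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Path length of an 8-connected pixel chain (unit + sqrt(2) diagonal steps).
chain_steps_length <- function(m) {
  if (nrow(m) < 2) return(0)
  dx <- abs(diff(m[, 1])); dy <- abs(diff(m[, 2]))
  sum(ifelse(dx + dy == 2, sqrt(2), 1) * (dx + dy > 0))
}

#' Extract a vessel graph from a skeleton
#'
#' Classifies skeleton pixels into endpoints (1 neighbor), junction pixels
#' (>= 3 neighbors) and chain pixels, traces the pixel chains between them,
#' merges junction pixels within `merge_radius_px` into single nodes, and
#' prunes spur branches shorter than `prune_px`. Chain path lengths count
#' diagonal steps as sqrt(2); for metric purposes chains are also stored
#' smoothed (see `smooth_window`), which removes the staircase bias of
#' digitized oblique lines.
#'
#' @param mask logical matrix (a binary vessel mask) or an already
#'   skeletonized 1-px mask.
#' @param pixel_size_um pixel pitch for µm lengths.
#' @param merge_radius_px junction pixels this close merge into one node.
#' @param prune_px spur branches (endpoint-to-junction) shorter than this
#'   are removed.
#' @param smooth_window moving-average window for the stored smoothed chains.
#' @param pre_skeletonized set TRUE if `mask` is already 1 px wide.
#' @return object of class `vessel_skeleton`: `nodes` (tibble: id, x, y,
#'   degree, kind), `edges` (tibble: id, from, to, n_px, length_px,
#'   length_um, points list-column of smoothed chains), `total_length_px`,
#'   and the skeleton mask.
#' @export
skeleton_graph <- function(mask, pixel_size_um = 1.4, merge_radius_px = 2,
                           prune_px = 3, smooth_window = 5L,
                           pre_skeletonized = FALSE) {
  skel <- if (pre_skeletonized) mask > 0 else skeletonize_mask(mask)
  skel <- remove_staircase(skel)
  deg <- skeleton_degree(skel)
  # after staircase removal, >= 3 neighbors marks branch pixels (possibly
  # several per branching, e.g. pixel triangles); cluster merging below
  # fuses each blob into one junction node
  node_px <- skel & (deg == 1L | deg >= 3L)
  # isolated pixels carry no length; drop them
  skel[deg == 0L & skel] <- FALSE
  node_px[deg == 0L] <- FALSE

  idx <- which(skel, arr.ind = TRUE)  # row, col
  if (nrow(idx) == 0) abort("empty skeleton")
  nr <- nrow(skel); nc <- ncol(skel)
  lin <- function(r, c) (c - 1L) * nr + r
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  nbrs_of <- function(r, c) {
    rr <- r + offs[, 1]; cc <- c + offs[, 2]
    ok <- rr >= 1L & cc >= 1L & rr <= nr & cc <= nc
    ok[ok] <- skel[cbind(rr[ok], cc[ok])]
    cbind(rr, cc)[ok, , drop = FALSE]
  }

  node_idx <- which(node_px, arr.ind = TRUE)
  # half-edge visit marks, indexed (linear pixel, direction 1..8)
  dir_code <- function(dr, dc) match(paste(dr, dc),
                                     paste(offs[, 1], offs[, 2]))
  visited <- matrix(FALSE, nr * nc, 8L)
  touched <- matrix(FALSE, nr, nc)
  edges <- vector("list", 256L); n_edges <- 0L
  add_edge <- function(chain_rc) {
    n_edges <<- n_edges + 1L
    if (n_edges > length(edges)) length(edges) <<- 2L * n_edges
    edges[[n_edges]] <<- chain_rc
  }
  max_steps <- nrow(idx) + 5L

  # trace from every node pixel along every incident direction
  for (i in seq_len(nrow(node_idx))) {
    r0 <- node_idx[i, 1]; c0 <- node_idx[i, 2]
    nbs <- nbrs_of(r0, c0)
    if (nrow(nbs) == 0) next
    for (k in seq_len(nrow(nbs))) {
      d0 <- dir_code(nbs[k, 1] - r0, nbs[k, 2] - c0)
      if (visited[lin(r0, c0), d0]) next
      visited[lin(r0, c0), d0] <- TRUE
      cr <- integer(max_steps); cc_ <- integer(max_steps)
      cr[1] <- r0; cc_[1] <- c0; cr[2] <- nbs[k, 1]; cc_[2] <- nbs[k, 2]
      len <- 2L
      prev <- c(r0, c0); cur <- nbs[k, ]
      while (!node_px[cur[1], cur[2]] && len < max_steps) {
        nxt <- nbrs_of(cur[1], cur[2])
        nxt <- nxt[!(nxt[, 1] == prev[1] & nxt[, 2] == prev[2]), ,
                   drop = FALSE]
        if (nrow(nxt) == 0) break  # dead end without endpoint flag (rare)
        pick <- 1L
        if (nrow(nxt) > 1) {
          # never cut a corner past a junction: prefer node pixels, then
          # 4-adjacent continuations, then any pixel not adjacent to prev
          is_nd <- node_px[nxt]
          ortho <- (abs(nxt[, 1] - cur[1]) + abs(nxt[, 2] - cur[2])) == 1
          far <- pmax(abs(nxt[, 1] - prev[1]), abs(nxt[, 2] - prev[2])) > 1
          pick <- if (any(is_nd)) which(is_nd)[1]
          else if (any(ortho & far)) which(ortho & far)[1]
          else if (any(far)) which(far)[1]
          else 1L
        }
        prev <- cur; cur <- nxt[pick, ]
        len <- len + 1L
        cr[len] <- cur[1]; cc_[len] <- cur[2]
      }
      visited[lin(cur[1], cur[2]),
              dir_code(prev[1] - cur[1], prev[2] - cur[2])] <- TRUE
      chain <- cbind(cr[seq_len(len)], cc_[seq_len(len)])
      touched[chain] <- TRUE
      add_edge(chain)
    }
  }

  # closed loops with no node pixel at all: walk any untouched chain pixel
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    if (node_px[r, c] || touched[r, c]) next
    nbs <- nbrs_of(r, c)
    if (nrow(nbs) < 2) next
    cr <- integer(max_steps); cc_ <- integer(max_steps)
    cr[1] <- r; cc_[1] <- c; len <- 1L
    prev <- c(r, c); cur <- nbs[1, ]
    while (!(cur[1] == r && cur[2] == c) && len < max_steps) {
      len <- len + 1L
      cr[len] <- cur[1]; cc_[len] <- cur[2]
      touched[cur[1], cur[2]] <- TRUE
      nxt <- nbrs_of(cur[1], cur[2])
      nxt <- nxt[!(nxt[, 1] == prev[1] & nxt[, 2] == prev[2]), , drop = FALSE]
      if (nrow(nxt) == 0) break
      prev <- cur; cur <- nxt[1, ]
    }
    len <- len + 1L
    cr[len] <- r; cc_[len] <- c
    touched[r, c] <- TRUE
    add_edge(cbind(cr[seq_len(len)], cc_[seq_len(len)]))
  }
  edges <- edges[seq_len(n_edges)]

  # ---- nodes: endpoints stay single; junction pixels cluster-merge
  ends <- node_idx[deg[node_idx] == 1L, , drop = FALSE]
  juncs <- node_idx[deg[node_idx] >= 3L, , drop = FALSE]
  jclust <- cluster_points(juncs, merge_radius_px)
  n_jnodes <- if (length(jclust)) max(jclust) else 0L
  nodes <- tibble(
    id = seq_len(nrow(ends) + n_jnodes),
    y = c(ends[, 1],
          if (n_jnodes) as.numeric(tapply(juncs[, 1], jclust, mean))),
    x = c(ends[, 2],
          if (n_jnodes) as.numeric(tapply(juncs[, 2], jclust, mean))),
    kind = c(rep("endpoint", nrow(ends)), rep("junction", n_jnodes))
  )
  node_of_px <- matrix(NA_integer_, nr, nc)
  if (nrow(ends)) node_of_px[ends] <- seq_len(nrow(ends))
  if (nrow(juncs)) node_of_px[juncs] <- nrow(ends) + jclust

  etab <- tibble(
    from = map_int2(edges, function(ch) node_of_px[ch[1, 1], ch[1, 2]]),
    to = map_int2(edges, function(ch) node_of_px[ch[nrow(ch), 1],
                                                 ch[nrow(ch), 2]]),
    n_px = map_int2(edges, nrow),
    points = lapply(edges, function(ch) cbind(x = ch[, 2], y = ch[, 1]))
  )
  if (nrow(etab) == 0) abort("skeleton produced no edges")
  # drop intra-cluster stubs (both ends in the same junction node)
  same_junc <- !is.na(etab$from) & etab$from == etab$to &
    etab$from > nrow(ends) & etab$n_px <= 2 * merge_radius_px + 1
  etab <- etab[!same_junc, , drop = FALSE]
  etab$length_px <- map_dbl(etab$points, function(p) {
    chain_length(smooth_chain(p, smooth_window))
  })

  # ---- spur pruning: short endpoint branches
  if (prune_px > 0 && nrow(etab) > 1) {
    repeat {
      deg_node <- table(factor(c(etab$from, etab$to), levels = nodes$id))
      spur <- which(
        etab$length_px < prune_px &
          ((nodes$kind[etab$from] == "endpoint" & deg_node[etab$from] == 1) |
             (nodes$kind[etab$to] == "endpoint" & deg_node[etab$to] == 1)) &
          !(nodes$kind[etab$from] == "endpoint" &
              nodes$kind[etab$to] == "endpoint"))
      if (length(spur) == 0 || nrow(etab) <= 1) break
      etab <- etab[-spur[1], , drop = FALSE]
    }
  }

  deg_node <- as.integer(table(factor(c(etab$from, etab$to),
                                      levels = nodes$id)))
  nodes$degree <- deg_node
  nodes <- nodes[nodes$degree > 0, , drop = FALSE]
  nodes$kind[nodes$degree == 1] <- "endpoint"
  nodes$kind[nodes$degree >= 3] <- "junction"

  etab$id <- seq_len(nrow(etab))
  etab$length_um <- etab$length_px * pixel_size_um
  etab <- etab[, c("id", "from", "to", "n_px", "length_px", "length_um",
                   "points")]
  structure(
    list(nodes = nodes, edges = etab,
         total_length_px = sum(etab$length_px),
         pixel_size_um = pixel_size_um, skeleton = skel,
         settings = list(merge_radius_px = merge_radius_px,
                         prune_px = prune_px,
                         smooth_window = smooth_window)),
    class = "vessel_skeleton"
  )
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  cat(sprintf(
    "<vessel_skeleton> %d edges, %d junctions, %d endpoints, length %.1f px\n",
    nrow(x$edges), sum(x$nodes$kind == "junction"),
    sum(x$nodes$kind == "endpoint"), x$total_length_px))
  invisible(x)
}

#' @export
tidy.vessel_skeleton <- function(x, ...) {
  dplyr::select(x$edges, -"points")
}

#' @export
glance.vessel_skeleton <- function(x, ...) {
  tibble(n_edges = nrow(x$edges),
         n_junctions = sum(x$nodes$kind == "junction"),
         n_endpoints = sum(x$nodes$kind == "endpoint"),
         total_length_px = x$total_length_px)
}
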