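# Polygon utilities for ROI rasterization. Vertices are 0-based pixel
# coordinates of voxel centres; a voxel belongs to a polygon when its centre
# lies inside or on the boundary (even-odd rule with explicit on-segment
# inclusion), so areas are unambiguous under resampling.

EPS_GEOM <- 1e-9

on_segment <- function(px, py, x1, y1, x2, y2) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  abs(cross) < EPS_GEOM &
    px >= pmin(x1, x2) - EPS_GEOM & px <= pmax(x1, x2) + EPS_GEOM &
    py >= pmin(y1, y2) - EPS_GEOM & py <= pmax(y1, y2) + EPS_GEOM
}

# Vectorised even-odd point-in-polygon, boundary inclusive.
# pts: n x 2 matrix; poly: m x 2 matrix (closed implicitly).
points_in_polygon <- function(pts, poly) {
  n <- nrow(pts)
  m <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- logical(n)
  boundary <- logical(n)
  j <- m
  for (i in seq_len(m)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    boundary <- boundary | on_segment(px, py, x1, y1, x2, y2)
    # ray casting toward +x; half-open rule on y avoids double counting
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint - EPS_GEOM))
    }
    j <- i
  }
  inside | boundary
}

segments_properly_intersect <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  ((d1 > EPS_GEOM & d2 < -EPS_GEOM) | (d1 < -EPS_GEOM & d2 > EPS_GEOM)) &&
    ((d3 > EPS_GEOM & d4 < -EPS_GEOM) | (d3 < -EPS_GEOM & d4 > EPS_GEOM))
}

# TRUE when any two non-adjacent edges properly cross (simple-polygon check)
polygon_self_intersects <- function(poly) {
  m <- nrow(poly)
  if (m < 4L) return(FALSE)
  edges <- cbind(seq_len(m), c(seq_len(m)[-1], 1L))
  for (i in seq_len(m - 1L)) {
    for (k in seq((i + 1L), m)) {
      # skip adjacent edges (sharing a vertex)
      share <- length(intersect(edges[i, ], edges[k, ])) > 0L
      if (share) next
      if (segments_properly_intersect(poly[edges[i, 1], ], poly[edges[i, 2], ],
                                      poly[edges[k, 1], ], poly[edges[k, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

# Rasterise one polygon on one slice: logical nx x ny matrix of voxel
# centres inside or on the boundary.
rasterize_polygon <- function(poly, nx, ny) {
  xs <- floor(max(0, min(poly[, 1]))):ceiling(min(nx - 1, max(poly[, 1])))
  ys <- floor(max(0, min(poly[, 2]))):ceiling(min(ny - 1, max(poly[, 2])))
  out <- matrix(FALSE, nx, ny)
  if (length(xs) == 0L || length(ys) == 0L) return(out)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  hit <- points_in_polygon(grid, poly)
  out[grid[hit, , drop = FALSE] + 1L] <- TRUE
  out
}
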