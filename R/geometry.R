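# Planar polygon primitives used by the synthetic tract generator and the
# exposure assignment. Coordinates are metres in a local projection centred
# on the emission source; polygons are rings stored as n x 2 matrices,
# implicitly closed (last vertex joins the first).

#' @noRd
polygon_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' @noRd
polygon_centroid <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x + x2) * cross) / (6 * a), sum((y + y2) * cross) / (6 * a))
}

# Even-odd crossing test, vectorised over query points. The strict/non-strict
# asymmetry in the vertex comparison yields a half-open boundary convention:
# a point on a shared edge is counted inside exactly one of the two adjacent
# polygons, so receptors on tract borders are assigned deterministically.
#' @noRd
points_in_polygon <- function(px, py, poly) {
  inside <- logical(length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Sutherland-Hodgman clip of a convex-or-simple ring against the half-plane
# a . p <= b. Returns a matrix (possibly with 0 rows).
#' @noRd
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  out_x <- numeric(0)
  out_y <- numeric(0)
  f <- poly %*% a - b
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    fi <- f[i]; fj <- f[j]
    if (fi <= 0) {
      out_x <- c(out_x, poly[i, 1])
      out_y <- c(out_y, poly[i, 2])
    }
    if ((fi <= 0) != (fj <= 0)) {
      t <- fi / (fi - fj)
      out_x <- c(out_x, poly[i, 1] + t * (poly[j, 1] - poly[i, 1]))
      out_y <- c(out_y, poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
    }
  }
  cbind(out_x, out_y, deparse.level = 0)
}

# Regular polygon approximating a disc of given radius (used both as the
# domain boundary and as the clipping frame for Voronoi cells).
#' @noRd
disc_polygon <- function(radius, centre = c(0, 0), n = 96L) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(centre[1] + radius * cos(theta), centre[2] + radius * sin(theta))
}

# Voronoi cell of site i among `sites` (m x 2), clipped to `frame`.
# Built by intersecting perpendicular-bisector half-planes: p is kept when
# |p - s_i|^2 <= |p - s_j|^2, i.e. 2 p . (s_j - s_i) <= |s_j|^2 - |s_i|^2.
#' @noRd
voronoi_cell <- function(i, sites, frame) {
  poly <- frame
  si <- sites[i, ]
  for (j in seq_len(nrow(sites))) {
    if (j == i) next
    sj <- sites[j, ]
    a <- 2 * (sj - si)
    b <- sum(sj^2) - sum(si^2)
    poly <- clip_halfplane(poly, a, b)
    if (nrow(poly) < 3L) break
  }
  poly
}
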