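# Planar geometry helpers shared by the simulator, the tessellation module
# and the compartment module. Polygons are n x 2 numeric matrices (open ring:
# last vertex != first; closure is implicit).

#' Signed and absolute polygon area
#'
#' Shoelace formula. Positive for counter-clockwise vertex order.
#'
#' @param poly numeric matrix with two columns (x, y), one row per vertex.
#' @return signed area for `polygon_area_signed()`; absolute area for
#'   `polygon_area()`.
#' @keywords internal
polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @rdname polygon_area_signed
#' @keywords internal
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Test points against a polygon
#'
#' Wrapper around [sp::point.in.polygon()]; points on the boundary count as
#' inside.
#'
#' @param x,y point coordinates.
#' @param poly polygon matrix.
#' @return logical vector.
#' @keywords internal
points_in_polygon <- function(x, y, poly) {
  sp::point.in.polygon(x, y, poly[, 1], poly[, 2]) > 0
}

# Proper intersection test for two closed segments, tolerating collinear
# touching. Used only for the simplicity check, so a conservative test is fine.
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

#' Is a polygon simple (non-self-intersecting)?
#'
#' O(n^2) pairwise segment test over non-adjacent edges; adequate for ROI
#' polygons of tens of vertices.
#'
#' @param poly polygon matrix.
#' @return logical scalar.
#' @keywords internal
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  if (anyDuplicated(poly)) return(FALSE)
  idx <- rbind(cbind(seq_len(n), c(2:n, 1)))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (segments_intersect(poly[idx[i, 1], ], poly[idx[i, 2], ],
                             poly[idx[j, 1], ], poly[idx[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Uniform rejection sampling inside a polygon. Draws from the bounding box
# until n points fall inside; polygons used here fill a decent fraction of
# their box so this terminates quickly.
sample_in_polygon <- function(n, poly) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  bx <- range(poly[, 1]); by <- range(poly[, 2])
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    px <- stats::runif(m, bx[1], bx[2])
    py <- stats::runif(m, by[1], by[2])
    keep <- which(points_in_polygon(px, py, poly))
    take <- utils::head(keep, n - got)
    if (length(take)) {
      out[(got + 1):(got + length(take)), ] <- cbind(px[take], py[take])
      got <- got + length(take)
    }
  }
  out
}

# First intersection of the directed segment p0 -> p1 with a polygon edge.
# Returns list(t, a, b) for the earliest crossing parameter t in (0, 1], with
# a, b the edge endpoints, or NULL when no edge is crossed.
first_edge_crossing <- function(p0, p1, poly) {
  n <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  ex <- bx - ax; ey <- by - ay
  denom <- dx * ey - dy * ex
  ok <- abs(denom) > 1e-300
  t <- ((ax - p0[1]) * ey - (ay - p0[2]) * ex) / denom
  u <- ((ax - p0[1]) * dy - (ay - p0[2]) * dx) / denom
  hit <- ok & t > 1e-12 & t <= 1 & u >= -1e-12 & u <= 1 + 1e-12
  if (!any(hit)) return(NULL)
  i <- which(hit)[which.min(t[hit])]
  list(t = t[i], a = c(ax[i], ay[i]), b = c(bx[i], by[i]))
}

# Mirror point p across the infinite line through a-b.
mirror_across_line <- function(p, a, b) {
  d <- b - a
  nrm <- sum(d * d)
  if (nrm == 0) return(p)
  w <- p - a
  proj <- a + d * sum(w * d) / nrm
  2 * proj - p
}

#' Specular reflection of a Brownian step at a polygon boundary
#'
#' Propagates a step from `p0` (inside `poly`) towards `p1`; whenever the
#' segment crosses an edge, the remaining displacement is mirrored across
#' that edge. After `max_bounce` unresolved bounces the walker is left at the
#' last interior point (a stalled step), which keeps the walk inside without
#' biasing it outward.
#'
#' @param p0 interior start point (length-2 numeric).
#' @param p1 proposed end point.
#' @param poly polygon matrix.
#' @param max_bounce maximum number of mirror operations.
#' @return length-2 numeric end point inside `poly`.
#' @keywords internal
reflect_in_polygon <- function(p0, p1, poly, max_bounce = 8L) {
  if (points_in_polygon(p1[1], p1[2], poly)) return(p1)
  cur0 <- p0; cur1 <- p1
  for (i in seq_len(max_bounce)) {
    hit <- first_edge_crossing(cur0, cur1, poly)
    if (is.null(hit)) break
    cross <- cur0 + hit$t * (cur1 - cur0)
    cur1 <- mirror_across_line(cur1, hit$a, hit$b)
    cur0 <- cross
    if (points_in_polygon(cur1[1], cur1[2], poly)) return(cur1)
  }
  p0
}

#' Radial reflection of a step at a circular boundary
#'
#' Positions beyond radius `r` from `center` are mirrored radially back
#' inside (distance d maps to 2r - d), iterating for the rare step that
#' overshoots more than one radius.
#'
#' @param p proposed end point.
#' @param center disc center.
#' @param r disc radius.
#' @return reflected point with distance-to-center <= r.
#' @keywords internal
reflect_in_disc <- function(p, center, r) {
  for (i in 1:16) {
    v <- p - center
    d <- sqrt(sum(v * v))
    if (d <= r) return(p)
    p <- center + v * ((2 * r - d) / d)
    if (2 * r - d < 0) p <- center  # pathological overshoot; recentre
  }
  p
}

# n points uniform in a disc.
sample_in_disc <- function(n, center, r) {
  th <- stats::runif(n, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(n))
  cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
}
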