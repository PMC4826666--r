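# Closed polygons are tibbles/data.frames with x, y columns (mm), vertex list
# open (last vertex != first); all routines treat them as implicitly closed.

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly data frame with `x`, `y` columns (mm), implicitly closed.
#' @return Signed area in mm^2.
#' @export
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  0.5 * sum(x[j] * y - x * y[j])
}

polygon_centroid <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

is_ccw <- function(poly) polygon_area(poly) > 0

ensure_ccw <- function(poly) {
  if (!is_ccw(poly)) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# segment pair proper/improper intersection test, vectorized over segment b
segs_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, cx, cy) (b[1] - a[1]) * (cy - a[2]) - (b[2] - a[2]) * (cx - a[1])
  d1 <- d(p1, p2, q1[, 1], q1[, 2])
  d2 <- d(p1, p2, q2[, 1], q2[, 2])
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' @inheritParams polygon_area
#' @return Logical scalar.
#' @export
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  v <- as.matrix(poly[, c("x", "y")])
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 1L)) {
    # skip adjacent segments (share a vertex)
    js <- setdiff(seq(i + 1L, n), c(i, if (i == 1L) n else i - 1L, nxt[i]))
    js <- js[nxt[js] != i]
    if (!length(js)) next
    if (any(segs_intersect(v[i, ], v[nxt[i], ], v[js, , drop = FALSE], v[nxt[js], , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param x,y numeric vectors of query coordinates (mm).
#' @inheritParams polygon_area
#' @return Logical vector; points on the boundary may report either way.
#' @export
points_in_polygon <- function(x, y, poly) {
  px <- poly$x; py <- poly$y
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    xi <- px[k]; yi <- py[k]; xj <- px[j[k]]; yj <- py[j[k]]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

# strict containment of polygon a inside polygon b: all vertices of a inside b
# and no edge crossings
polygon_inside <- function(a, b) {
  if (!all(points_in_polygon(a$x, a$y, b))) return(FALSE)
  va <- as.matrix(a[, c("x", "y")]); vb <- as.matrix(b[, c("x", "y")])
  na <- nrow(va); nb <- nrow(vb)
  nxa <- c(2:na, 1L); nxb <- c(2:nb, 1L)
  for (i in seq_len(na)) {
    if (any(segs_intersect(va[i, ], va[nxa[i], ], vb, vb[nxb, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# radius of a star-shaped polygon along direction theta from `center`;
# errors if the polygon is not star-shaped about center along that ray
ray_polygon_radius <- function(poly, center, theta) {
  vapply(theta, function(th) {
    hits <- ray_polygon_hits(poly, center, c(cos(th), sin(th)))
    if (length(hits) == 0L) {
      # a ray through a vertex can slip between both adjacent segments
      for (eps in c(1e-9, -1e-9)) {
        hits <- ray_polygon_hits(poly, center, c(cos(th + eps), sin(th + eps)))
        if (length(hits)) break
      }
    }
    if (length(hits) == 0L)
      stop("ray from center does not hit polygon; geometry not star-shaped", call. = FALSE)
    max(hits)
  }, numeric(1))
}

# Sutherland-Hodgman clip of a polygon (n x 2 matrix) against a CCW convex
# polygon; returns the clipped vertex matrix (possibly with 0 rows)
clip_polygon_convex <- function(subject, clip) {
  cx <- clip$x; cy <- clip$y
  m <- length(cx)
  out <- subject
  for (e in seq_len(m)) {
    if (nrow(out) == 0L) break
    ax <- cx[e]; ay <- cy[e]
    bx <- cx[if (e == m) 1L else e + 1L]; by <- cy[if (e == m) 1L else e + 1L]
    inside <- (bx - ax) * (out[, 2] - ay) - (by - ay) * (out[, 1] - ax) >= 0
    n <- nrow(out)
    res <- matrix(0, 0, 2)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (inside[i]) res <- rbind(res, out[i, ])
      if (inside[i] != inside[j]) {
        # intersection of segment out[i]-out[j] with the clip edge line
        dx <- out[j, 1] - out[i, 1]; dy <- out[j, 2] - out[i, 2]
        den <- (bx - ax) * dy - (by - ay) * dx
        t <- ((by - ay) * (out[i, 1] - ax) - (bx - ax) * (out[i, 2] - ay)) / den
        res <- rbind(res, out[i, ] + t * c(dx, dy))
      }
    }
    out <- res
  }
  out
}

# all positive ray parameters t where center + t*d crosses the polygon boundary
ray_polygon_hits <- function(poly, center, d) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(2:n, 1L)
  ex <- x[j] - x; ey <- y[j] - y
  # solve center + t d = v_i + s e_i, 0<=s<1, t>0
  det <- d[1] * (-ey) - d[2] * (-ex)
  rx <- x - center[1]; ry <- y - center[2]
  ok <- abs(det) > 1e-14
  t <- (rx * (-ey) + ry * ex) / det
  s <- (d[1] * ry - d[2] * rx) / det
  t[ok & s >= 0 & s < 1 & t > 1e-12]
}
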