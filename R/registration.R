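# Thin-plate-spline mapping of histology contours onto the ultrasound frame,
# driven by lumen and outer-wall contour correspondence.

# arc-length resampling helper: n points along a closed polygon starting at
# the point closest (by ray) to angle `anchor_theta` from `center`
contour_arc_landmarks <- function(poly, center, anchor_theta, n) {
  poly <- ensure_ccw(poly)
  r0 <- ray_polygon_radius(poly, center, anchor_theta)
  p0 <- center + r0 * c(cos(anchor_theta), sin(anchor_theta))
  v <- as.matrix(poly[, c("x", "y")])
  m <- nrow(v)
  vn <- v[c(2:m, 1L), , drop = FALSE]
  seg <- sqrt(rowSums((vn - v)^2))
  # insert the anchor point: find the closest segment to p0
  d2 <- numeric(m)
  tpar <- numeric(m)
  for (i in seq_len(m)) {
    e <- vn[i, ] - v[i, ]
    t <- sum((p0 - v[i, ]) * e) / sum(e^2)
    t <- min(max(t, 0), 1)
    q <- v[i, ] + t * e
    d2[i] <- sum((p0 - q)^2); tpar[i] <- t
  }
  i0 <- which.min(d2)
  start <- v[i0, ] + tpar[i0] * (vn[i0, ] - v[i0, ])
  # path from `start` CCW around the polygon
  idx <- c(i0, if (i0 < m) (i0 + 1L):m else integer(0), if (i0 > 1L) 1L:(i0 - 1L))
  pts <- rbind(start, v[idx[-1L], , drop = FALSE], start)
  cl <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- cl[length(cl)]
  s <- (seq_len(n) - 1L) / n * total
  out <- matrix(0, n, 2L)
  for (k in seq_len(n)) {
    j <- findInterval(s[k], cl, all.inside = TRUE)
    f <- (s[k] - cl[j]) / (cl[j + 1L] - cl[j])
    out[k, ] <- pts[j, ] + f * (pts[j + 1L, ] - pts[j, ])
  }
  out
}

tps_kernel <- function(r2) ifelse(r2 < 1e-300, 0, 0.5 * r2 * log(r2))

tps_fit <- function(src, dst, lambda = 0) {
  m <- nrow(src)
  d2 <- as.matrix(stats::dist(src))^2
  K <- tps_kernel(d2) + diag(lambda, m)
  P <- cbind(1, src)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  sol <- solve(A, rhs)
  list(src = src, w = sol[seq_len(m), , drop = FALSE],
       a = sol[m + 1:3, , drop = FALSE])
}

tps_eval <- function(fit, pts) {
  pts <- matrix(pts, ncol = 2L)
  d2 <- outer(rowSums(pts^2), rep(1, nrow(fit$src))) +
    outer(rep(1, nrow(pts)), rowSums(fit$src^2)) - 2 * pts %*% t(fit$src)
  d2[d2 < 0] <- 0
  U <- tps_kernel(d2)
  cbind(1, pts) %*% fit$a + U %*% fit$w
}

#' Fit a histology-to-ultrasound contour transform
#'
#' Places matched landmarks on the lumen and outer-wall contours of both
#' images by arc-length parameterization, anchored at the point of maximum
#' wall thickness (which fixes the rotational correspondence), and fits a
#' thin-plate spline through the landmark pairs. This stands in for
#' intensity-based image registration when only contours are available.
#'
#' @param hist_lumen,hist_outer Closed contours on the histology image
#'   (data frames with `x`, `y` in mm).
#' @param us_lumen,us_outer Corresponding contours on the ultrasound image.
#' @param n_landmarks Landmarks per contour (>= 8).
#' @param regularization Bending-energy regularization weight (>= 0); 0
#'   interpolates the landmarks exactly.
#' @return A `contour_transform` with control points, fitted spline and the
#'   maximum landmark residual (mm).
#' @export
fit_contour_transform <- function(hist_lumen, hist_outer, us_lumen, us_outer,
                                  n_landmarks = 16L, regularization = 0) {
  stopifnot(n_landmarks >= 8L, regularization >= 0)
  for (ct in list(hist_lumen, hist_outer, us_lumen, us_outer))
    if (!polygon_is_simple(ct))
      stop("degenerate contour: self-intersecting", call. = FALSE)

  anchor_angle <- function(lum, out) {
    ctr <- polygon_centroid(lum)
    th <- seq(0, 2 * pi, length.out = 241L)[-241L]
    thick <- ray_polygon_radius(out, ctr, th) - ray_polygon_radius(lum, ctr, th)
    # thickness-weighted circular mean of the thickened region: far more
    # stable than the bare argmax when the thickness profile has a plateau
    w <- pmax(thick - (max(thick) + min(thick)) / 2, 0)
    list(theta = atan2(sum(w * sin(th)), sum(w * cos(th))), center = ctr)
  }
  ah <- anchor_angle(hist_lumen, hist_outer)
  au <- anchor_angle(us_lumen, us_outer)

  src <- rbind(
    contour_arc_landmarks(hist_lumen, ah$center, ah$theta, n_landmarks),
    contour_arc_landmarks(hist_outer, ah$center, ah$theta, n_landmarks))
  dst <- rbind(
    contour_arc_landmarks(us_lumen, au$center, au$theta, n_landmarks),
    contour_arc_landmarks(us_outer, au$center, au$theta, n_landmarks))

  fit <- tps_fit(src, dst, regularization)
  resid <- sqrt(rowSums((tps_eval(fit, src) - dst)^2))
  hull <- grDevices::chull(src)
  structure(list(fit = fit, source_points = src, target_points = dst,
                 kind = "thin-plate spline", regularization = regularization,
                 max_residual = max(resid), hull = src[hull, , drop = FALSE]),
            class = "contour_transform")
}

#' Apply a contour transform to contours
#'
#' Maps contour vertices through the fitted thin-plate spline. Points well
#' outside the convex hull of the control points trigger an extrapolation
#' warning.
#'
#' @param transform A `contour_transform`.
#' @param contours A single contour (data frame with `x`, `y`) or a list of
#'   them.
#' @return The mapped contour(s), same structure as the input.
#' @export
apply_transform <- function(transform, contours) {
  stopifnot(inherits(transform, "contour_transform"))
  single <- is.data.frame(contours)
  if (single) contours <- list(contours)
  hull <- transform$hull
  # hull margin: 5% of its diameter
  ctr <- colMeans(hull)
  diam <- max(sqrt(rowSums(sweep(hull, 2, ctr)^2)))
  grown <- sweep(sweep(hull, 2, ctr) * 1.05, 2, ctr, "+")
  hull_poly <- tibble::tibble(x = grown[, 1], y = grown[, 2])
  out <- lapply(contours, function(ct) {
    pts <- as.matrix(ct[, c("x", "y")])
    if (!all(points_in_polygon(pts[, 1], pts[, 2], hull_poly)))
      warning("contour point outside the control-point hull; extrapolating")
    mapped <- tps_eval(transform$fit, pts)
    res <- ct
    res$x <- mapped[, 1]; res$y <- mapped[, 2]
    res
  })
  if (single) out[[1L]] else out
}

#' Register a histology geometry onto ultrasound contours
#'
#' Convenience wrapper: fits the lumen/outer transform and maps all
#' component contours (IMA interface, calcium regions) of the histology
#' geometry onto the ultrasound frame.
#'
#' @param hist_geometry `plaque_geometry` traced on histology.
#' @param us_lumen,us_outer Lumen and outer contours drawn on ultrasound.
#' @inheritParams fit_contour_transform
#' @return A `plaque_geometry` in ultrasound coordinates.
#' @export
register_geometry <- function(hist_geometry, us_lumen, us_outer,
                              n_landmarks = 16L, regularization = 0) {
  tr <- fit_contour_transform(hist_geometry$lumen, hist_geometry$outer,
                              us_lumen, us_outer, n_landmarks, regularization)
  geom <- hist_geometry
  geom$lumen <- tibble::as_tibble(us_lumen)
  geom$outer <- tibble::as_tibble(us_outer)
  geom$ima <- apply_transform(tr, hist_geometry$ima)
  geom$calcium <- if (length(hist_geometry$calcium))
    apply_transform(tr, hist_geometry$calcium) else list()
  geom$center <- polygon_centroid(geom$lumen)
  validate_geometry(geom)
  geom
}
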