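ring <- function(r, n = 60, cx = 0, cy = 0, squish = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(x = cx + r * cos(th), y = cy + squish * r * sin(th))
}

# eccentric wall: lumen offset inside the outer ring fixes the rotation anchor
hist_lumen <- ring(1.2, cx = 0.4)
hist_outer <- ring(3.0)

affine_pts <- function(pts, A, b = c(0, 0)) {
  out <- as.matrix(pts[, c("x", "y")]) %*% t(A)
  tibble::tibble(x = out[, 1] + b[1], y = out[, 2] + b[2])
}

test_that("identical contours give the identity transform", {
  tr <- fit_contour_transform(hist_lumen, hist_outer, hist_lumen, hist_outer)
  expect_lt(tr$max_residual, 1e-9)
  mapped <- apply_transform(tr, ring(2.0, cx = 0.2))
  expect_equal(mapped$x, ring(2.0, cx = 0.2)$x, tolerance = 1e-6)
})

test_that("a pure scaling is recovered for interior points", {
  A <- diag(c(1.2, 1.2))
  us_lumen <- affine_pts(hist_lumen, A)
  us_outer <- affine_pts(hist_outer, A)
  tr <- fit_contour_transform(hist_lumen, hist_outer, us_lumen, us_outer)
  test_pts <- ring(1.9, cx = 0.2, n = 24)
  got <- apply_transform(tr, test_pts)
  want <- affine_pts(test_pts, A)
  rel <- sqrt((got$x - want$x)^2 + (got$y - want$y)^2) /
    sqrt(want$x^2 + want$y^2 + 1e-12)
  expect_lt(max(rel), 0.01)
})

test_that("a 30-degree rotation is recovered for interior points", {
  th <- 30 * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr <- fit_contour_transform(hist_lumen, hist_outer,
                              affine_pts(hist_lumen, A),
                              affine_pts(hist_outer, A))
  test_pts <- ring(2.2, n = 24)
  got <- apply_transform(tr, test_pts)
  want <- affine_pts(test_pts, A)
  err <- sqrt((got$x - want$x)^2 + (got$y - want$y)^2)
  expect_lt(max(err) / 2.2, 0.01)
})

test_that("areas scale as the transform's determinant", {
  A <- diag(c(1.2, 1.2))
  tr <- fit_contour_transform(hist_lumen, hist_outer,
                              affine_pts(hist_lumen, A),
                              affine_pts(hist_outer, A))
  cal <- ring(0.3, cx = 1.6)
  mapped <- apply_transform(tr, cal)
  expect_equal(polygon_area(mapped) / polygon_area(cal), 1.44,
               tolerance = 0.01)
})

test_that("the containment chain survives a smooth synthetic warp", {
  g <- make_vessel_geometry(1.5, 0.5, 1.5, eccentricity = 0.6,
                            calcium_spec = list(size = 0.3, angle = -90),
                            center = c(0, 0))
  # smooth non-affine warp standing in for histology shrinkage (mild
  # anisotropy: strongly anisotropic scalings blunt the thickness-based
  # rotational anchor)
  warp <- function(ct) tibble::tibble(
    x = 1.12 * ct$x + 0.03 * ct$y^2 / 4,
    y = 1.08 * ct$y - 0.04 * ct$x^2 / 4)
  us_lumen <- warp(g$lumen); us_outer <- warp(g$outer)
  reg <- register_geometry(g, us_lumen, us_outer, n_landmarks = 24)
  expect_true(all(points_in_polygon(reg$lumen$x, reg$lumen$y, reg$ima)))
  expect_true(all(points_in_polygon(reg$ima$x, reg$ima$y, reg$outer)))
  # mapped IMA close to the directly warped IMA
  want <- warp(g$ima)
  err <- sqrt((reg$ima$x - want$x)^2 + (reg$ima$y - want$y)^2)
  expect_lt(max(err), 0.15)
})

test_that("points far outside the control hull warn about extrapolation", {
  tr <- fit_contour_transform(hist_lumen, hist_outer, hist_lumen, hist_outer)
  expect_warning(apply_transform(tr, ring(6)), "extrapolat")
})

test_that("degenerate contours are rejected", {
  bad <- hist_lumen
  bad[c(1, 30), ] <- bad[c(30, 1), ]
  expect_error(fit_contour_transform(bad, hist_outer, hist_lumen, hist_outer),
               "degenerate")
})
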