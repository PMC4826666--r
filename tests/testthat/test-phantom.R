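test_that("generated geometries satisfy the containment and orientation invariants", {
  for (ecc in c(0, 0.5, 1)) {
    g <- make_vessel_geometry(1.5, 0.5, 2.0, eccentricity = ecc)
    expect_true(polygon_is_simple(g$lumen))
    expect_true(polygon_is_simple(g$ima))
    expect_true(polygon_is_simple(g$outer))
    expect_true(all(points_in_polygon(g$lumen$x, g$lumen$y, g$ima)))
    expect_true(all(points_in_polygon(g$ima$x, g$ima$y, g$outer)))
    expect_gt(polygon_area(g$lumen), 0)  # counter-clockwise
    expect_gt(polygon_area(g$ima), polygon_area(g$lumen))
    expect_gt(polygon_area(g$outer), polygon_area(g$ima))
  }
})

test_that("shoelace area matches the closed form for the concentric rings", {
  g <- make_vessel_geometry(1.5, 0.5, 2.0, eccentricity = 0, n_vertices = 720L)
  # a regular n-gon inscribed in radius r has area n/2 r^2 sin(2 pi / n)
  n <- 720
  expect_equal(polygon_area(g$lumen), n / 2 * 1.5^2 * sin(2 * pi / n),
               tolerance = 1e-9)
  expect_equal(polygon_area(g$ima), n / 2 * 3.5^2 * sin(2 * pi / n),
               tolerance = 1e-9)
})

test_that("concentric phantoms have uniform intima thickness", {
  g <- make_vessel_geometry(1.5, 0.5, 2.0, eccentricity = 0)
  th <- layer_thickness(g, c(0, 45, 90, 180, 270))
  expect_true(all(abs(th - 2.0) < 0.01))
})

test_that("eccentric intima thins to the opposite pole (ray-cast check)", {
  g <- make_vessel_geometry(1.5, 0.5, 2.0, eccentricity = 1,
                            thick_angle_deg = -90)
  thick <- layer_thickness(g, -90)
  thin <- layer_thickness(g, 90)
  expect_equal(thick, 2.0, tolerance = 0.05)
  expect_lt(thin, 0.06)  # floored near zero
})

test_that("calcium is placed adjacent to the intima-media interface", {
  g <- make_vessel_geometry(1.5, 0.5, 2.0, eccentricity = 0,
                            calcium_spec = list(size = 0.4, angle = 90))
  expect_length(g$calcium, 1L)
  cen <- polygon_centroid(g$calcium[[1]])
  th <- atan2(cen[2] - g$center[2], cen[1] - g$center[1])
  r_ima <- ray_polygon_radius(g$ima, g$center, th)
  r_cen <- sqrt(sum((cen - g$center)^2))
  expect_lt(abs(r_cen - r_ima), 0.3)
  # and inside the tissue band
  expect_true(all(points_in_polygon(g$calcium[[1]]$x, g$calcium[[1]]$y, g$outer)))
  expect_false(any(points_in_polygon(g$calcium[[1]]$x, g$calcium[[1]]$y, g$lumen)))
})

test_that("infeasible parameter sets are rejected", {
  bad <- make_vessel_geometry(1.5, 0.5, 1.0)
  bad$lumen <- bad$ima  # lumen on top of the IMA: containment broken
  expect_error(validate_geometry(bad), "infeasible")
  # calcium overlapping the lumen
  expect_error(make_vessel_geometry(0.3, 0.2, 0.1,
                                    calcium_spec = list(size = 1.5, angle = 0)),
               "infeasible")
})

test_that("scatterer fields have Poisson-consistent counts inside the domain", {
  g <- default_geom()
  s <- make_scatterers(g, density = 200, seed = 7)
  dil_area <- polygon_area(g$outer)  # lower bound (margin excluded)
  lam_lo <- 200 * dil_area
  expect_gt(nrow(s), lam_lo - 5 * sqrt(lam_lo))
  # all scatterers within outer contour + margin: radial check
  d <- sqrt((s$x_mm - g$center[1])^2 + (s$y_mm - g$center[2])^2)
  r_out <- max(sqrt((g$outer$x - g$center[1])^2 + (g$outer$y - g$center[2])^2))
  expect_true(all(d <= r_out + 0.3 + 1e-9))
})

test_that("scatterer generation is bit-identical under a fixed seed", {
  g <- default_geom()
  s1 <- make_scatterers(g, 150, seed = 3)
  s2 <- make_scatterers(g, 150, seed = 3)
  expect_identical(s1$x_mm, s2$x_mm)
  expect_identical(s1$amplitude, s2$amplitude)
})

test_that("zero scatterer density is rejected", {
  expect_error(make_scatterers(default_geom(), 0), "empty speckle")
})

test_that("geometry JSON round-trips losslessly", {
  g <- make_vessel_geometry(1.5, 0.5, 1.0, eccentricity = 0.5,
                            calcium_spec = list(size = 0.3, angle = -45))
  f <- withr::local_tempfile(fileext = ".json")
  write_geometry(g, f)
  g2 <- read_geometry(f)
  expect_equal(g2$lumen$x, g$lumen$x)
  expect_equal(g2$ima$y, g$ima$y)
  expect_equal(g2$calcium[[1]]$x, g$calcium[[1]]$x)
  expect_equal(g2$center, g$center)
})

test_that("malformed geometry files are rejected", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(read_geometry(f), "malformed")

  # self-intersecting contour
  g <- default_geom()
  bow <- g$lumen
  bow[c(1, 25), ] <- bow[c(25, 1), ]  # swap two vertices to create a crossing
  g$lumen <- bow
  f2 <- withr::local_tempfile(fileext = ".json")
  obj <- list(units = "mm", center = g$center,
              contours = list(lumen = unname(as.matrix(bow)),
                              ima = unname(as.matrix(g$ima)),
                              outer = unname(as.matrix(g$outer))))
  jsonlite::write_json(obj, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_geometry(f2), "self-intersecting")

  # lumen outside the outer contour
  g3 <- default_geom()
  shifted <- g3$lumen
  shifted$x <- shifted$x + 10
  obj3 <- list(units = "mm", center = g3$center,
               contours = list(lumen = unname(as.matrix(shifted)),
                               ima = unname(as.matrix(g3$ima)),
                               outer = unname(as.matrix(g3$outer))))
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj3, f3, auto_unbox = TRUE, digits = NA)
  expect_error(read_geometry(f3), "infeasible")
})
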