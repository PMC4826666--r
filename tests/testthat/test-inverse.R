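test_that("step definitions match the inflation protocol", {
  sd <- step_definitions()
  expect_equal(sd$from_mmHg, c(10, 80, 100))
  expect_equal(sd$to_mmHg, c(80, 100, 120))
})

test_that("the default phantom yields 30-50 measurement cells, disjoint and in tissue", {
  g <- default_geom()
  grid <- build_measurement_grid(g)
  n <- attr(grid, "n")
  expect_gte(n, 30); expect_lte(n, 50)
  # cells pairwise disjoint (centers at least one cell size apart per axis)
  d <- as.matrix(stats::dist(cbind(grid$x_mm, grid$y_mm)))
  diag(d) <- Inf
  expect_gte(min(d), attr(grid, "cell_mm") - 1e-12)
  # all corners inside tissue
  h <- attr(grid, "cell_mm") / 2
  for (dd in list(c(-h, -h), c(h, h))) {
    expect_true(all(points_in_polygon(grid$x_mm + dd[1], grid$y_mm + dd[2],
                                      g$outer)))
    expect_false(any(points_in_polygon(grid$x_mm + dd[1], grid$y_mm + dd[2],
                                       g$lumen)))
  }
  expect_true(all(c("near", "far") %in% grid$side))
})

test_that("a band outside the vessel is rejected", {
  g <- default_geom()
  g2 <- g
  g2$center <- g$center + c(20, 0)  # band no longer crosses the tissue
  expect_error(build_measurement_grid(g2), "grid|band")
})

test_that("grid averaging is exact for constant and linear fields", {
  g <- default_geom()
  grid <- build_measurement_grid(g)
  # computed-field route (4x4 quadrature)
  const <- function(p) cbind(0, rep(0.123, nrow(p)))
  expect_equal(average_on_grid(const, grid), rep(0.123, nrow(grid)))
  lin <- function(p) cbind(0, 0.04 * p[, 2])
  expect_equal(average_on_grid(lin, grid), 0.04 * grid$y_mm, tolerance = 1e-12)
})

test_that("measured-map and quadrature averaging agree on a smooth field", {
  g <- default_geom()
  grid <- build_measurement_grid(g)
  f <- function(y, x) 50 * sin(y / 2) + 5 * x          # um
  y <- seq(0, 10, by = 0.015); x <- seq(-0.5, 0.5, by = 0.05)
  map <- structure(list(
    axial_um = outer(y, x, f), lateral_um = outer(y, x, f) * 0,
    corr = outer(y, x, f) * 0 + 1, y_mm = y, x_mm = x,
    axial_step_um = 15, lateral_step_um = 50,
    sample_step_um = 5, line_pitch_um = 50), class = "displacement_map")
  u_map <- average_on_grid(map, grid)
  u_q <- average_on_grid(function(p) cbind(0, f(p[, 2], p[, 1]) / 1000), grid)
  expect_equal(u_map, u_q * 1000 / 1000, tolerance = 0.02)
})

test_that("objective function and relative difference follow the printed formulas", {
  expect_equal(objective_F(c(0.1, 0.2), c(0, 0)), 0.05)
  expect_equal(objective_F(1:4 / 10, 1:4 / 10), 0)
  expect_error(objective_F(1:3, 1:4), "equal-length")
  # F is invariant only under simultaneous permutation of both vectors
  set.seed(1)
  a <- runif(6); b <- runif(6); pr <- sample(6)
  expect_equal(objective_F(a[pr], b[pr]), objective_F(a, b))
  expect_false(isTRUE(all.equal(objective_F(a[pr], b), objective_F(a, b))))

  expect_equal(relative_difference(0, 10, 0.5), 0)
  expect_equal(relative_difference(0.04, 40, 0.25), 2.0)
  expect_error(relative_difference(0.1, 10, 0), "zero mean")
  # degree-0 homogeneity: scaling displacements and errors together
  expect_equal(relative_difference(0.04 * 4, 40, 0.5),
               relative_difference(0.04, 40, 0.25))
  # rms alternative stays available but differs
  expect_equal(relative_difference(0.04, 40, 0.25, method = "rms"),
               sqrt(0.001) / 0.25 * 100)
})

test_that("E = 6C exactly, including the calcium assumption", {
  expect_equal(young_from_shear(1), 6)
  expect_equal(young_from_shear(100), 600)
  expect_equal(young_from_shear(1e5), 6e5)
  expect_error(young_from_shear(0), "positive")
})

test_that("grid search recovers lattice truths with the documented tie-breaking", {
  # cheap analytic stand-in for the FE forward: smooth, injective response
  toy <- function(Cw, Ci, step) {
    p <- c(9.33, 2.67, 2.67)[step]
    c(p / Cw, p / Ci, p / (Cw + Ci))
  }
  lat <- lattice_spec("linear", values = seq(20, 200, by = 20))
  u_meas <- lapply(1:3, function(s) toy(120, 40, s))
  est <- grid_search(toy, u_meas, lat)
  expect_equal(est$C_wall, rep(120, 3))
  expect_equal(est$C_intima, rep(40, 3))
  expect_equal(est$F_mm2, rep(0, 3))
  expect_equal(est$E_wall, rep(720, 3))
  # off-lattice truth lands on a lattice neighbour
  est2 <- grid_search(toy, list(toy(127, 40, 1)), lat, steps = 1L)
  expect_lte(abs(est2$C_wall - 127), 20)
  # ties: a forward that ignores the intima must pick the smallest C_intima
  flat <- function(Cw, Ci, step) c(1 / Cw, 2 / Cw)
  est3 <- grid_search(flat, list(flat(100, 1, 1)), lat, steps = 1L)
  expect_equal(est3$C_intima, 20)
})

test_that("non-converging lattice points are excluded with a warning", {
  part <- function(Cw, Ci, step) {
    if (Cw < 50) stop("no convergence")
    c(10 / Cw, 10 / Ci)
  }
  lat <- lattice_spec("linear", values = seq(20, 200, by = 30))
  expect_warning(est <- grid_search(part, list(part(110, 80, 1)), lat, steps = 1L),
                 "excluded")
  expect_equal(est$C_wall, 110)
})

test_that("the two-stage lattice refines around the coarse winner", {
  toy <- function(Cw, Ci, step) c(9.33 / Cw, 9.33 / Ci)
  lat <- lattice_spec("two_stage", coarse_n = 10L, refine_n = 5L)
  est <- grid_search(toy, list(toy(150, 30, 1)), lat, steps = 1L)
  step_w <- attr(est, "lattice_step")[1]
  expect_lte(abs(est$C_wall - 150), step_w + 1e-9)
  expect_gt(step_w, 0)
})

test_that("tidy and glance summarize a stiffness estimate", {
  toy <- function(Cw, Ci, step) c(1 / Cw, 1 / Ci)
  lat <- lattice_spec("linear", values = c(50, 100, 150))
  est <- grid_search(toy, lapply(1:3, function(s) toy(100, 50, s)), lat)
  td <- tidy(est)
  expect_setequal(unique(td$component), c("wall", "intima"))
  expect_equal(nrow(td), 6)
  expect_true(all(td$E == 6 * td$C))
  gl <- glance(est)
  expect_equal(gl$n_steps, 3)
})
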