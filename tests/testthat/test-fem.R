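test_that("strain energy density matches closed forms", {
  expect_equal(strain_energy_density(10, diag(2)), 0)
  # isochoric simple shear gamma = 0.5: I1 = 3 + gamma^2
  Fs <- matrix(c(1, 0, 0.5, 1), 2, 2)
  expect_equal(strain_energy_density(10, Fs), 10 * 0.25)
  expect_error(strain_energy_density(10, diag(c(-1, 1))), "Jacobian")
})

test_that("strain energy is non-negative for random isochoric deformations", {
  set.seed(42)
  for (i in 1:50) {
    A <- matrix(rnorm(4, sd = 0.3), 2, 2) + diag(2)
    if (det(A) <= 0) next
    F1 <- A / sqrt(det(A))  # det = 1
    expect_gte(strain_energy_density(5, F1), -1e-12)
  }
})

test_that("zero pressure produces zero displacement", {
  m <- coarse_mesh()
  sol <- solve_inflation(m, material_map(50, 50),
                         pressure_protocol(c(10), reference_mmHg = 10))
  expect_lt(max(abs(sol[[1]]$U)), 1e-12)
})

test_that("analytic tube oracle: limits and monotonicity", {
  expect_equal(analytic_tube_inflation(50, 1.5, 3.25, 0), 1.5)
  # small-load slope matches the plane-strain incompressible Lame solution
  # u(A) = P A B^2 / (4 C (B^2 - A^2))
  P <- 0.01
  u_num <- analytic_tube_inflation(50, 1.5, 3.25, P) - 1.5
  u_lin <- P * 1.5 * 3.25^2 / (4 * 50 * (3.25^2 - 1.5^2))
  expect_equal(u_num, u_lin, tolerance = 0.02)
  r1 <- analytic_tube_inflation(50, 1.5, 3.25, 5)
  r2 <- analytic_tube_inflation(50, 1.5, 3.25, 10)
  expect_gt(r2, r1)
})

test_that("FE tube inflation matches the 1D oracle at a representative load", {
  m <- coarse_mesh()
  C <- 50; P <- 10
  sol <- solve_inflation(m, material_map(C, C),
                         pressure_protocol(c(10, 10 + P / MMHG_TO_KPA)))
  exp_fe <- lumen_expansion(m, sol[[2]])
  exp_an <- analytic_tube_inflation(C, 1.5, 3.25, P) - 1.5
  expect_equal(exp_fe, exp_an, tolerance = 0.01)
})

test_that("doubling all moduli strictly shrinks the displacement field", {
  m <- coarse_mesh()
  prot <- pressure_protocol(c(10, 80))
  s1 <- solve_inflation(m, material_map(30, 10), prot)[[2]]
  s2 <- solve_inflation(m, material_map(60, 20), prot)[[2]]
  lum <- unique(as.vector(m$lumen_edges))
  mag1 <- sqrt(rowSums(s1$U[lum, ]^2))
  mag2 <- sqrt(rowSums(s2$U[lum, ]^2))
  expect_true(all(mag2 < mag1))
})

test_that("tissue is incompressible to within 0.5% area change at the top load", {
  m <- coarse_mesh()
  sol <- solve_inflation(m, material_map(25, 8), pressure_protocol(c(10, 120)))
  a0 <- element_areas(m); a1 <- element_areas(m, sol[[2]]$U)
  tis <- m$region != "buffer"
  expect_lt(abs(sum(a1[tis]) - sum(a0[tis])) / sum(a0[tis]), 0.005)
})

test_that("mixed and penalty formulations agree within 1%", {
  m <- coarse_mesh()
  prot <- pressure_protocol(c(10, 90))
  s_mix <- solve_inflation(m, material_map(40, 40), prot)[[2]]
  s_pen <- solve_inflation(m, material_map(40, 40), prot,
                           solver_opts = list(formulation = "penalty"))[[2]]
  e_mix <- lumen_expansion(m, s_mix)
  e_pen <- lumen_expansion(m, s_pen)
  expect_equal(e_pen, e_mix, tolerance = 0.01)
})

test_that("layered tube inflation matches the two-layer 1D solution", {
  m <- coarse_mesh()
  prot <- pressure_protocol(c(10, 90))
  an <- analytic_tube_inflation(c(15, 40), 1.5, 3.25, prot$kPa_gauge[2],
                                interface_radius = 2.75) - 1.5
  # penalty path (element-wise volumetric treatment) resolves the
  # bi-material interface sharply
  e_pen <- lumen_expansion(m, solve_inflation(
    m, material_map(40, 15), prot,
    solver_opts = list(formulation = "penalty"))[[2]])
  expect_equal(e_pen, an, tolerance = 0.01)
  # the mixed element smears the interface pressure jump over one element
  # layer; its small systematic bias is documented
  e_mix <- lumen_expansion(m, solve_inflation(m, material_map(40, 15), prot)[[2]])
  expect_equal(e_mix, an, tolerance = 0.03)
})

test_that("the model obeys the exact modulus-pressure scaling law", {
  m <- coarse_mesh()
  s1 <- solve_inflation(m, material_map(20, 5, C_buffer = 0.002),
                        pressure_protocol(c(10, 70)))[[2]]
  # k x moduli at k x pressure: gauge load doubles when (P - 10) doubles
  s2 <- solve_inflation(m, material_map(40, 10, C_buffer = 0.004),
                        pressure_protocol(c(10, 130)))[[2]]
  expect_equal(s2$U, s1$U, tolerance = 1e-6)
})

test_that("lumen displacement is insensitive to the buffer stiffness", {
  m <- coarse_mesh()
  prot <- pressure_protocol(c(10, 100))
  e <- vapply(c(0.001, 0.1), function(cb)
    lumen_expansion(m, solve_inflation(m, material_map(150, 30, C_buffer = cb),
                                       prot)[[2]]), numeric(1))
  expect_lt(abs(e[2] - e[1]) / e[1], 0.005)
})

test_that("displacement interpolation is exact at nodes and for linear fields", {
  m <- coarse_mesh()
  n <- nrow(m$nodes)
  U <- cbind(0.3 + 0.1 * m$nodes[, 1] - 0.05 * m$nodes[, 2],
             -0.2 + 0.02 * m$nodes[, 1] + 0.07 * m$nodes[, 2])
  sol <- structure(list(U = U), class = "fe_solution")
  # at a node
  pick <- c(10L, 500L)
  got <- interpolate_displacement(sol, m, m$nodes[pick, ])
  expect_equal(got, U[pick, ], tolerance = 1e-10)
  # linear field reproduced anywhere in the domain
  pts <- cbind(c(0.2, -1.0, 1.7), 6 + c(1.7, -2.0, 0.4))
  got2 <- interpolate_displacement(sol, m, pts)
  want <- cbind(0.3 + 0.1 * pts[, 1] - 0.05 * pts[, 2],
                -0.2 + 0.02 * pts[, 1] + 0.07 * pts[, 2])
  expect_equal(got2, want, tolerance = 1e-9)
  expect_error(interpolate_displacement(sol, m, cbind(50, 50)), "outside")
})

test_that("solver reports non-convergence on a hopeless load step", {
  m <- coarse_mesh()
  expect_error(
    solve_inflation(m, material_map(0.05, 0.05),
                    pressure_protocol(c(10, 120)),
                    solver_opts = list(max_bisect = 2L, max_it = 6L)),
    "did not converge")
})
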