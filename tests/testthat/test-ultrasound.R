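tr <- transducer_spec()

test_that("transducer defaults satisfy the sampling invariant", {
  expect_equal(tr$axial_step_um, 1540 / (2 * 160))
  expect_error(transducer_spec(center_frequency = 40, sampling_frequency = 100),
               "4x")
})

test_that("a single scatterer produces a peak at its location", {
  scat <- structure(tibble::tibble(x_mm = 0, y_mm = 5, amplitude = 1),
                    class = c("scatterer_field", "tbl_df", "tbl", "data.frame"))
  rf <- simulate_rf(scat, tr, fov = list(x0_mm = -1, width_mm = 2, depth_mm = 7))
  env <- plaquemech:::rf_envelope(rf$samples)
  pk <- which(env == max(env), arr.ind = TRUE)[1, ]
  y_pk <- (pk[1] - 1) * rf$axial_step_um / 1000
  x_pk <- rf$x0_mm + (pk[2] - 1) * rf$line_pitch_um / 1000
  expect_lt(abs(y_pk - 5), 2 * rf$axial_step_um / 1000)
  expect_lt(abs(x_pk - 0), 2 * rf$line_pitch_um / 1000)
})

test_that("RF simulation is deterministic given the seed", {
  scat <- speckle_slab(n = 2000)
  a <- simulate_rf(scat, tr, slab_fov, noise_snr_db = 20, seed = 5)
  b <- simulate_rf(scat, tr, slab_fov, noise_snr_db = 20, seed = 5)
  expect_identical(a$samples, b$samples)
})

test_that("dense speckle has a Rayleigh-distributed envelope", {
  scat <- speckle_slab(n = 24000, seed = 2)   # >= 10 per resolution cell
  rf <- simulate_rf(scat, tr, slab_fov)
  env <- plaquemech:::rf_envelope(rf$samples)
  # interior samples, decimated well beyond the resolution-cell size for
  # approximate independence, and thinned so the test is not powered to
  # detect the residual correlation
  sub <- env[seq(450, 1700, by = 16), seq(20, 140, by = 8)]
  set.seed(1)
  x <- sample(as.vector(sub), 300)
  sigma <- sqrt(mean(x^2) / 2)  # Rayleigh MLE
  ks <- suppressWarnings(stats::ks.test(x, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("displace_scatterers moves positions and preserves amplitudes", {
  s <- speckle_slab(500)
  z <- displace_scatterers(s, matrix(0, nrow(s), 2))
  expect_equal(z$x_mm, s$x_mm)
  u <- displace_scatterers(s, cbind(0, rep(0.030, nrow(s))))
  expect_equal(u$y_mm, s$y_mm + 0.030)
  expect_identical(u$amplitude, s$amplitude)
  expect_error(displace_scatterers(s, matrix(NA_real_, nrow(s), 2)),
               "domain")
})

test_that("a radial expansion preserves the radial ordering of scatterers", {
  g <- default_geom(); m <- coarse_mesh()
  sol <- solve_inflation(m, material_map(25, 8), pressure_protocol(c(10, 80)))[[2]]
  set.seed(9)
  s <- make_scatterers(g, 100, seed = 9, exclude_lumen = TRUE, margin = 0.1)
  u <- interpolate_displacement(sol, m, cbind(s$x_mm, s$y_mm), extrapolate = TRUE)
  s2 <- displace_scatterers(s, u)
  r1 <- sqrt((s$x_mm - g$center[1])^2 + (s$y_mm - g$center[2])^2)
  r2 <- sqrt((s2$x_mm - g$center[1])^2 + (s2$y_mm - g$center[2])^2)
  # no crossings along any ray: within narrow angular sectors the radial
  # ordering is preserved (a small tolerance absorbs the slight angular
  # dependence of the expansion between nearly-equal radii)
  th <- atan2(s$y_mm - g$center[2], s$x_mm - g$center[1])
  sector <- cut(th, breaks = seq(-pi, pi, length.out = 33L))
  for (sec in levels(sector)) {
    idx <- which(sector == sec)
    if (length(idx) < 2L) next
    expect_true(all(diff(r2[idx][order(r1[idx])]) > -1e-3))
  }
})

test_that("b-mode output is normalized and localizes a single scatterer", {
  scat <- structure(tibble::tibble(x_mm = 0.2, y_mm = 4, amplitude = 1),
                    class = c("scatterer_field", "tbl_df", "tbl", "data.frame"))
  rf <- simulate_rf(scat, tr, fov = list(x0_mm = -1, width_mm = 2, depth_mm = 6))
  img <- bmode(rf, 40)
  expect_true(all(img >= 0 & img <= 1))
  pk <- which(unclass(img) == max(img), arr.ind = TRUE)[1, ]
  expect_lt(abs((pk[1] - 1) * rf$axial_step_um / 1000 - 4), 0.05)
  # all-zero frame
  rf0 <- rf; rf0$samples <- rf0$samples * 0
  expect_true(all(bmode(rf0) == 0))
})

test_that("shift theorem: displaced scatterers equal an axial resample shift", {
  scat <- speckle_slab(8000, seed = 4)
  shift_samples <- 4L
  d_mm <- shift_samples * tr$axial_step_um / 1000
  rf1 <- simulate_rf(scat, tr, slab_fov)
  rf2 <- simulate_rf(displace_scatterers(scat, cbind(0, rep(d_mm, nrow(scat)))),
                     tr, slab_fov)
  rolled <- rf1$samples * 0
  rolled[(1 + shift_samples):nrow(rolled), ] <-
    rf1$samples[1:(nrow(rolled) - shift_samples), ]
  core <- 500:1500
  err <- rf2$samples[core, ] - rolled[core, ]
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(rf2$samples[core, ]^2)), 1e-6)
})

test_that("RF energy grows linearly with scatterer count", {
  e <- vapply(c(6000, 12000, 24000), function(n) {
    rf <- simulate_rf(speckle_slab(n, seed = 8), tr, slab_fov)
    mean(rf$samples^2)
  }, numeric(1))
  expect_equal(e[2] / e[1], 2, tolerance = 0.1)
  expect_equal(e[3] / e[2], 2, tolerance = 0.1)
})

test_that("RF frames round-trip through the binary + sidecar format", {
  rf <- simulate_rf(speckle_slab(1000), tr, slab_fov)
  f <- withr::local_tempfile(fileext = ".rf")
  write_rf(rf, f)
  rf2 <- read_rf(f)
  expect_equal(rf2$samples, rf$samples)
  expect_equal(rf2$axial_step_um, rf$axial_step_um)
  expect_equal(rf2$transducer$center_frequency, rf$transducer$center_frequency)
})
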