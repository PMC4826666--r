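test_that("the default schedule reproduces the published kernel settings", {
  s <- default_schedule()
  expect_equal(unname(unlist(s[1, c("template_ax_um", "template_lat_um")])),
               c(3850, 715))
  expect_equal(unname(unlist(s[1, c("search_ax_um", "search_lat_um")])),
               c(7700, 935))
  expect_equal(s$overlap_ax, c(0.50, 0.75, 0.75))
  expect_equal(s$overlap_lat, rep(0.92, 3))
  # kernel sizes identical in iterations two and three
  expect_equal(s$template_ax_um[2], s$template_ax_um[3])
  expect_equal(s$search_ax_um[2], s$search_ax_um[3])
  expect_true(s$local_align[3] && s$subsample[3])
})

test_that("physical kernel sizes convert to even sample counts with the documented rounding", {
  rf <- list(axial_step_um = 1540 / 320, line_pitch_um = 20)
  ss <- plaquemech:::schedule_in_samples(default_schedule(), rf)
  expect_equal(ss$ta, c(800L, 12L, 12L))
  expect_equal(ss$sa, c(1600L, 24L, 24L))
  expect_equal(ss$tl, c(34L, 34L, 34L))
  expect_equal(ss$step_ax, c(400L, 3L, 3L))
  # grid contract: final-iteration step in samples times the sample pitch
  expect_equal(ss$step_ax[3] * rf$axial_step_um, 3 * 4.8125)
})

test_that("ncc_surface finds embedded blocks with peak +/- 1", {
  set.seed(11)
  search <- matrix(rnorm(60 * 40), 60, 40)
  tmpl <- search[21:32, 11:20]
  cc <- ncc_surface(tmpl, search)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(21, 11))
  expect_equal(max(cc), 1, tolerance = 1e-12)
  cc_neg <- ncc_surface(-tmpl, search)
  expect_equal(cc_neg[21, 11], -1, tolerance = 1e-12)
  # independent noise never reaches |1|
  other <- matrix(rnorm(60 * 40), 60, 40)
  expect_lt(max(abs(ncc_surface(tmpl, other))), 1)
  expect_error(ncc_surface(matrix(1, 5, 5), search), "flat signal")
})

test_that("FFT and direct NCC paths agree", {
  set.seed(3)
  tmpl <- matrix(rnorm(40 * 12), 40, 12)
  search <- matrix(rnorm(90 * 20), 90, 20)
  d <- plaquemech:::.ncc_surface_core(tmpl, search, FALSE)
  f <- plaquemech:::.ncc_surface_core(tmpl, search, TRUE)
  expect_equal(d, f, tolerance = 1e-10)
})

test_that("parabolic subsample interpolation is exact for parabolas", {
  expect_equal(parabolic_subsample(0.5, 1.0, 0.5), 0)
  y <- function(x) 1 - (x - 0.2)^2
  expect_equal(parabolic_subsample(y(-1), y(0), y(1)), 0.2)
  expect_warning(d <- parabolic_subsample(1, 1, 1), "flat")
  expect_equal(d, 0)
  expect_error(parabolic_subsample(1, 0.5, 0.8), "largest")
})

test_that("median filtering removes spikes and respects order-statistic bounds", {
  rf <- list(axial_step_um = 4.8125, line_pitch_um = 20)
  mk <- function(m) plaquemech:::new_displacement_map(
    m, m * 0, m * 0 + 1, seq_len(nrow(m)) - 1L, seq_len(ncol(m)) - 1L,
    list(axial_step_um = 4.8125, line_pitch_um = 20, x0_mm = 0))
  const <- mk(matrix(2.5, 8, 8))
  expect_equal(median_filter_displacements(const)$axial_um, matrix(2.5, 8, 8))
  spiked <- matrix(1, 9, 9); spiked[5, 5] <- 50
  expect_equal(median_filter_displacements(mk(spiked))$axial_um, matrix(1, 9, 9))
  set.seed(2)
  noisy <- matrix(rnorm(100), 10, 10)
  filt <- median_filter_displacements(mk(noisy))$axial_um
  expect_true(all(filt >= min(noisy) & filt <= max(noisy)))
  expect_error(median_filter_displacements(mk(matrix(1, 3, 3))), "smaller")
})

test_that("tracking identical frames yields a zero displacement map", {
  rf <- simulate_rf(speckle_slab(12000, seed = 6), transducer_spec(), slab_fov)
  m <- estimate_displacement(rf, rf, roi = slab_roi)
  expect_lt(max(abs(m$axial_um)), 1e-9)
  expect_lt(max(abs(m$lateral_um)), 1e-9)
  expect_equal(m$axial_step_um, 3 * 4.8125)   # grid contract
  expect_equal(m$lateral_step_um, 3 * 20)
  expect_error(estimate_displacement(rf, structure(list(
    samples = rf$samples * 0, axial_step_um = rf$axial_step_um,
    line_pitch_um = rf$line_pitch_um, x0_mm = rf$x0_mm,
    transducer = rf$transducer), class = "rf_frame")), "all-zero")
})

test_that("estimating pre->post and negating approximates post->pre", {
  tr <- transducer_spec()
  scat <- speckle_slab(16000, seed = 12)
  d_mm <- 0.7 * tr$axial_step_um / 1000
  scat2 <- displace_scatterers(scat, cbind(0, rep(d_mm, nrow(scat))))
  a <- simulate_rf(scat, tr, slab_fov, noise_snr_db = 30, seed = 21)
  b <- simulate_rf(scat2, tr, slab_fov, noise_snr_db = 30, seed = 22)
  fwd <- estimate_displacement(a, b, roi = slab_roi)
  bwd <- estimate_displacement(b, a, roi = slab_roi)
  dif <- fwd$axial_um + bwd$axial_um
  expect_lt(median(abs(dif)), 1)
})

test_that("displacement maps round-trip through CSV + JSON", {
  rf <- simulate_rf(speckle_slab(8000, seed = 13), transducer_spec(), slab_fov)
  m <- estimate_displacement(rf, rf, roi = slab_roi)
  f <- withr::local_tempfile(fileext = ".csv")
  write_displacement_map(m, f)
  m2 <- read_displacement_map(f)
  expect_equal(m2$axial_um, m$axial_um)
  expect_equal(m2$y_mm, m$y_mm)
  expect_equal(m2$axial_step_um, m$axial_step_um)
})
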