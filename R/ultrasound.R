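#' Linear-array transducer specification
#'
#' Defaults emulate a 40 MHz high-frequency linear array: 160 MHz axial
#' sampling (4 samples per carrier period), 20 um line pitch and 50%
#' fractional bandwidth, so that a 60 um axial kernel holds 12 RF samples.
#' The axial depth-to-sample convention is `y = k * axial_step` with
#' `axial_step = c / (2 fs)` (4.8125 um at the defaults).
#'
#' @param center_frequency Center frequency in MHz.
#' @param sampling_frequency Axial sampling frequency in MHz
#'   (must be >= 4 x center frequency).
#' @param line_pitch Lateral RF line spacing in um.
#' @param pulse_bandwidth Fractional -6 dB (FWHM) bandwidth of the Gaussian
#'   pulse spectrum.
#' @param speed_of_sound m/s.
#' @param lateral_beam_sigma Gaussian lateral beam sigma in um.
#' @return A `transducer_spec` list, including the derived `axial_step_um`
#'   and axial pulse envelope `sigma_ax_um`.
#' @export
transducer_spec <- function(center_frequency = 40, sampling_frequency = 160,
                            line_pitch = 20, pulse_bandwidth = 0.5,
                            speed_of_sound = 1540, lateral_beam_sigma = 50) {
  stopifnot(center_frequency > 0, line_pitch > 0, pulse_bandwidth > 0,
            speed_of_sound > 0, lateral_beam_sigma > 0)
  if (sampling_frequency < 4 * center_frequency)
    stop("sampling_frequency must be at least 4x the center frequency", call. = FALSE)
  c_um_per_us <- speed_of_sound  # m/s == um/us
  axial_step_um <- c_um_per_us / (2 * sampling_frequency)
  sigma_f <- pulse_bandwidth * center_frequency / (2 * sqrt(2 * log(2)))  # MHz
  sigma_t <- 1 / (2 * pi * sigma_f)                                       # us
  sigma_ax_um <- c_um_per_us * sigma_t / 2
  structure(list(center_frequency = center_frequency,
                 sampling_frequency = sampling_frequency,
                 line_pitch = line_pitch, pulse_bandwidth = pulse_bandwidth,
                 speed_of_sound = speed_of_sound,
                 lateral_beam_sigma = lateral_beam_sigma,
                 axial_step_um = axial_step_um, sigma_ax_um = sigma_ax_um,
                 carrier_per_um = 2 * center_frequency / c_um_per_us),
            class = "transducer_spec")
}

#' Simulate an RF frame of a scatterer field
#'
#' Convolutional point-spread-function model: each RF line is the sum over
#' scatterers of amplitude x lateral Gaussian beam weight x
#' Gaussian-modulated cosine pulse centered at the scatterer's axial
#' position. Optional additive white Gaussian noise at a stated SNR.
#'
#' @param scatterers A `scatterer_field`.
#' @param transducer A `transducer_spec`.
#' @param fov List with `x0_mm` (lateral position of the first line),
#'   `width_mm` and `depth_mm`; defaults cover the scatterer bounding box.
#' @param noise_snr_db Optional signal-to-noise ratio in dB.
#' @param seed RNG seed for the noise realization.
#' @return An `rf_frame`: list with `samples` (axial sample x line matrix),
#'   `axial_step_um`, `line_pitch_um`, `x0_mm` and the `transducer`.
#' @export
simulate_rf <- function(scatterers, transducer = transducer_spec(), fov = NULL,
                        noise_snr_db = NULL, seed = 1L) {
  if (nrow(scatterers) == 0L) stop("empty scatterer field", call. = FALSE)
  if (is.null(fov)) {
    pad <- 0.5
    fov <- list(x0_mm = min(scatterers$x_mm) - pad,
                width_mm = diff(range(scatterers$x_mm)) + 2 * pad,
                depth_mm = max(scatterers$y_mm) + pad)
  }
  n_lines <- max(2L, as.integer(ceiling(fov$width_mm * 1000 / transducer$line_pitch)) + 1L)
  n_samples <- max(2L, as.integer(ceiling(fov$depth_mm * 1000 / transducer$axial_step_um)) + 1L)
  rf <- .simulate_rf_core(scatterers$x_mm, scatterers$y_mm, scatterers$amplitude,
                          n_samples, n_lines, fov$x0_mm,
                          transducer$line_pitch, transducer$axial_step_um,
                          transducer$lateral_beam_sigma, transducer$sigma_ax_um,
                          transducer$carrier_per_um)
  if (!is.null(noise_snr_db)) {
    set.seed(seed)
    p_sig <- mean(rf^2)
    if (p_sig > 0) {
      sd_n <- sqrt(p_sig / 10^(noise_snr_db / 10))
      rf <- rf + matrix(stats::rnorm(length(rf), sd = sd_n), nrow(rf))
    }
  }
  structure(list(samples = rf, axial_step_um = transducer$axial_step_um,
                 line_pitch_um = transducer$line_pitch, x0_mm = fov$x0_mm,
                 transducer = transducer),
            class = "rf_frame")
}

#' Displace a scatterer field by a displacement field
#'
#' @param scatterers A `scatterer_field`.
#' @param displacement Either an n x 2 matrix of displacements (mm) matching
#'   the scatterer rows, or a function `f(x_mm, y_mm)` returning one.
#' @return The displaced `scatterer_field` (amplitudes unchanged).
#' @export
displace_scatterers <- function(scatterers, displacement) {
  if (is.function(displacement))
    displacement <- displacement(scatterers$x_mm, scatterers$y_mm)
  displacement <- matrix(displacement, ncol = 2L)
  stopifnot(nrow(displacement) == nrow(scatterers))
  if (anyNA(displacement))
    stop("scatterer outside displacement-field domain", call. = FALSE)
  out <- scatterers
  out$x_mm <- out$x_mm + displacement[, 1]
  out$y_mm <- out$y_mm + displacement[, 2]
  out
}

# analytic-signal envelope per RF line via FFT
rf_envelope <- function(samples) {
  n <- nrow(samples)
  X <- stats::mvfft(samples)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::mvfft(X * h, inverse = TRUE) / n)
}

#' B-mode image from an RF frame
#'
#' Envelope via the analytic-signal magnitude per line, log-compressed to
#' the given dynamic range and normalized to `[0, 1]`.
#'
#' @param rf An `rf_frame`.
#' @param dynamic_range_db Dynamic range in dB (default 50).
#' @return A `bmode_image`: matrix in `[0, 1]` (axial sample x line) with
#'   grid attributes.
#' @export
bmode <- function(rf, dynamic_range_db = 50) {
  stopifnot(inherits(rf, "rf_frame"), dynamic_range_db > 0)
  env <- rf_envelope(rf$samples)
  mx <- max(env)
  if (mx == 0) {
    img <- env
  } else {
    db <- 20 * log10(pmax(env / mx, 10^(-dynamic_range_db / 20 - 1)))
    img <- pmax(db + dynamic_range_db, 0) / dynamic_range_db
  }
  structure(img, axial_step_um = rf$axial_step_um,
            line_pitch_um = rf$line_pitch_um, x0_mm = rf$x0_mm,
            class = c("bmode_image", "matrix", "array"))
}

#' Write/read an RF frame (binary samples + JSON sidecar)
#'
#' Samples are stored as little-endian doubles in column order; the sidecar
#' `<path>.json` records the array shape, grid metadata and transducer.
#'
#' @param rf An `rf_frame`.
#' @param path Path for the binary sample file.
#' @export
write_rf <- function(rf, path) {
  con <- file(path, "wb")
  writeBin(as.vector(rf$samples), con, size = 8, endian = "little")
  close(con)
  meta <- list(n_samples = nrow(rf$samples), n_lines = ncol(rf$samples),
               axial_step_um = rf$axial_step_um, line_pitch_um = rf$line_pitch_um,
               x0_mm = rf$x0_mm,
               transducer = unclass(rf$transducer))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rf
#' @export
read_rf <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  v <- readBin(con, "double", n = meta$n_samples * meta$n_lines, size = 8,
               endian = "little")
  close(con)
  tr <- do.call(transducer_spec, meta$transducer[
    c("center_frequency", "sampling_frequency", "line_pitch",
      "pulse_bandwidth", "speed_of_sound", "lateral_beam_sigma")])
  structure(list(samples = matrix(v, meta$n_samples, meta$n_lines),
                 axial_step_um = meta$axial_step_um,
                 line_pitch_um = meta$line_pitch_um, x0_mm = meta$x0_mm,
                 transducer = tr),
            class = "rf_frame")
}
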