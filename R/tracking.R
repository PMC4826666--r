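#' Coarse-to-fine kernel schedule for RF displacement tracking
#'
#' The default three-iteration schedule: a large coarse kernel
#' (3850 x 715 um template, 7700 x 935 um search, 50% axial / 92% lateral
#' overlap), followed by two fine iterations with 60 x 715 um templates and
#' 120 x 935 um search windows at 75% / 92% overlap; the final iteration
#' additionally performs local alignment of the data and parabolic
#' subsample interpolation of the correlation peak. The final-iteration
#' axial grid step is 60 x (1 - 0.75) = 15 um.
#'
#' @return A `kernel_schedule` tibble with one row per iteration.
#' @export
default_schedule <- function() {
  sched <- tibble::tibble(
    iteration = 1:3,
    template_ax_um = c(3850, 60, 60), template_lat_um = c(715, 715, 715),
    search_ax_um = c(7700, 120, 120), search_lat_um = c(935, 935, 935),
    overlap_ax = c(0.50, 0.75, 0.75), overlap_lat = c(0.92, 0.92, 0.92),
    local_align = c(FALSE, FALSE, TRUE), subsample = c(FALSE, FALSE, TRUE))
  structure(sched, class = c("kernel_schedule", class(sched)))
}

#' @rdname default_schedule
#' @param template_ax_um,template_lat_um,search_ax_um,search_lat_um,overlap_ax,overlap_lat,local_align,subsample
#'   Per-iteration vectors (recycled) defining a custom schedule.
#' @export
kernel_schedule <- function(template_ax_um, template_lat_um, search_ax_um,
                            search_lat_um, overlap_ax, overlap_lat,
                            local_align = FALSE, subsample = FALSE) {
  sched <- tibble::tibble(
    iteration = seq_along(template_ax_um),
    template_ax_um = template_ax_um, template_lat_um = template_lat_um,
    search_ax_um = search_ax_um, search_lat_um = search_lat_um,
    overlap_ax = overlap_ax, overlap_lat = overlap_lat,
    local_align = local_align, subsample = subsample)
  stopifnot(all(sched$search_ax_um >= sched$template_ax_um),
            all(sched$search_lat_um >= sched$template_lat_um),
            all(sched$overlap_ax >= 0 & sched$overlap_ax < 1),
            all(sched$overlap_lat >= 0 & sched$overlap_lat < 1))
  structure(sched, class = c("kernel_schedule", class(sched)))
}

# physical kernel sizes -> integer sample counts: floor to the nearest even
# count, axial counts at least 8 samples, lateral at least 2 lines; search
# strictly larger than template
schedule_in_samples <- function(schedule, rf) {
  even_floor <- function(x, lo) pmax(2L * (as.integer(x) %/% 2L), lo)
  ta <- even_floor(schedule$template_ax_um / rf$axial_step_um, 8L)
  tl <- even_floor(schedule$template_lat_um / rf$line_pitch_um, 2L)
  sa <- pmax(even_floor(schedule$search_ax_um / rf$axial_step_um, 8L), ta + 2L)
  sl <- pmax(even_floor(schedule$search_lat_um / rf$line_pitch_um, 2L), tl + 2L)
  step_ax <- pmax(1L, as.integer(round(ta * (1 - schedule$overlap_ax))))
  step_lat <- pmax(1L, as.integer(round(tl * (1 - schedule$overlap_lat))))
  tibble::tibble(ta = ta, tl = tl, sa = sa, sl = sl,
                 step_ax = step_ax, step_lat = step_lat,
                 local_align = schedule$local_align,
                 subsample = schedule$subsample)
}

#' Normalized cross-correlation surface
#'
#' Zero-mean normalized cross-correlation of a template against every
#' fully-overlapping integer-lag position inside a larger search region.
#'
#' @param template,search Numeric matrices (axial sample x line); `search`
#'   must be at least as large as `template` in both axes and strictly
#'   larger in at least one.
#' @return Matrix of correlation values in `[-1, 1]`, dimension
#'   `(nrow(search) - nrow(template) + 1) x (ncol(search) - ncol(template) + 1)`.
#' @export
ncc_surface <- function(template, search) {
  template <- as.matrix(template); search <- as.matrix(search)
  if (nrow(search) < nrow(template) || ncol(search) < ncol(template) ||
      (nrow(search) == nrow(template) && ncol(search) == ncol(template)))
    stop("search must be strictly larger than template in at least one axis",
         call. = FALSE)
  if (stats::var(as.vector(template)) == 0)
    stop("flat signal region: zero-variance template", call. = FALSE)
  big <- length(template) * (nrow(search) - nrow(template) + 1) > 2e6
  .ncc_surface_core(template, search, big)
}

#' Parabolic subsample interpolation of a correlation peak
#'
#' Fits a parabola through the correlation values at the peak and its two
#' neighbours: `delta = (c_minus - c_plus) / (2 (c_minus - 2 c_peak + c_plus))`,
#' clamped to `[-0.5, 0.5]`.
#'
#' @param c_minus,c_peak,c_plus Correlation at lag -1, the peak lag, and +1.
#' @return Fractional lag offset in `[-0.5, 0.5]`; a degenerate (flat)
#'   triple yields 0 with a warning.
#' @export
parabolic_subsample <- function(c_minus, c_peak, c_plus) {
  stopifnot(length(c_minus) == length(c_peak), length(c_plus) == length(c_peak))
  if (any(c_peak < pmax(c_minus, c_plus) - 1e-12))
    stop("c_peak must be the largest of the triple", call. = FALSE)
  den <- c_minus - 2 * c_peak + c_plus
  flat <- abs(den) < 1e-12
  if (any(flat))
    warning("flat correlation triple; subsample offset set to 0")
  delta <- ifelse(flat, 0, (c_minus - c_plus) / (2 * den))
  pmin(pmax(delta, -0.5), 0.5)
}

new_displacement_map <- function(ax_um, lat_um, corr, cy, cx, rf) {
  structure(list(
    axial_um = ax_um, lateral_um = lat_um, corr = corr,
    cy = cy, cx = cx,
    y_mm = cy * rf$axial_step_um / 1000,
    x_mm = rf$x0_mm + cx * rf$line_pitch_um / 1000,
    axial_step_um = NA_real_, lateral_step_um = NA_real_,
    sample_step_um = rf$axial_step_um, line_pitch_um = rf$line_pitch_um),
    class = "displacement_map")
}

#' 5 x 5 median filtering of a displacement map
#'
#' Component-wise median filter with reflect padding at the edges, applied
#' after each tracking iteration to suppress outlying displacement
#' estimates.
#'
#' @param map A `displacement_map`.
#' @param size Odd kernel size (default 5).
#' @return The filtered `displacement_map`.
#' @export
median_filter_displacements <- function(map, size = 5L) {
  stopifnot(inherits(map, "displacement_map"), size %% 2L == 1L)
  if (nrow(map$axial_um) < size || ncol(map$axial_um) < size)
    stop("displacement map smaller than the median filter kernel", call. = FALSE)
  map$axial_um <- .median_filter2(map$axial_um, size)
  map$lateral_um <- .median_filter2(map$lateral_um, size)
  map
}

# clamped bilinear interpolation of matrix Z on grid (y, x) at query points
interp2_clamped <- function(y, x, Z, yq, xq) {
  ny <- length(y); nx <- length(x)
  iy <- findInterval(yq, y, all.inside = TRUE)
  ix <- findInterval(xq, x, all.inside = TRUE)
  fy <- (yq - y[iy]) / (y[iy + 1L] - y[iy])
  fx <- (xq - x[ix]) / (x[ix + 1L] - x[ix])
  fy <- pmin(pmax(fy, 0), 1); fx <- pmin(pmax(fx, 0), 1)
  Z[cbind(iy, ix)] * (1 - fy) * (1 - fx) +
    Z[cbind(iy + 1L, ix)] * fy * (1 - fx) +
    Z[cbind(iy, ix + 1L)] * (1 - fy) * fx +
    Z[cbind(iy + 1L, ix + 1L)] * fy * fx
}

#' Sample a displacement map at arbitrary positions
#'
#' Bilinear interpolation of both displacement components; positions outside
#' the map grid are clamped to the nearest grid cell.
#'
#' @param map A `displacement_map`.
#' @param y_mm,x_mm Query coordinates (axial and lateral, mm).
#' @return Matrix with columns `axial_um`, `lateral_um`.
#' @export
sample_displacement_map <- function(map, y_mm, x_mm) {
  cbind(axial_um = interp2_clamped(map$y_mm, map$x_mm, map$axial_um, y_mm, x_mm),
        lateral_um = interp2_clamped(map$y_mm, map$x_mm, map$lateral_um, y_mm, x_mm))
}

#' Estimate a displacement field between two RF frames
#'
#' The three-iteration coarse-to-fine 2D cross-correlation estimator:
#' iteration 1 finds a coarse integer-lag displacement with large kernels;
#' iteration 2 refines it on the fine grid, using the coarse map to offset
#' the search window; iteration 3 locally aligns the post frame by the
#' current estimate (fractional bilinear warp) and adds parabolic subsample
#' interpolation of the correlation peak. A 5 x 5 median filter is applied
#' to the displacement field after each iteration.
#'
#' @param rf_pre,rf_post `rf_frame` objects sharing shape and transducer.
#' @param schedule A `kernel_schedule`; default `default_schedule()`.
#' @param roi Optional list with `y_mm = c(min, max)` and/or
#'   `x_mm = c(min, max)` restricting the estimation grid.
#' @param median_after_subsample Apply the final median filter after the
#'   subsample refinement (default) or skip it in the last iteration.
#' @return A `displacement_map` with `axial_um` and `lateral_um` matrices on
#'   the final-iteration grid, grid coordinates (`y_mm`, `x_mm`), grid steps
#'   in um, and the peak correlation per kernel.
#' @export
estimate_displacement <- function(rf_pre, rf_post, schedule = default_schedule(),
                                  roi = NULL, median_after_subsample = TRUE) {
  stopifnot(inherits(rf_pre, "rf_frame"), inherits(rf_post, "rf_frame"),
            all(dim(rf_pre$samples) == dim(rf_post$samples)))
  if (all(rf_pre$samples == 0) || all(rf_post$samples == 0))
    stop("all-zero RF frame", call. = FALSE)
  ss <- schedule_in_samples(schedule, rf_pre)
  n_it <- nrow(ss)
  nsamp <- nrow(rf_pre$samples); nlin <- ncol(rf_pre$samples)

  grid_centers <- function(t_half, step, n, lo, hi) {
    lo <- max(lo, t_half); hi <- min(hi, n - 1L - t_half)
    if (hi < lo) stop("insufficient frame extent for the kernel schedule", call. = FALSE)
    seq(lo, hi, by = step)
  }
  ylim <- c(0L, nsamp - 1L); xlim <- c(0L, nlin - 1L)
  if (!is.null(roi$y_mm))
    ylim <- as.integer(round(roi$y_mm * 1000 / rf_pre$axial_step_um))
  if (!is.null(roi$x_mm))
    xlim <- as.integer(round((roi$x_mm - rf_pre$x0_mm) * 1000 / rf_pre$line_pitch_um))

  est <- NULL; prev_cy <- NULL; prev_cx <- NULL
  for (it in seq_len(n_it)) {
    cy <- grid_centers(ss$ta[it] %/% 2L, ss$step_ax[it], nsamp, ylim[1], ylim[2])
    cx <- grid_centers(ss$tl[it] %/% 2L, ss$step_lat[it], nlin, xlim[1], xlim[2])
    if (is.null(est)) {
      init_ax <- matrix(0, length(cy), length(cx))
      init_lat <- matrix(0, length(cy), length(cx))
    } else {
      qy <- rep(cy, times = length(cx)); qx <- rep(cx, each = length(cy))
      init_ax <- matrix(interp2_clamped(prev_cy, prev_cx, est$ax, qy, qx),
                        length(cy), length(cx))
      init_lat <- matrix(interp2_clamped(prev_cy, prev_cx, est$lat, qy, qx),
                         length(cy), length(cx))
    }
    mode <- if (ss$local_align[it] || ss$subsample[it]) 3L else 1L
    big <- as.double(ss$ta[it]) * ss$tl[it] *
      (ss$sa[it] - ss$ta[it] + 1) * (ss$sl[it] - ss$tl[it] + 1) > 2e6
    res <- .track_grid(rf_pre$samples, rf_post$samples,
                       as.integer(cy), as.integer(cx), init_ax, init_lat,
                       ss$ta[it], ss$tl[it], ss$sa[it], ss$sl[it], mode, big)
    res$ax[!is.finite(res$ax)] <- 0
    res$lat[!is.finite(res$lat)] <- 0
    do_median <- nrow(res$ax) >= 5L && ncol(res$ax) >= 5L &&
      (it < n_it || median_after_subsample)
    if (do_median) {
      res$ax <- .median_filter2(res$ax, 5L)
      res$lat <- .median_filter2(res$lat, 5L)
    }
    est <- res; prev_cy <- cy; prev_cx <- cx
  }

  map <- new_displacement_map(est$ax * rf_pre$axial_step_um,
                              est$lat * rf_pre$line_pitch_um,
                              est$corr, prev_cy, prev_cx, rf_pre)
  map$axial_step_um <- ss$step_ax[n_it] * rf_pre$axial_step_um
  map$lateral_step_um <- ss$step_lat[n_it] * rf_pre$line_pitch_um
  map
}

#' Cumulative tracking through a pressure sequence
#'
#' Tracks each consecutive RF frame pair and composes the incremental
#' estimates into cumulative displacement fields expressed in the frame of
#' the first (reference) acquisition:
#' `U[k+1](X) = U[k](X) + u_k(X + U[k](X))` (Lagrangian accumulation, with
#' the incremental Eulerian map sampled bilinearly at the advected
#' positions).
#'
#' @param frames List of `rf_frame` objects, ordered by pressure level.
#' @param schedule A `kernel_schedule`.
#' @param roi As in [estimate_displacement()].
#' @return List of cumulative `displacement_map`s, one per frame after the
#'   first, on the reference grid.
#' @export
track_sequence <- function(frames, schedule = default_schedule(), roi = NULL) {
  stopifnot(length(frames) >= 2L)
  ref_map <- NULL
  out <- vector("list", length(frames) - 1L)
  for (k in seq_len(length(frames) - 1L)) {
    inc <- estimate_displacement(frames[[k]], frames[[k + 1L]], schedule, roi)
    if (is.null(ref_map)) {
      ref_map <- inc
    } else {
      ny <- length(ref_map$y_mm); nx <- length(ref_map$x_mm)
      yq <- rep(ref_map$y_mm, times = nx) + as.vector(ref_map$axial_um) / 1000
      xq <- rep(ref_map$x_mm, each = ny) + as.vector(ref_map$lateral_um) / 1000
      u <- sample_displacement_map(inc, yq, xq)
      ref_map$axial_um <- ref_map$axial_um + matrix(u[, 1], ny, nx)
      ref_map$lateral_um <- ref_map$lateral_um + matrix(u[, 2], ny, nx)
      cq <- interp2_clamped(inc$y_mm, inc$x_mm, inc$corr, yq, xq)
      ref_map$corr <- pmin(ref_map$corr, matrix(cq, ny, nx))
    }
    out[[k]] <- ref_map
  }
  out
}

#' Write/read a displacement map (flat CSV + JSON header)
#'
#' CSV columns: `x_mm`, `y_mm`, `axial_um`, `lateral_um`, `corr`; the JSON
#' sidecar `<path>.json` records the grid shape and steps.
#'
#' @param map A `displacement_map`.
#' @param path CSV file path.
#' @export
write_displacement_map <- function(map, path) {
  ny <- length(map$y_mm); nx <- length(map$x_mm)
  df <- data.frame(x_mm = rep(map$x_mm, each = ny),
                   y_mm = rep(map$y_mm, times = nx),
                   axial_um = as.vector(map$axial_um),
                   lateral_um = as.vector(map$lateral_um),
                   corr = as.vector(map$corr))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(ny = ny, nx = nx,
                            axial_step_um = map$axial_step_um,
                            lateral_step_um = map$lateral_step_um,
                            sample_step_um = map$sample_step_um,
                            line_pitch_um = map$line_pitch_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_displacement_map
#' @export
read_displacement_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  ny <- meta$ny; nx <- meta$nx
  map <- structure(list(
    axial_um = matrix(df$axial_um, ny, nx),
    lateral_um = matrix(df$lateral_um, ny, nx),
    corr = matrix(df$corr, ny, nx),
    cy = NULL, cx = NULL,
    y_mm = df$y_mm[seq_len(ny)], x_mm = df$x_mm[seq(1L, nrow(df), by = ny)],
    axial_step_um = meta$axial_step_um, lateral_step_um = meta$lateral_step_um,
    sample_step_um = meta$sample_step_um, line_pitch_um = meta$line_pitch_um),
    class = "displacement_map")
  map
}
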