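#' Synthetic atherosclerotic plaque cross-section phantom
#'
#' Generates a layered 2D vessel cross-section: lumen, diseased intima,
#' intima--media interface (IMA), and the fused media+adventitia "wall",
#' optionally with a calcified inclusion adjacent to the IMA. Contours are
#' explicit closed polylines in mm so that traced (measured) contours and
#' synthetic ones share one representation. The coordinate convention is
#' x = lateral, y = axial (ultrasound beam direction, increasing away from
#' the transducer), origin at the transducer face center.
#'
#' Intima thickening follows a cosine-modulated radial profile
#' `t(theta) = t_max * ((1 - ecc) + ecc * (1 + cos(theta - theta0)) / 2)`,
#' a smooth single-parameter family spanning concentric (`eccentricity = 0`)
#' to fully one-sided eccentric (`eccentricity = 1`) plaques. A small
#' thickness floor (2% of `intima_thickness_max`) keeps contours strictly
#' nested at full eccentricity.
#'
#' @param lumen_radius Lumen radius in mm (> 0).
#' @param wall_thickness Media+adventitia thickness in mm (> 0).
#' @param intima_thickness_max Maximum intima thickness in mm (> 0).
#' @param eccentricity In `[0, 1]`; 0 gives a concentric plaque.
#' @param calcium_spec Optional list with `size` (major diameter, mm),
#'   `angle` (degrees, position around the IMA), and optionally `aspect`
#'   (radial/tangential axis ratio, default 0.6).
#' @param n_vertices Number of vertices per layer contour (>= 16).
#' @param center Vessel center `c(x, y)` in mm; default places the vessel
#'   6 mm below the transducer face.
#' @param thick_angle_deg Angular position (degrees) of the thickest intima;
#'   default -90 (facing the transducer, as specimens were positioned).
#' @param seed Optional RNG seed (reserved for randomized contour roughness;
#'   the default family is deterministic).
#' @return A `plaque_geometry` object: list with closed counter-clockwise
#'   contours `lumen`, `ima`, `outer` (tibbles with `x`, `y` in mm),
#'   `calcium` (list of tibbles), `eccentric` flag and `center`.
#' @examples
#' geom <- make_vessel_geometry(1.5, 0.5, 1.25, eccentricity = 0)
#' polygon_area(geom$outer) > polygon_area(geom$ima)
#' @export
make_vessel_geometry <- function(lumen_radius, wall_thickness, intima_thickness_max,
                                 eccentricity = 0, calcium_spec = NULL,
                                 n_vertices = 96L, center = c(0, 6),
                                 thick_angle_deg = -90, seed = NULL) {
  stopifnot(lumen_radius > 0, wall_thickness > 0, intima_thickness_max > 0,
            eccentricity >= 0, eccentricity <= 1, n_vertices >= 16L)
  if (!is.null(seed)) set.seed(seed)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  th0 <- thick_angle_deg * pi / 180
  t_int <- intima_thickness_max *
    ((1 - eccentricity) + eccentricity * (1 + cos(theta - th0)) / 2)
  t_int <- pmax(t_int, 0.02 * intima_thickness_max)
  r_lum <- rep(lumen_radius, n_vertices)
  r_ima <- r_lum + t_int
  r_out <- r_ima + wall_thickness

  ring <- function(r) tibble::tibble(x = center[1] + r * cos(theta),
                                     y = center[2] + r * sin(theta))
  geom <- structure(list(
    lumen = ring(r_lum), ima = ring(r_ima), outer = ring(r_out),
    calcium = list(), eccentric = eccentricity > 0, center = center,
    units = "mm"
  ), class = "plaque_geometry")

  if (!is.null(calcium_spec)) {
    size <- calcium_spec$size
    ang <- calcium_spec$angle * pi / 180
    aspect <- calcium_spec$aspect %||% 0.6
    stopifnot(size > 0)
    r_c <- stats::approx(c(theta, 2 * pi), c(r_ima, r_ima[1]),
                         xout = ang %% (2 * pi))$y
    cc <- center + r_c * c(cos(ang), sin(ang))
    phi <- seq(0, 2 * pi, length.out = 33L)[-33L]
    # tangential major axis, radial minor axis, rotated to the local frame
    a <- size / 2; b <- aspect * size / 2
    ex <- a * cos(phi); ey <- b * sin(phi)
    rot <- ang + pi / 2  # tangential direction
    cal <- tibble::tibble(
      x = cc[1] + ex * cos(rot) - ey * sin(rot),
      y = cc[2] + ex * sin(rot) + ey * cos(rot))
    geom$calcium <- list(ensure_ccw(cal))
  }
  validate_geometry(geom)
}

#' Validate a plaque geometry against its structural invariants
#'
#' Checks that all contours are simple, counter-clockwise, strictly nested
#' (`lumen` in `ima` in `outer`), and that calcifications lie in the tissue
#' between lumen and outer wall.
#'
#' @param geom A `plaque_geometry`.
#' @return The (orientation-normalized) geometry, invisibly on success;
#'   errors with an informative message for infeasible geometry.
#' @export
validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "plaque_geometry"))
  for (nm in c("lumen", "ima", "outer")) {
    geom[[nm]] <- ensure_ccw(geom[[nm]])
    if (!polygon_is_simple(geom[[nm]]))
      stop("infeasible geometry: ", nm, " contour is self-intersecting", call. = FALSE)
  }
  if (!polygon_inside(geom$lumen, geom$ima))
    stop("infeasible geometry: lumen contour not strictly inside IMA contour", call. = FALSE)
  if (!polygon_inside(geom$ima, geom$outer))
    stop("infeasible geometry: IMA contour not strictly inside outer contour", call. = FALSE)
  if (length(geom$calcium)) {
    geom$calcium <- lapply(geom$calcium, ensure_ccw)
    for (cal in geom$calcium) {
      if (!polygon_is_simple(cal))
        stop("infeasible geometry: calcium contour is self-intersecting", call. = FALSE)
      if (!polygon_inside(cal, geom$outer))
        stop("infeasible geometry: calcium region outside the vessel wall", call. = FALSE)
      if (any(points_in_polygon(geom$lumen$x, geom$lumen$y, cal)) ||
          all(points_in_polygon(cal$x, cal$y, geom$lumen)))
        stop("infeasible geometry: calcium region overlaps the lumen", call. = FALSE)
    }
  }
  invisible(geom)
}

#' Radial layer thickness of a geometry along a direction
#'
#' Ray-casting utility: distance between two contours along the ray from the
#' vessel center at angle `theta_deg`.
#'
#' @param geom A `plaque_geometry`.
#' @param theta_deg Angles in degrees.
#' @param from,to Contour names among `"lumen"`, `"ima"`, `"outer"`.
#' @return Numeric vector of thicknesses (mm).
#' @export
layer_thickness <- function(geom, theta_deg, from = "lumen", to = "ima") {
  th <- theta_deg * pi / 180
  ray_polygon_radius(geom[[to]], geom$center, th) -
    ray_polygon_radius(geom[[from]], geom$center, th)
}

#' Material map for the plaque model
#'
#' Shear moduli (kPa) of the Neo-Hookean strain energy `W = C (I1 - 3)` per
#' region. The media and adventitia share one modulus (`C_wall`); calcium is
#' quasi-rigid by default; the buffer is the very soft compressible embedding
#' layer used to suppress rigid-body motion.
#'
#' @param C_wall,C_intima Shear moduli in kPa (> 0).
#' @param C_calcium Calcium shear modulus, default `1e5` kPa.
#' @param C_buffer Buffer shear modulus, default 0.01 kPa; must be softer
#'   than both tissue components.
#' @return A `material_map` list.
#' @export
material_map <- function(C_wall, C_intima, C_calcium = 1e5, C_buffer = 0.01) {
  C_wall <- unname(as.numeric(C_wall))[1]
  C_intima <- unname(as.numeric(C_intima))[1]
  C_calcium <- unname(as.numeric(C_calcium))[1]
  C_buffer <- unname(as.numeric(C_buffer))[1]
  stopifnot(C_wall > 0, C_intima > 0, C_calcium > 0, C_buffer > 0)
  if (C_calcium < max(C_wall, C_intima))
    stop("C_calcium must be at least as stiff as the tissue components", call. = FALSE)
  if (C_buffer >= min(C_wall, C_intima))
    stop("C_buffer must be softer than both tissue components", call. = FALSE)
  structure(list(C_wall = C_wall, C_intima = C_intima,
                 C_calcium = C_calcium, C_buffer = C_buffer),
            class = "material_map")
}

#' Random ultrasound scatterer field for a plaque phantom
#'
#' Draws a Poisson number of scatterers uniformly over the vessel
#' cross-section (outer contour dilated by `margin`), with i.i.d. standard
#' normal reflectivities. Fully developed speckle requires roughly >= 10
#' scatterers per ultrasound resolution cell; with the default transducer
#' that corresponds to a density of about 2500 per mm^2.
#'
#' @param geometry A `plaque_geometry`.
#' @param density Scatterers per mm^2 (> 0).
#' @param seed RNG seed (field is reproducible given the seed).
#' @param margin Radial dilation of the outer contour in mm.
#' @param exclude_lumen Drop scatterers inside the lumen (anechoic saline).
#' @return A `scatterer_field`: tibble with columns `x_mm`, `y_mm`,
#'   `amplitude`; attributes `seed` and `density`.
#' @export
make_scatterers <- function(geometry, density, seed = 1L, margin = 0.3,
                            exclude_lumen = FALSE) {
  stopifnot(inherits(geometry, "plaque_geometry"))
  if (!is.numeric(density) || density <= 0)
    stop("empty speckle: scatterer density must be > 0", call. = FALSE)
  ctr <- geometry$center
  dil <- geometry$outer
  d <- sqrt((dil$x - ctr[1])^2 + (dil$y - ctr[2])^2)
  dil$x <- ctr[1] + (dil$x - ctr[1]) * (d + margin) / d
  dil$y <- ctr[2] + (dil$y - ctr[2]) * (d + margin) / d
  area <- polygon_area(dil)
  if (exclude_lumen) area <- area - polygon_area(geometry$lumen)

  set.seed(seed)
  n <- stats::rpois(1L, density * area)
  bb <- c(range(dil$x), range(dil$y))
  xs <- ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 100L)
    cx <- stats::runif(m, bb[1], bb[2]); cy <- stats::runif(m, bb[3], bb[4])
    keep <- points_in_polygon(cx, cy, dil)
    if (exclude_lumen) keep <- keep & !points_in_polygon(cx, cy, geometry$lumen)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  out <- tibble::tibble(x_mm = xs[seq_len(n)], y_mm = ys[seq_len(n)],
                        amplitude = stats::rnorm(n))
  structure(out, seed = seed, density = density,
            class = c("scatterer_field", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
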