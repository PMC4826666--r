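#' Read and write plaque geometry files
#'
#' Geometry files are JSON with named contour arrays in mm:
#' ```json
#' {
#'   "units": "mm",
#'   "center": [0, 6],
#'   "eccentric": false,
#'   "contours": {"lumen": [[x, y], ...], "ima": [...], "outer": [...]},
#'   "calcium": [ [[x, y], ...], ... ]
#' }
#' ```
#' Vertex coordinates round-trip losslessly (written with full double
#' precision). Files describing open or self-intersecting contours, or a
#' broken containment chain, are rejected on read.
#'
#' @param geom A `plaque_geometry`.
#' @param path File path.
#' @return `read_geometry` returns a validated `plaque_geometry`;
#'   `write_geometry` returns `path` invisibly.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "plaque_geometry"))
  as_arr <- function(df) unname(as.matrix(df[, c("x", "y")]))
  obj <- list(
    units = "mm",
    center = geom$center,
    eccentric = isTRUE(geom$eccentric),
    contours = list(lumen = as_arr(geom$lumen), ima = as_arr(geom$ima),
                    outer = as_arr(geom$outer)),
    calcium = lapply(geom$calcium, as_arr)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed geometry file: ",
                                           conditionMessage(e), call. = FALSE))
  need <- c("lumen", "ima", "outer")
  if (is.null(obj$contours) || !all(need %in% names(obj$contours)))
    stop("malformed geometry file: missing contours ",
         paste(setdiff(need, names(obj$contours)), collapse = ", "), call. = FALSE)
  as_df <- function(m, nm) {
    m <- as.matrix(m)
    if (!is.numeric(m) || ncol(m) != 2L || nrow(m) < 3L || anyNA(m))
      stop("malformed geometry file: contour ", nm,
           " is not an n x 2 numeric array", call. = FALSE)
    # an explicitly closed polyline (first == last vertex) is normalized;
    # anything else must be an implicitly closed ring
    if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    tibble::tibble(x = m[, 1], y = m[, 2])
  }
  cal <- obj$calcium
  if (is.null(cal) || length(cal) == 0L) cal <- list()
  if (is.array(cal) && length(dim(cal)) == 3L)  # simplified list of rings
    cal <- lapply(seq_len(dim(cal)[1L]), function(i) cal[i, , ])
  if (is.matrix(cal)) cal <- list(cal)
  geom <- structure(list(
    lumen = as_df(obj$contours$lumen, "lumen"),
    ima = as_df(obj$contours$ima, "ima"),
    outer = as_df(obj$contours$outer, "outer"),
    calcium = lapply(seq_along(cal), function(i) as_df(cal[[i]], paste0("calcium[", i, "]"))),
    eccentric = isTRUE(obj$eccentric),
    center = if (!is.null(obj$center)) as.numeric(obj$center)
             else polygon_centroid(as_df(obj$contours$lumen, "lumen")),
    units = "mm"
  ), class = "plaque_geometry")
  validate_geometry(geom)
  geom
}

#' Write/read a scatterer field as CSV
#'
#' Plain CSV with columns `x_mm`, `y_mm`, `amplitude`.
#'
#' @param field A `scatterer_field`.
#' @param path File path.
#' @export
write_scatterers <- function(field, path) {
  utils::write.csv(as.data.frame(field)[, c("x_mm", "y_mm", "amplitude")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scatterers
#' @export
read_scatterers <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x_mm", "y_mm", "amplitude") %in% names(df)))
  out <- tibble::as_tibble(df[, c("x_mm", "y_mm", "amplitude")])
  structure(out, class = c("scatterer_field", class(out)))
}
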