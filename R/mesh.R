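#' Mesh a plaque cross-section for plane-strain analysis
#'
#' Builds a structured radial--angular triangulation of the layered vessel
#' cross-section with six-node (quadratic) triangles, plus a soft buffer ring
#' appended outside the outer contour whose outer border carries the
#' zero-displacement boundary condition. Layer interfaces (lumen, IMA, outer
#' wall) are mesh-conforming by construction; calcium boundaries are
#' conformed by snapping the nearest interior radial nodes onto the calcium
#' contour along each crossing ray, and elements are labelled by centroid
#' containment. Contours must be star-shaped about the lumen center
#' (meshing fails with an error otherwise), which every generated phantom
#' satisfies.
#'
#' @param geometry A `plaque_geometry`.
#' @param target_edge Target element edge length in mm (> 0).
#' @param buffer_thickness Buffer ring thickness in mm (> 0), default 2.
#' @return A `plaque_mesh`: list with `nodes` (all quadratic nodes, mm),
#'   `n_corner`, `tri` (m x 6 connectivity, corners 1:3 counter-clockwise,
#'   midsides 4:6 opposite), `region` factor per element in
#'   `wall`, `intima`, `calcium`, `buffer`, `lumen_edges` (ordered e x 3
#'   node triples on the lumen), and `fixed_nodes` (outer buffer border).
#' @export
mesh_geometry <- function(geometry, target_edge = 0.15, buffer_thickness = 2) {
  stopifnot(inherits(geometry, "plaque_geometry"),
            target_edge > 0, buffer_thickness > 0)
  ctr <- geometry$center

  r_mid_est <- mean(sqrt((geometry$ima$x - ctr[1])^2 + (geometry$ima$y - ctr[2])^2))
  n_theta <- max(24L, 2L * round(pi * r_mid_est / target_edge))
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

  r_lum <- ray_polygon_radius(geometry$lumen, ctr, theta)
  r_ima <- ray_polygon_radius(geometry$ima, ctr, theta)
  r_out <- ray_polygon_radius(geometry$outer, ctr, theta)
  if (any(r_ima <= r_lum) || any(r_out <= r_ima))
    stop("meshing failure: degenerate layer ordering along a ray", call. = FALSE)

  n1 <- max(2L, round(mean(r_ima - r_lum) / target_edge))
  n2 <- max(2L, round(mean(r_out - r_ima) / target_edge))
  nb <- max(2L, round(buffer_thickness / (2 * target_edge)))
  nr <- n1 + n2 + nb + 1L  # radial corner rows

  # radii matrix: nr rows x n_theta columns
  rad <- matrix(0, nr, n_theta)
  for (j in seq_len(n_theta)) {
    rad[, j] <- c(
      seq(r_lum[j], r_ima[j], length.out = n1 + 1L),
      seq(r_ima[j], r_out[j], length.out = n2 + 1L)[-1L],
      seq(r_out[j], r_out[j] + buffer_thickness, length.out = nb + 1L)[-1L])
  }

  # conform interior rows to calcium boundaries by radial snapping
  interface_rows <- c(1L, n1 + 1L, n1 + n2 + 1L, nr)
  for (cal in geometry$calcium) {
    for (j in seq_len(n_theta)) {
      hits <- sort(ray_polygon_hits(cal, ctr, c(cos(theta[j]), sin(theta[j]))))
      if (length(hits) < 2L) next
      for (rt in c(hits[1L], hits[length(hits)])) {
        k <- which.min(abs(rad[, j] - rt))
        if (k %in% interface_rows) next
        lo <- rad[k - 1L, j]; hi <- rad[k + 1L, j]
        m <- 0.2 * min(rt - lo, hi - rt)
        if (rt > lo + 0.1 * (rad[k, j] - lo) && rt < hi - 0.1 * (hi - rad[k, j]) && m > 0)
          rad[k, j] <- rt
      }
    }
  }

  corner_id <- function(j, k) (j - 1L) * nr + k  # j in 1..n_theta (wraps), k in 1..nr
  jj <- rep(seq_len(n_theta), each = nr)
  kk <- rep(seq_len(nr), n_theta)
  corners <- cbind(ctr[1] + rad[cbind(kk, jj)] * cos(theta[jj]),
                   ctr[2] + rad[cbind(kk, jj)] * sin(theta[jj]))
  n_corner <- nrow(corners)

  # quads (j,k)-(j+1,k)-(j+1,k+1)-(j,k+1), split into two CCW triangles
  tri3 <- matrix(0L, 2L * n_theta * (nr - 1L), 3L)
  row_of_elem <- integer(nrow(tri3))
  e <- 0L
  for (j in seq_len(n_theta)) {
    jn <- if (j == n_theta) 1L else j + 1L
    for (k in seq_len(nr - 1L)) {
      a <- corner_id(j, k); b <- corner_id(jn, k)
      cc <- corner_id(jn, k + 1L); d <- corner_id(j, k + 1L)
      tri3[e + 1L, ] <- c(a, cc, b)
      tri3[e + 2L, ] <- c(a, d, cc)
      row_of_elem[e + 1L] <- k; row_of_elem[e + 2L] <- k
      e <- e + 2L
    }
  }

  # quadratic midside nodes on unique edges
  ed <- rbind(tri3[, c(1L, 2L)], tri3[, c(2L, 3L)], tri3[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  uk <- !duplicated(key)
  edge_id <- match(key, key[uk])
  uedges <- ed[uk, , drop = FALSE]
  mids <- (corners[uedges[, 1], , drop = FALSE] + corners[uedges[, 2], , drop = FALSE]) / 2
  nodes <- rbind(corners, mids)
  m <- nrow(tri3)
  tri <- cbind(tri3,
               n_corner + edge_id[seq_len(m)],
               n_corner + edge_id[m + seq_len(m)],
               n_corner + edge_id[2L * m + seq_len(m)])

  # element region labels from radial row, calcium by centroid override
  cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  cy <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  region <- ifelse(row_of_elem <= n1, "intima",
                   ifelse(row_of_elem <= n1 + n2, "wall", "buffer"))
  # calcium label by area-overlap fraction (first-order errors cancel,
  # unlike centroid classification)
  for (cal in geometry$calcium) {
    bb <- c(range(cal$x), range(cal$y))
    near <- which(cx >= bb[1] - 0.3 & cx <= bb[2] + 0.3 &
                    cy >= bb[3] - 0.3 & cy <= bb[4] + 0.3 & region != "buffer")
    for (e in near) {
      tri_m <- nodes[tri[e, 1:3], , drop = FALSE]
      a_tri <- abs(polygon_area(data.frame(x = tri_m[, 1], y = tri_m[, 2])))
      ov <- clip_polygon_convex(tri_m, cal)
      if (nrow(ov) >= 3L) {
        a_ov <- abs(polygon_area(data.frame(x = ov[, 1], y = ov[, 2])))
        if (a_ov > 0.5 * a_tri) region[e] <- "calcium"
      }
    }
  }
  region <- factor(region, levels = c("wall", "intima", "calcium", "buffer"))

  # signed areas must all be positive
  ax <- nodes[tri[, 2], 1] - nodes[tri[, 1], 1]; ay <- nodes[tri[, 2], 2] - nodes[tri[, 1], 2]
  bx <- nodes[tri[, 3], 1] - nodes[tri[, 1], 1]; by <- nodes[tri[, 3], 2] - nodes[tri[, 1], 2]
  area2 <- ax * by - ay * bx
  if (any(area2 <= 0))
    stop("meshing failure: inverted element produced", call. = FALSE)

  # lumen boundary edges (k = 1 ring), ordered counter-clockwise
  lum_a <- corner_id(seq_len(n_theta), 1L)
  lum_b <- corner_id(c(2:n_theta, 1L), 1L)
  lkey <- paste(pmin(lum_a, lum_b), pmax(lum_a, lum_b))
  lmid <- n_corner + match(lkey, key[uk])
  lumen_edges <- cbind(lum_a, lmid, lum_b)

  # fixed outer buffer border: corner ring k = nr plus its midside nodes
  out_a <- corner_id(seq_len(n_theta), nr)
  out_b <- corner_id(c(2:n_theta, 1L), nr)
  okey <- paste(pmin(out_a, out_b), pmax(out_a, out_b))
  omid <- n_corner + match(okey, key[uk])
  fixed_nodes <- unique(c(out_a, omid))

  structure(list(
    nodes = nodes, n_corner = n_corner, tri = tri, region = region,
    lumen_edges = lumen_edges, fixed_nodes = fixed_nodes,
    center = ctr, n_theta = n_theta, nr = nr, rad = rad, theta = theta,
    layer_rows = c(intima = n1, wall = n2, buffer = nb),
    target_edge = target_edge
  ), class = "plaque_mesh")
}

#' Element areas of a mesh (optionally deformed)
#'
#' @param mesh A `plaque_mesh`.
#' @param U Optional nodal displacement matrix (same shape as `mesh$nodes`).
#' @return Numeric vector of triangle areas in mm^2 (corner geometry).
#' @export
element_areas <- function(mesh, U = NULL) {
  nd <- mesh$nodes
  if (!is.null(U)) nd <- nd + U
  t3 <- mesh$tri[, 1:3, drop = FALSE]
  ax <- nd[t3[, 2], 1] - nd[t3[, 1], 1]; ay <- nd[t3[, 2], 2] - nd[t3[, 1], 2]
  bx <- nd[t3[, 3], 1] - nd[t3[, 1], 1]; by <- nd[t3[, 3], 2] - nd[t3[, 1], 2]
  (ax * by - ay * bx) / 2
}

#' Export a mesh and nodal fields in legacy VTK format
#'
#' Writes an ASCII VTK unstructured grid (quadratic triangles) with the
#' element region and any nodal vector fields, for inspection in ParaView.
#'
#' @param mesh A `plaque_mesh`.
#' @param path Output file path.
#' @param point_data Named list of nodal fields (vectors of length n nodes,
#'   or n x 2 matrices written as 3-vectors with zero z).
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  writeLines(c("# vtk DataFile Version 3.0", "plaquemech mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  utils::write.table(cbind(mesh$nodes, 0), con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 7L * m), con)
  utils::write.table(cbind(6L, mesh$tri - 1L), con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(22L, m)), con)  # VTK_QUADRATIC_TRIANGLE
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS region int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$region)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(cbind(v, 0), con, row.names = FALSE, col.names = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(as.character(v), con)
      }
    }
  }
  invisible(path)
}
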