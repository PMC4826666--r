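test_that("meshes have positive element areas and a single region per element", {
  m <- coarse_mesh()
  expect_true(all(element_areas(m) > 0))
  expect_true(all(!is.na(m$region)))
  expect_setequal(as.character(unique(m$region)), c("intima", "wall", "buffer"))
  # layer interfaces are conforming: intima elements all lie inside the IMA
  g <- default_geom()
  cx <- rowMeans(matrix(m$nodes[m$tri[, 1:3], 1], ncol = 3))
  cy <- rowMeans(matrix(m$nodes[m$tri[, 1:3], 2], ncol = 3))
  int <- m$region == "intima"
  expect_true(all(points_in_polygon(cx[int], cy[int], g$ima)))
  wall <- m$region == "wall"
  expect_false(any(points_in_polygon(cx[wall], cy[wall], g$ima)))
})

test_that("halving the target edge multiplies the element count by roughly four", {
  g <- default_geom()
  n1 <- nrow(mesh_geometry(g, target_edge = 0.3)$tri)
  n2 <- nrow(mesh_geometry(g, target_edge = 0.15)$tri)
  expect_gt(n2 / n1, 3.0)
  expect_lt(n2 / n1, 5.0)
})

test_that("calcium-labelled elements capture the calcium polygon area within 5%", {
  # the target edge must resolve the inclusion tangentially (a few angular
  # sectors across its width) for the labelled area to converge
  g <- make_vessel_geometry(1.5, 0.5, 2.0,
                            calcium_spec = list(size = 0.5, angle = 90))
  m <- mesh_geometry(g, target_edge = 0.08)
  a_cal <- sum(element_areas(m)[m$region == "calcium"])
  a_poly <- polygon_area(g$calcium[[1]])
  expect_lt(abs(a_cal - a_poly) / a_poly, 0.05)
})

test_that("meshing rejects non-star-shaped (degenerate) contours", {
  g <- default_geom()
  # collapse part of the IMA inside the lumen radius along some rays
  g$ima$x <- g$center[1] + (g$ima$x - g$center[1]) * 0.3
  g$ima$y <- g$center[2] + (g$ima$y - g$center[2]) * 0.3
  expect_error(mesh_geometry(g, 0.3), "meshing failure|degenerate")
})

test_that("lumen boundary edges are counter-clockwise and lie on the lumen ring", {
  m <- coarse_mesh()
  g <- default_geom()
  r <- sqrt(rowSums(sweep(m$nodes[m$lumen_edges[, 1], ], 2, m$center)^2))
  expect_true(all(abs(r - 1.5) < 0.01))
  # consecutive corner nodes advance in angle (counter-clockwise)
  th <- atan2(m$nodes[m$lumen_edges[, 1], 2] - m$center[2],
              m$nodes[m$lumen_edges[, 1], 1] - m$center[1])
  dth <- diff(unwrap <- th)
  expect_gt(sum(sign(ifelse(dth < -pi, dth + 2 * pi, dth))), 0)
})

test_that("VTK export writes a parsable unstructured grid", {
  m <- coarse_mesh()
  f <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f, point_data = list(depth = m$nodes[, 2]))
  lines <- readLines(f)
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("^CELL_TYPES", lines)))
  expect_true(any(grepl("SCALARS region", lines)))
})
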