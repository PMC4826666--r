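# shared fixtures, built once per test run and cached in this environment
.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

default_geom <- function() fixture("geom", function()
  make_vessel_geometry(1.5, 0.5, 1.25, eccentricity = 0))

coarse_mesh <- function() fixture("mesh35", function()
  mesh_geometry(default_geom(), target_edge = 0.35))

# small speckle slab + transducer for tracking tests
speckle_slab <- function(n = 16000, seed = 1) {
  set.seed(seed)
  scat <- tibble::tibble(x_mm = runif(n, -1.6, 1.6),
                         y_mm = runif(n, 0.5, 9.0),
                         amplitude = rnorm(n))
  structure(scat, class = c("scatterer_field", class(scat)))
}

slab_fov <- list(x0_mm = -1.6, width_mm = 3.2, depth_mm = 9.5)
slab_roi <- list(y_mm = c(2.5, 7), x_mm = c(-0.8, 0.8))

# deformed-radius expansion of the lumen ring, averaged over its nodes
lumen_expansion <- function(mesh, sol) {
  lum <- unique(as.vector(mesh$lumen_edges))
  ref <- mesh$nodes[lum, ]
  def <- ref + sol$U[lum, ]
  mean(sqrt(rowSums(sweep(def, 2, mesh$center)^2))) -
    mean(sqrt(rowSums(sweep(ref, 2, mesh$center)^2)))
}
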