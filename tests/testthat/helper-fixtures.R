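# Shared fixtures: small phantoms and meshes built in code at test time.

# small 3-D phantom: one straight vein along X, radius shrunk to fit
small_spec <- function(seed = 7L, shape = c(96L, 96L, 40L), density = 6) {
  ext <- (shape - 1) * c(4, 4, 13)
  wall <- 20
  radius <- min(87.5, min(ext[2], ext[3]) / 2 - wall / 2 - 15)
  phantom_spec(shape = shape, spacing = c(4, 4, 13),
               vein_centerline = rbind(c(0, ext[2] / 2, ext[3] / 2),
                                       c(ext[1], ext[2] / 2, ext[3] / 2)),
               vein_radius = radius, wall_thickness = wall,
               speckle_density = density, seed = seed)
}

# planar (2-D) phantom
flat_spec <- function(seed = 3L, shape = c(200L, 200L, 1L)) {
  phantom_spec(shape = shape, spacing = c(4, 4, 1), vein_radius = 87.5,
               wall_thickness = 20, seed = seed)
}

# tracker settings sized for the small fixtures (windows must fit the frame)
small_tracker <- function(...) {
  validation_tracker_config(axial_windows = c(9L, 13L, 17L),
                            search_lateral = 31L, search_axial = 13L,
                            dedup_radius = 30, ...)
}

# unit tetrahedron and a stretched copy
unit_tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

# one-tet mesh with prescribed displacements at frame 2
one_tet_mesh <- function(disp = array(0, c(2, 4, 3))) {
  strain_mesh_from_points(unit_tet * 100, disp, mode = "3d")
}

# deterministic point clouds matching tests/testthat/fixtures-hull.csv
hull_case_points <- function(i) {
  n <- 10 + (i %% 20)
  set.seed(1000 + i)
  matrix(runif(3 * n), n, 3)
}
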