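test_that("chamber spec validates its inputs and derives the reticulum radius", {
  expect_error(chamber_spec(R = 0.9), "radius R")
  expect_error(chamber_spec(theta_a = 0), "theta_a")
  expect_error(chamber_spec(theta_a = 120), "theta_a")
  expect_error(chamber_spec(R = 1.1, reticulum_offset = 16), "collar length")
  expect_equal(reticulum_radius(chamber_spec(R = 1.5)), 1.5 - 8.2 / 13)
  expect_equal(reticulum_radius(chamber_spec(R = 1.5)), 0.869, tolerance = 1e-3)
})

test_that("zone meshes recover the analytic spherical-zone areas within 1%", {
  for (tha in c(30, 60, 90)) {
    sp <- chamber_spec(theta_a = tha, N = 24, mesh_resolution = 500)
    m <- build_chamber_mesh(sp)
    zone <- 2 * pi * sp$R^2 * (1 + cos(tha * pi / 180))
    got <- mesh_area(m, c("wall", "prosopyle"))
    expect_lt(abs(got / zone - 1), 0.01)
    cap <- 2 * pi * sp$R^2 * (1 - cos(tha * pi / 180))
    expect_lt(abs(mesh_area(m, "apopyle_surface") / cap - 1), 0.015)
  }
  # theta_a = 90: wall covers the hemisphere zone, half the sphere
  m90 <- build_chamber_mesh(chamber_spec(theta_a = 90, N = 24,
                                         mesh_resolution = 500))
  frac <- mesh_area(m90, c("wall", "prosopyle")) / (4 * pi * 1.5^2)
  expect_equal(frac, 0.5, tolerance = 0.01)
})

test_that("prosopyle carving reaches the target open fraction", {
  m <- build_chamber_mesh(chamber_spec(mesh_resolution = 700))
  expect_gte(m$prosopyle_fraction, 5e-4)
  expect_lte(m$prosopyle_fraction, 2e-3)
  # reproducible carving
  m2 <- build_chamber_mesh(chamber_spec(mesh_resolution = 700))
  expect_identical(which(m$region == "prosopyle"),
                   which(m2$region == "prosopyle"))
  # too coarse to carve within the band
  expect_error(build_chamber_mesh(chamber_spec(mesh_resolution = 60)),
               "too coarse")
  # per-hole mode: many holes, each of the target area, larger total
  mh <- build_chamber_mesh(chamber_spec(mesh_resolution = 700,
                                        prosopyle_mode = "per_hole"))
  expect_gt(mh$prosopyle_fraction, m$prosopyle_fraction)
  expect_gt(sum(mh$region == "prosopyle"), 10)
})

test_that("wall normals point outward and regions are labelled", {
  m <- small_scene_solution()$mesh
  wall <- m$region == "wall"
  expect_true(all(rowSums(m$normals[wall, ] * m$centroids[wall, ]) > 0))
  expect_setequal(unique(m$region),
                  c("wall", "reticulum", "cone", "apopyle_surface",
                    "prosopyle"))
})

test_that("flagella placement is deterministic, seeded, and quasi-uniform", {
  sp <- chamber_spec(N = 100)
  l1 <- place_flagella(sp, 7)
  l2 <- place_flagella(sp, 7)
  l3 <- place_flagella(sp, 8)
  expect_identical(l1, l2)
  expect_identical(l1$base_points, l3$base_points)   # lattice is seed-free
  expect_false(any(l1$psi == l3$psi))
  expect_false(any(l1$phi == l3$phi))
  # all bases outside the apopyle cap
  polar <- acos(l1$base_points[, 3] / sp$R)
  expect_true(all(polar > 30 * pi / 180))
  # minimum spacing within 25% of the hexagonal-lattice estimate
  area <- 2 * pi * sp$R^2 * (1 + cos(30 * pi / 180))
  hex <- sqrt(2 * area / (sqrt(3) * 100))
  ch <- min(dist(l1$base_points))
  dmin <- sp$R * 2 * asin(ch / (2 * sp$R))
  expect_lt(abs(dmin / hex - 1), 0.25)
  # single flagellum sits at the pole opposite the apopyle
  lp <- place_flagella(chamber_spec(N = 1), 1)
  expect_equal(as.numeric(lp$base_points), c(0, 0, -1.5), tolerance = 1e-12)
  # overpacking is rejected
  expect_error(place_flagella(chamber_spec(N = 2000), 1), "overpacked")
})

test_that("mesh exporters write valid OBJ and VTK files", {
  m <- small_scene_solution()$mesh
  f1 <- tempfile(fileext = ".obj"); f2 <- tempfile(fileext = ".vtk")
  write_mesh_obj(m, f1); write_mesh_vtk(m, f2)
  obj <- readLines(f1)
  expect_equal(sum(grepl("^v ", obj)), nrow(m$vertices))
  expect_equal(sum(grepl("^f ", obj)), nrow(m$triangles))
  vtk <- readLines(f2)
  expect_true(any(grepl("POLYGONS", vtk)))
})
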