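test_that("velocity and pressure kernels match the closed-form Stokeslet", {
  src <- matrix(c(0.2, -0.1, 0.4), 1)
  F <- matrix(c(0.3, -0.2, 1.0), 1)
  x <- matrix(c(1.1, 0.6, -0.8), 1)
  r <- x - src; rn <- sqrt(sum(r^2))
  u <- choanopump:::cp_stokeslet_velocity(src, 1e-9, F, x)
  uex <- (F / rn + r * sum(F * r) / rn^3) / (8 * pi)
  expect_lt(max(abs(u - uex)), 1e-6)
  p <- choanopump:::cp_stokeslet_pressure(src, 1e-9, F, x)
  expect_lt(abs(p - sum(F * r) / (4 * pi * rn^3)), 1e-6)
  # axial point force: p = 1/(16 pi) at distance 2 along the force
  p2 <- choanopump:::cp_stokeslet_pressure(matrix(0, 1, 3), 1e-9,
                                           matrix(c(0, 0, 1), 1),
                                           matrix(c(0, 0, 2), 1))
  expect_equal(as.numeric(p2), 1 / (16 * pi), tolerance = 1e-8)
})

test_that("field evaluation is linear in the forces", {
  sc <- small_scene_solution()
  pts <- matrix(c(0, 0, 0, 0.2, -0.1, 0.3), 2, 3, byrow = TRUE)
  u1 <- evaluate_velocity(sc$sol, pts)
  sol2 <- sc$sol; sol2$forces <- 2 * sol2$forces
  expect_equal(evaluate_velocity(sol2, pts), 2 * u1, tolerance = 1e-12)
  expect_equal(evaluate_pressure(sol2, pts),
               2 * evaluate_pressure(sc$sol, pts), tolerance = 1e-12)
})

test_that("zero prescribed velocities give zero forces", {
  sc <- small_scene_solution()
  st0 <- sc$states
  st0$velocities[] <- 0
  sol <- solve_resistance(stokes_scene(sc$mesh, st0))
  expect_lt(max(abs(sol$forces)), 1e-10)
})

test_that("a translating rigid sphere recovers Stokes drag within 3%", {
  g <- unit_sphere_points(700)
  n <- nrow(g$centroids)
  scene <- structure(list(points = g$centroids,
                          velocities = matrix(rep(c(0, 0, 1), each = n), n),
                          eps = 0.5 * sqrt(g$areas),
                          type = rep("surface", n), weights = g$areas,
                          flagellum = rep(NA, n), kernel = "free",
                          mesh = NULL, states = NULL, forcing = NULL),
                     class = "stokes_scene")
  sol <- solve_resistance(scene)
  drag <- colSums(sol$forces)
  expect_lt(abs(drag[3] / (6 * pi) - 1), 0.03)
  expect_lt(max(abs(drag[1:2])), 0.02 * drag[3])
  expect_lt(sol$residual, 1e-6)
})

test_that("the mobility operator is symmetric for uniform regularization", {
  set.seed(4)
  pts <- matrix(rnorm(30), 10, 3)
  A <- choanopump:::cp_stokeslet_matrix(pts, rep(0.1, 10))
  expect_lt(max(abs(A - t(A))), 1e-12)
})

test_that("pressure is harmonic away from the singularities", {
  sc <- small_scene_solution()
  h <- 0.01
  for (x0 in list(c(0, 0, 0), c(0.2, 0.1, -0.2))) {
    sten <- rbind(x0,
                  x0 + c(h, 0, 0), x0 - c(h, 0, 0),
                  x0 + c(0, h, 0), x0 - c(0, h, 0),
                  x0 + c(0, 0, h), x0 - c(0, 0, h))
    p <- evaluate_pressure(sc$sol, sten)
    lap <- (sum(p[-1]) - 6 * p[1]) / h^2
    expect_lt(abs(lap) * h^2 / max(abs(p[1]), 1), 1e-3)
  }
})

test_that("the far field decays at least as fast as a Stokeslet", {
  sc <- small_scene_solution()
  rs <- c(5, 10, 20, 50) * sc$spec$R
  us <- vapply(rs, function(r)
    sqrt(sum(evaluate_velocity(sc$sol, c(r, 0.3 * r, 0.5 * r) /
                                 sqrt(1 + 0.09 + 0.25))^2)), numeric(1))
  slope <- coef(lm(log(us) ~ log(rs)))[[2]]
  expect_lt(slope, -0.95)
})

test_that("field maps export to structured VTK", {
  sc <- small_scene_solution()
  f <- tempfile(fileext = ".vtk")
  write_field_vtk(sc$sol, f, half_width = 2, spacing = 0.5)
  v <- readLines(f)
  expect_true(any(grepl("VECTORS velocity", v)))
  expect_true(any(grepl("SCALARS pressure", v)))
  expect_equal(sum(grepl("DIMENSIONS", v)), 1)
})

test_that("the wall kernel enforces no-slip on the plane", {
  # one beating flagellum above z = 0 via the image system
  p <- waveform_params(kl = 3 * pi, n_nodes = 10)
  entry <- list(base = c(0, 0, 0), e1 = c(0, 0, 1), e2 = c(1, 0, 0), phi = 0)
  st <- flagellum_state(entry, p, 0.2)
  keep <- st$positions[, 3] > 1e-9
  states <- list(positions = st$positions[keep, ],
                 velocities = st$velocities[keep, ],
                 ds = st$ds[keep], flagellum = rep(1L, sum(keep)))
  sol <- solve_resistance(stokes_scene(NULL, states, kernel = "wall"))
  wallpts <- cbind(runif(20, -2, 2), runif(20, -2, 2), 0)
  uw <- evaluate_velocity(sol, wallpts)
  unear <- evaluate_velocity(sol, matrix(c(0.3, 0.3, 0.5), 1))
  expect_lt(max(abs(uw)), 0.05 * sqrt(sum(unear^2)))
})
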