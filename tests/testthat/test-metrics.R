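test_that("a quiescent chamber has zero flux, work and pressure", {
  sc <- small_scene_solution()
  st0 <- sc$states
  st0$velocities[] <- 0
  sol <- solve_resistance(stokes_scene(sc$mesh, st0))
  expect_lt(abs(outlet_flow_rate(sol, sc$mesh)), 1e-10)
  expect_lt(abs(work_rate(sol)), 1e-12)
  pr <- max_pressure(sol, sc$spec)
  expect_lt(abs(pr$Pc), 1e-10)
  expect_lt(abs(pr$Pmax), 1e-10)
})

test_that("a beating chamber dissipates, balances forces and conserves mass", {
  sc <- small_scene_solution()
  expect_gt(work_rate(sc$sol), 0)
  expect_lt(force_balance(sc$sol)$relative, 0.02)
  # net flux through a closed sphere enclosing the chamber is tiny
  sph <- choanopump:::zone_mesh(1.7 * sc$spec$R, 1e-6, pi - 1e-6, 0.12)
  g <- choanopump:::tri_geometry(sph$vertices, sph$triangles)
  u <- evaluate_velocity(sc$sol, g$centroids)
  net <- sum(rowSums(u * g$normals) * g$areas)
  expect_lt(abs(net), 0.01 * max(abs(outlet_flow_rate(sc$sol, sc$mesh)), 0.01))
})

test_that("the pressure maximum sits near the chamber center", {
  sc <- small_scene_solution()
  pr <- max_pressure(sc$sol, sc$spec)
  expect_lt(pr$r_max, 0.5 * sc$spec$R)
  expect_gt(pr$Pmax, 0)
  expect_gt(pr$Pc, 0)
})

test_that("flagellar power density peaks toward the tip", {
  sc <- small_scene_solution()
  idx <- sc$sol$type == "flagellum"
  pw <- rowSums(sc$sol$velocities[idx, ] * sc$sol$forces[idx, ])
  node <- rep(seq_len(sc$params$n_nodes), sc$spec$N)
  prof <- tapply(pw, node, mean)
  n <- sc$params$n_nodes
  expect_gt(which.max(prof), 2 * n / 3)
})

test_that("metrics scale correctly with the beat speed", {
  sc <- small_scene_solution()
  st2 <- sc$states
  st2$velocities <- 3 * st2$velocities
  sol2 <- solve_resistance(stokes_scene(sc$mesh, st2))
  expect_equal(outlet_flow_rate(sol2, sc$mesh),
               3 * outlet_flow_rate(sc$sol, sc$mesh), tolerance = 1e-8)
  expect_equal(evaluate_pressure(sol2, c(0, 0, 0)),
               3 * evaluate_pressure(sc$sol, c(0, 0, 0)), tolerance = 1e-8)
  expect_equal(work_rate(sol2), 9 * work_rate(sc$sol), tolerance = 1e-8)
})

test_that("efficiency combines time averages and rejects zero work", {
  expect_equal(efficiency(0, 5, 2), 0)
  expect_equal(efficiency(0.07, 4, 200), 0.07 * 4 / 200)
  expect_error(efficiency(0.07, 4, 0), "Wbar")
})

test_that("pressure-difference superposition has the right identity and sign", {
  sc <- small_scene_solution()
  dp <- delta_p_response(sc$mesh, sc$layout, sc$params)
  expect_lt(dp$C1, 0)       # adverse pressure reduces the output
  av <- list(Qbar = 0.05, Pmaxbar = 3, Wbar = 100)
  sh <- shifted_metrics(av, dp$C1, dp$C2, dP = c(0, 1, 2))
  expect_equal(sh$Qp[1], av$Qbar)
  expect_equal(sh$Pp[1], av$Pmaxbar)
  expect_equal(sh$etap[1], av$Qbar * av$Pmaxbar / av$Wbar)
  expect_true(all(diff(sh$Qp) < 0))
})

test_that("time and ensemble averaging summarize runs correctly", {
  mk <- function(q, seed) {
    structure(list(series = data.frame(t = 0:4 / 5, Q = q, Pc = 1,
                                       Pmax = 2, W = 10),
                   averages = list(Qbar = mean(q), Pcbar = 1, Pmaxbar = 2,
                                   Wbar = 10, eta = mean(q) * 2 / 10),
                   seed = seed), class = "pump_run")
  }
  runs <- list(mk(rep(0.05, 5), 1), mk(rep(0.07, 5), 2))
  m <- time_ensemble_average(runs)
  expect_equal(m$mean$Qbar, 0.06)
  expect_equal(m$sd$Qbar, sd(c(0.05, 0.07)))
  expect_equal(m$n, 2)
  # a constant series averages to the constant
  expect_equal(time_ensemble_average(list(mk(rep(0.04, 5), 1)))$mean$Qbar,
               0.04)
})
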