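#' Simulate one beat cycle of a chamber
#'
#' Builds (or reuses) the chamber mesh and flagellar layout, then steps the
#' beat through one period with time step `1 / n_steps` (the reference
#' choice is 50 steps, i.e. 0.02 T), solving the resistance problem at every
#' step and recording the outlet flow rate `Q`, center and maximum chamber
#' pressures `Pc`/`Pmax`, and flagellar work rate `W`. Time averages and the
#' mechanical pumping efficiency `eta = Qbar Pmaxbar / Wbar` are computed
#' from the series; `Pmaxbar` averages the per-step grid maximum (whose
#' location may move), and `Pcbar` the fixed center value, reported side by
#' side.
#'
#' @param spec A [chamber_spec()].
#' @param params A [waveform_params()].
#' @param seed Seed for the flagellar phases and beat-plane angles.
#' @param n_steps Time steps per beat period (default 50).
#' @param eps_factor Regularization factor for [stokes_scene()].
#' @param mesh Optionally a prebuilt [build_chamber_mesh()] (reused across
#'   ensemble members).
#' @param pressure_spacing Grid spacing for [max_pressure()].
#' @param keep_last_solution Keep the final step's [solve_resistance()]
#'   result (for field maps / exports).
#' @param verbose Print per-step progress.
#' @return An object of class `pump_run`: `series` (data frame with one row
#'   per step), `averages` (`Qbar`, `Pcbar`, `Pmaxbar`, `Wbar`, `eta`),
#'   the mesh, layout, spec, params and seed.
#' @export
simulate_chamber <- function(spec, params, seed = 1L, n_steps = 50L,
                             eps_factor = 0.5, mesh = NULL,
                             pressure_spacing = 0.05,
                             keep_last_solution = FALSE, verbose = FALSE) {
  if (is.null(mesh)) mesh <- build_chamber_mesh(spec)
  layout <- place_flagella(spec, seed)
  ts <- (seq_len(n_steps) - 1) / n_steps
  ser <- data.frame(t = ts, Q = NA_real_, Pc = NA_real_, Pmax = NA_real_,
                    W = NA_real_, residual = NA_real_)
  sol <- NULL
  for (j in seq_len(n_steps)) {
    st <- flagella_states(layout, params, ts[j])
    scene <- stokes_scene(mesh, st, eps_factor = eps_factor)
    sol <- solve_resistance(scene)
    pr <- max_pressure(sol, spec, spacing = pressure_spacing)
    ser$Q[j] <- outlet_flow_rate(sol, mesh)
    ser$Pc[j] <- pr$Pc
    ser$Pmax[j] <- pr$Pmax
    ser$W[j] <- work_rate(sol)
    ser$residual[j] <- sol$residual
    if (verbose)
      message(sprintf("t = %.2f T: Q = %.4g, Pmax = %.4g, W = %.4g",
                      ts[j], ser$Q[j], ser$Pmax[j], ser$W[j]))
    if (!keep_last_solution && j < n_steps) sol <- NULL
  }
  av <- list(Qbar = mean(ser$Q), Pcbar = mean(ser$Pc),
             Pmaxbar = mean(ser$Pmax), Wbar = mean(ser$W))
  av$eta <- efficiency(av$Qbar, av$Pmaxbar, av$Wbar)
  structure(list(series = ser, averages = av, mesh = mesh, layout = layout,
                 spec = spec, params = params, seed = seed,
                 n_steps = n_steps,
                 solution = if (keep_last_solution) sol else NULL),
            class = "pump_run")
}

#' @export
print.pump_run <- function(x, ...) {
  cat(sprintf("pump_run: N = %d, R = %.3g, theta_a = %.3g, kl = %.3g*pi, seed %d\n",
              x$spec$N, x$spec$R, x$spec$theta_a, x$params$kl / pi, x$seed))
  cat(sprintf("  Qbar = %.4g  Pmaxbar = %.4g  Wbar = %.4g  eta = %.4g\n",
              x$averages$Qbar, x$averages$Pmaxbar, x$averages$Wbar,
              x$averages$eta))
  invisible(x)
}

#' Ensemble of chamber simulations
#'
#' Repeats [simulate_chamber()] over several seeds (independent flagellar
#' phases and beat-plane rotations; the chamber geometry is shared) and
#' summarizes with [time_ensemble_average()].
#'
#' @inheritParams simulate_chamber
#' @param seeds Integer seeds, one per ensemble member (default 3).
#' @param ... Passed to [simulate_chamber()].
#' @return A list with `runs` (the `pump_run` objects) and `metrics`
#'   (a `pump_metrics`).
#' @export
ensemble_run <- function(spec, params, seeds = 1:3, ...) {
  mesh <- build_chamber_mesh(spec)
  runs <- lapply(seeds, function(s)
    simulate_chamber(spec, params, seed = s, mesh = mesh, ...))
  list(runs = runs, metrics = time_ensemble_average(runs))
}

#' Time-averaged flux of a single wall-attached flagellum
#'
#' Places one model flagellum perpendicular to an infinite no-slip plane
#' (image-system kernel), beats it through one period, time-averages the
#' velocity field over the period, and integrates only the outgoing
#' (away-from-wall) component of that mean field over a control hemisphere
#' centred on the base. A point force normal to a wall drives zero net
#' flux (outgoing flow near the axis is balanced by return flow toward the
#' wall), so the outgoing component of the steady streaming field is the
#' meaningful single-flagellum pumping capacity; for the default waveform
#' it is of order 0.01 L^3/T. The instantaneous oscillatory field is much
#' larger than the mean, which is why the average is taken before the
#' positive part.
#'
#' @param params A [waveform_params()].
#' @param n_steps Time steps per period (default 50).
#' @param hemisphere_radius Control-surface radius in units of L.
#' @param n_sphere Angular resolution of the control hemisphere.
#' @param eps_factor Regularization factor.
#' @return List with the time-averaged outgoing flux `Q_out`, the (near
#'   zero) net flux `Q_net`, and the per-step series.
#' @export
single_flagellum_wall_flux <- function(params, n_steps = 50L,
                                       hemisphere_radius = 1.2,
                                       n_sphere = 24L, eps_factor = 0.5) {
  entry <- list(base = c(0, 0, 0), e1 = c(0, 0, 1), e2 = c(1, 0, 0), phi = 0)
  # quadrature points on the upper hemisphere
  th <- (seq_len(n_sphere) - 0.5) * (pi / 2) / n_sphere
  pts <- NULL; wts <- NULL
  for (tt in th) {
    m <- max(6L, round(2 * n_sphere * sin(tt)))
    ph <- (seq_len(m) - 0.5) * 2 * pi / m
    nrm <- cbind(sin(tt) * cos(ph), sin(tt) * sin(ph), rep(cos(tt), m))
    pts <- rbind(pts, hemisphere_radius * nrm)
    wts <- c(wts, rep(hemisphere_radius^2 * sin(tt) * (pi / 2 / n_sphere) *
                        (2 * pi / m), m))
  }
  ts <- (seq_len(n_steps) - 1) / n_steps
  qn <- numeric(n_steps)
  umean <- matrix(0, nrow(pts), 3)
  for (j in seq_len(n_steps)) {
    st <- flagellum_state(entry, params, ts[j])
    states <- list(positions = st$positions, velocities = st$velocities,
                   ds = st$ds, flagellum = rep(1L, nrow(st$positions)))
    # the base node sits on the wall; drop it from the unknowns
    keep <- st$positions[, 3] > 1e-9
    states <- lapply(states, function(x)
      if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep])
    scene <- stokes_scene(NULL, states, eps_factor = eps_factor,
                          kernel = "wall")
    sol <- solve_resistance(scene)
    u <- evaluate_velocity(sol, pts)
    umean <- umean + u / n_steps
    qn[j] <- sum(rowSums(u * pts / hemisphere_radius) * wts)
  }
  ur <- rowSums(umean * pts / hemisphere_radius)
  list(Q_out = sum(pmax(ur, 0) * wts), Q_net = mean(qn),
       series = data.frame(t = ts, Q_net = qn))
}
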