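#' Outlet flow rate through the apopyle
#'
#' Integrates `u . n` over the spherical-cap flux surface spanning the
#' apopyle (per-triangle centroid quadrature, outward normals). In model
#' units (L = T = 1) the rescaled rate `Q = Q* T / L^3` equals the raw
#' integral; positive values are outward flow.
#'
#' @param sol A [solve_resistance()] result for a chamber scene.
#' @param mesh The [build_chamber_mesh()] used in the scene.
#' @param region Surface over which to integrate (default the apopyle cap).
#' @return Dimensionless flow rate.
#' @export
outlet_flow_rate <- function(sol, mesh, region = "apopyle_surface") {
  idx <- which(mesh$region %in% region)
  if (length(idx) == 0) stop("degenerate flux surface: no triangles in region")
  u <- evaluate_velocity(sol, mesh$centroids[idx, , drop = FALSE])
  sum(rowSums(u * mesh$normals[idx, , drop = FALSE]) * mesh$areas[idx])
}

#' Inlet flow through the prosopyles
#'
#' Flux integral over the carved prosopyle patches (outward normals, so
#' inflow is negative).
#'
#' @inheritParams outlet_flow_rate
#' @return Dimensionless flow rate.
#' @export
prosopyle_flux <- function(sol, mesh) outlet_flow_rate(sol, mesh, "prosopyle")

#' Chamber pressure: center value and interior maximum
#'
#' Evaluates the rescaled pressure `P = P* T / mu` at the chamber center
#' (`Pc`) and on a regular Cartesian grid inside `radius_frac * R`
#' (default spacing `0.05 R`), excluding points within one regularization
#' length of any collocation node; `Pmax` is the grid maximum, which sits
#' near the chamber center in this geometry.
#'
#' @param sol A [solve_resistance()] result.
#' @param spec The [chamber_spec()] of the scene.
#' @param spacing Grid spacing as a fraction of R (default 0.05).
#' @param radius_frac Sampling-ball radius as a fraction of R (default 0.5).
#' @param clearance Exclusion radius around each singularity in units of
#'   its regularization length (default 2.5; the regularized pressure
#'   kernel still carries an appreciable self-signature at one
#'   regularization length, so a wider margin is needed for a
#'   discretization-independent maximum).
#' @return List with `Pc`, `Pmax`, and `r_max` (radius of the argmax).
#' @export
max_pressure <- function(sol, spec, spacing = 0.05, radius_frac = 0.5,
                         clearance = 2.5) {
  R <- spec$R
  g <- seq(-radius_frac * R, radius_frac * R, by = spacing * R)
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  grid <- grid[rowSums(grid^2) <= (radius_frac * R)^2, , drop = FALSE]
  # exclude points too close to any singularity (per source class)
  ok <- rep(TRUE, nrow(grid))
  for (ty in unique(sol$type)) {
    src <- sol$points[sol$type == ty, , drop = FALSE]
    dmin <- cp_min_dist(src, grid)
    ok <- ok & dmin > clearance * max(sol$eps[sol$type == ty])
  }
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0) stop("empty pressure sampling set after exclusions")
  p <- evaluate_pressure(sol, grid)
  i <- which.max(p)
  list(Pc = evaluate_pressure(sol, c(0, 0, 0))[1],
       Pmax = p[i], r_max = sqrt(sum(grid[i, ]^2)))
}

#' Flagellar rate of working
#'
#' `W* = sum_i int u . f ds` over all flagellar nodes, where `f` is the
#' force per unit length exerted by the flagellum on the fluid (equal and
#' opposite to the drag); in model units `W = W* T^2 / (mu L^3)` is the raw
#' sum. Positive whenever any flagellum moves (viscous dissipation).
#'
#' @param sol A [solve_resistance()] result containing flagellar nodes.
#' @return Dimensionless work rate.
#' @export
work_rate <- function(sol) {
  idx <- sol$type == "flagellum"
  if (!any(idx)) return(0)
  sum(rowSums(sol$velocities[idx, , drop = FALSE] *
              sol$forces[idx, , drop = FALSE]))
}

#' Mechanical pumping efficiency
#'
#' `eta = Qbar * Pmaxbar / Wbar`: the useful pumping power (pressure rise
#' times volumetric rate, with zero pressure at infinity) over the flagellar
#' power input. Time averages are taken first, then combined.
#'
#' @param Qbar Time-averaged outlet flow rate.
#' @param Pmaxbar Time-averaged maximum chamber pressure.
#' @param Wbar Time-averaged flagellar work rate (> 0).
#' @return Dimensionless efficiency.
#' @export
efficiency <- function(Qbar, Pmaxbar, Wbar) {
  if (Wbar <= 0) stop("efficiency undefined: Wbar must be > 0")
  Qbar * Pmaxbar / Wbar
}

#' Response to a pressure difference across the chamber
#'
#' By superposition of Stokes solutions, the pump under an adverse pressure
#' difference `dP` (apopyle side exceeding the prosopyle side) splits into
#' (a) beating flagella with no pressure difference and (b) immotile
#' flagella, rigid in the chamber, driven by `dP` alone. This solves (b)
#' with a unit normal-stress jump realized as a force per unit area `-n` on
#' the apopyle cap, giving `C1` (flux per unit dP, negative with the
#' outward-positive convention) and `C2` (chamber-center pressure per unit
#' dP). Then `Q' = Qbar + C1 dP`, `P' = Pmaxbar + C2 dP` and `eta'` follows
#' from [efficiency()] with the unchanged work rate.
#'
#' @param mesh A [build_chamber_mesh()] result.
#' @param layout A [place_flagella()] result.
#' @param params A [waveform_params()].
#' @param t_freeze Reference phase at which the flagella are frozen.
#' @param eps_factor Regularization factor, as in [stokes_scene()].
#' @return List with `C1`, `C2` and the unit-response solution.
#' @export
delta_p_response <- function(mesh, layout, params, t_freeze = 0,
                             eps_factor = 0.5) {
  st <- flagella_states(layout, params, t_freeze)
  st$velocities[] <- 0
  idx <- which(mesh$region == "apopyle_surface")
  forcing <- list(points = mesh$centroids[idx, , drop = FALSE],
                  forces = -mesh$normals[idx, , drop = FALSE] *
                    mesh$areas[idx],
                  eps = eps_factor * sqrt(mesh$areas[idx]))
  scene <- stokes_scene(mesh, st, eps_factor = eps_factor, forcing = forcing)
  sol <- solve_resistance(scene)
  C1 <- outlet_flow_rate(sol, mesh)
  C2 <- evaluate_pressure(sol, c(0, 0, 0))[1]
  if (!is.finite(C1) || abs(C1) > 1e3)
    stop("leaky geometry: unbounded pressure-driven flux")
  list(C1 = C1, C2 = C2, sol = sol)
}

#' Pressure-shifted pump metrics
#'
#' Applies the linear superposition `Q' = Qbar + C1 dP`,
#' `P' = Pmaxbar + C2 dP`, `eta' = Q' P' / Wbar`.
#'
#' @param averages A list with `Qbar`, `Pmaxbar`, `Wbar` (e.g. from
#'   [simulate_chamber()]`$averages`).
#' @param C1,C2 Response coefficients from [delta_p_response()].
#' @param dP Pressure difference(s) in rescaled units.
#' @return Data frame with `dP`, `Qp`, `Pp`, `etap`.
#' @export
shifted_metrics <- function(averages, C1, C2, dP) {
  data.frame(dP = dP,
             Qp = averages$Qbar + C1 * dP,
             Pp = averages$Pmaxbar + C2 * dP,
             etap = (averages$Qbar + C1 * dP) *
               (averages$Pmaxbar + C2 * dP) / averages$Wbar)
}

#' Time and ensemble averages of pump metrics
#'
#' Averages each run's per-step series over its beat period, then reports
#' the ensemble mean and SD across runs (seeds).
#'
#' @param runs A list of `pump_run` objects from [simulate_chamber()].
#' @return An object of class `pump_metrics`: per-run averages and ensemble
#'   mean/SD of `Qbar`, `Pcbar`, `Pmaxbar`, `Wbar`, `eta`.
#' @export
time_ensemble_average <- function(runs) {
  if (length(runs) < 1) stop("no runs")
  per <- do.call(rbind, lapply(runs, function(r) {
    as.data.frame(r$averages[c("Qbar", "Pcbar", "Pmaxbar", "Wbar", "eta")])
  }))
  per$seed <- vapply(runs, function(r) r$seed, numeric(1))
  mn <- colMeans(per[, 1:5, drop = FALSE])
  sdv <- apply(per[, 1:5, drop = FALSE], 2, sd)
  structure(list(per_run = per, mean = as.list(mn),
                 sd = as.list(sdv), n = length(runs)),
            class = "pump_metrics")
}

#' @export
print.pump_metrics <- function(x, ...) {
  cat(sprintf("pump_metrics over %d run(s):\n", x$n))
  for (k in names(x$mean))
    cat(sprintf("  %-8s %.4g +/- %.2g\n", k, x$mean[[k]],
                if (x$n > 1) x$sd[[k]] else 0))
  invisible(x)
}
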