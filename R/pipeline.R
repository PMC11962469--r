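#' Configure a parameter sweep
#'
#' Describes one axis of the four study sweeps: number of flagella `N`,
#' chamber radius `rho = R / L` (holding the flagellar number density
#' fixed, so N grows with R^2), wavenumber `k_ell`, or opening angle
#' `theta_a` (optionally holding the coverage fraction `phi` inside a
#' narrow band by adjusting N to the band midpoint).
#'
#' @param axis One of `"N"`, `"rho"`, `"k_ell"`, `"theta_a"`.
#' @param values Grid values along the axis.
#' @param base Named list of held-fixed parameters; defaults `R = 1.5`,
#'   `theta_a = 30`, `N = 143`, `kl = 3 * pi`, `A = 0.14`.
#' @param phi_band Optional `c(lo, hi)` coverage-fraction band; N is set to
#'   the band midpoint for each grid point (theta_a sweeps).
#' @param seeds Ensemble seeds (default 1:3).
#' @param tier Resolution tier: `"coarse"` (~500 wall elements, 10 nodes
#'   per flagellum), `"paper"` (~2000 elements, 20 nodes), or `"trend"`
#'   (~350 elements, 8 nodes; resolves trend directions and peak locations,
#'   not absolute values).
#' @param n_steps Time steps per period (default 50).
#' @param allow_outside_range Permit grid values outside the study ranges
#'   (N 37--359, rho 1.5--3, k_ell 1.5pi--6pi, theta_a 10--90 degrees).
#' @param outdir Optional output directory for per-point CSVs, the combined
#'   table and a JSON manifest; grid points with an existing CSV are reused
#'   (resumable sweeps).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(axis = c("N", "rho", "k_ell", "theta_a"), values,
                         base = list(), phi_band = NULL, seeds = 1:3,
                         tier = c("coarse", "paper", "trend"), n_steps = 50L,
                         allow_outside_range = FALSE, outdir = NULL) {
  axis <- match.arg(axis)
  tier <- match.arg(tier)
  b <- utils::modifyList(list(R = 1.5, theta_a = 30, N = 143L, kl = 3 * pi,
                              A = 0.14), base)
  rng <- switch(axis, N = c(37, 359), rho = c(1.5, 3),
                k_ell = c(1.5 * pi, 6 * pi), theta_a = c(10, 90))
  if (!allow_outside_range && (min(values) < rng[1] || max(values) > rng[2]))
    stop(sprintf("grid values outside the study range [%.3g, %.3g] for %s; set allow_outside_range = TRUE to override",
                 rng[1], rng[2], axis))
  structure(list(axis = axis, values = values, base = b,
                 phi_band = phi_band, seeds = seeds, tier = tier,
                 n_steps = as.integer(n_steps), outdir = outdir),
            class = "sweep_config")
}

tier_settings <- function(tier) {
  switch(tier,
         trend = list(mesh_resolution = 350, n_nodes = 8L),
         coarse = list(mesh_resolution = 500, n_nodes = 10L),
         paper = list(mesh_resolution = 2000, n_nodes = 20L))
}

point_parameters <- function(config, value) {
  b <- config$base
  ts <- tier_settings(config$tier)
  R <- b$R; theta_a <- b$theta_a; N <- b$N; kl <- b$kl
  if (config$axis == "N") N <- as.integer(value)
  if (config$axis == "rho") {
    dens <- flagellar_density(b$N, b$R, b$theta_a)
    R <- value
    N <- as.integer(round(dens * 2 * pi * R^2 *
                            (1 + cos(deg2rad(theta_a)))))
  }
  if (config$axis == "k_ell") kl <- value
  if (config$axis == "theta_a") theta_a <- value
  if (!is.null(config$phi_band)) {
    phi_mid <- mean(config$phi_band)
    N <- as.integer(round(phi_mid * 2 * R^2 *
                            (1 + cos(deg2rad(theta_a))) / b$A^2))
  }
  spec <- chamber_spec(R = R, theta_a = theta_a, N = N, A = b$A,
                       mesh_resolution = ts$mesh_resolution,
                       prosopyle_mode = "per_hole")
  params <- waveform_params(kl = kl, A = b$A, n_nodes = ts$n_nodes)
  list(spec = spec, params = params)
}

#' Run a parameter sweep
#'
#' For every grid point: build the scene, run one beat period per ensemble
#' seed, and collect the time/ensemble-averaged pump metrics. Failures at
#' individual grid points are recorded without aborting the sweep. With an
#' `outdir`, per-point results are written as CSV and reused on rerun, and
#' a JSON manifest (all parameters, seeds, tier, package version) plus the
#' combined tidy CSV are written.
#'
#' @param config A [sweep_config()].
#' @param verbose Log per-point progress.
#' @return Data frame, one row per grid point: parameters, achieved `phi`,
#'   ensemble means and SDs of `Qbar`, `Wbar`, `Pmaxbar`, `eta`, plus
#'   `Q_per_N` and an `error` column (NA on success).
#' @export
run_sweep <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "sweep_config"))
  if (!is.null(config$outdir) && !dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  rows <- lapply(config$values, function(v) {
    tag <- sprintf("point_%s_%s.csv", config$axis, signif(v, 6))
    fp <- if (!is.null(config$outdir)) file.path(config$outdir, tag) else NULL
    if (!is.null(fp) && file.exists(fp)) {
      if (verbose) message("reusing ", tag)
      return(read.csv(fp))
    }
    row <- tryCatch({
      pp <- point_parameters(config, v)
      ens <- ensemble_run(pp$spec, pp$params, seeds = config$seeds,
                          n_steps = config$n_steps)
      m <- ens$metrics
      data.frame(axis = config$axis, value = v, N = pp$spec$N,
                 R = pp$spec$R, theta_a = pp$spec$theta_a,
                 kl_over_pi = pp$params$kl / pi, ell = pp$params$ell,
                 phi = coverage_fraction(pp$spec$N, pp$spec$A, pp$spec$R,
                                         pp$spec$theta_a),
                 Qbar = m$mean$Qbar, Qbar_sd = m$sd$Qbar,
                 Wbar = m$mean$Wbar, Wbar_sd = m$sd$Wbar,
                 Pmaxbar = m$mean$Pmaxbar, Pmaxbar_sd = m$sd$Pmaxbar,
                 Pcbar = m$mean$Pcbar,
                 eta = m$mean$eta, eta_sd = m$sd$eta,
                 Q_per_N = m$mean$Qbar / pp$spec$N,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(axis = config$axis, value = v, N = NA, R = NA,
                 theta_a = NA, kl_over_pi = NA, ell = NA, phi = NA,
                 Qbar = NA, Qbar_sd = NA, Wbar = NA, Wbar_sd = NA,
                 Pmaxbar = NA, Pmaxbar_sd = NA, Pcbar = NA,
                 eta = NA, eta_sd = NA, Q_per_N = NA,
                 error = conditionMessage(e))
    })
    if (verbose)
      message(sprintf("%s = %.4g: %s", config$axis, v,
                      if (is.na(row$error)) sprintf("Qbar = %.4g, eta = %.4g",
                                                    row$Qbar, row$eta)
                      else paste("ERROR:", row$error)))
    if (!is.null(fp)) write.csv(row, fp, row.names = FALSE)
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(config$outdir)) {
    write.csv(out, file.path(config$outdir, "sweep.csv"), row.names = FALSE)
    manifest <- list(axis = config$axis, values = config$values,
                     base = config$base, phi_band = config$phi_band,
                     seeds = config$seeds, tier = config$tier,
                     n_steps = config$n_steps,
                     package_version = as.character(utils::packageVersion("choanopump")))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Rebuild a sweep configuration from a manifest
#'
#' @param path Path to a `manifest.json` written by [run_sweep()].
#' @param outdir Optional new output directory.
#' @return A [sweep_config()].
#' @export
sweep_from_manifest <- function(path, outdir = NULL) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  sweep_config(axis = m$axis, values = m$values, base = as.list(m$base),
               phi_band = m$phi_band, seeds = m$seeds, tier = m$tier,
               n_steps = m$n_steps, allow_outside_range = TRUE,
               outdir = outdir)
}

#' Figure-ready tables from sweep results
#'
#' Splits a [run_sweep()] result into one tidy table per pumping function
#' (`Qbar`, `Wbar`, `Pmaxbar`, `eta` against the sweep axis).
#'
#' @param results Data frame from [run_sweep()] (one or more sweeps bound
#'   together).
#' @return Named list of data frames.
#' @export
report_sweep <- function(results) {
  if (nrow(results) == 0) stop("empty results")
  lapply(setNames(nm = c("Qbar", "Wbar", "Pmaxbar", "eta")), function(m) {
    out <- results[, c("axis", "value", "N", "R", "theta_a", "kl_over_pi",
                       "phi", m, paste0(m, "_sd"))]
    names(out)[8:9] <- c("mean", "sd")
    out
  })
}
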