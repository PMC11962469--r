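#' Apopyle opening angle from chamber and apopyle size
#'
#' Assuming a spherical chamber, an apopyle of diameter `d` on a chamber of
#' diameter `D` is the chord of a spherical cap, so the half-opening angle
#' is `theta_a = asin(d / D)`. When only the apopyle area is known the
#' diameter is recovered from `d = 2 sqrt(area / pi)`.
#'
#' @param D Chamber diameter (micrometres).
#' @param d Apopyle diameter (same units as `D`).
#' @param area Apopyle area (square micrometres), used when `d` is missing.
#' @return Opening angle in degrees. Vectorized.
#' @export
opening_angle <- function(D, d = NULL, area = NULL) {
  if (is.null(d)) {
    if (is.null(area)) stop("supply the apopyle diameter or area")
    d <- 2 * sqrt(area / pi)
  }
  if (any(stats::na.omit(d > D))) stop("apopyle diameter exceeds chamber diameter")
  rad2deg(asin(d / D))
}

#' Choanocyte coverage fraction
#'
#' The wall area available to choanocytes is `2 pi R^2 (1 + cos theta_a)`;
#' assigning each flagellum a beat-envelope footprint `pi A^2` gives the
#' area fraction `phi = N A^2 / (2 R^2 (1 + cos theta_a))`. For reference,
#' hexagonal close packing on a plane reaches `pi sqrt(3) / 6 ~= 0.907`
#' (see [hex_packing_fraction]).
#'
#' @param N Number of flagella.
#' @param A Beat amplitude.
#' @param R Chamber radius (same units as `A`).
#' @param theta_a Opening angle, degrees.
#' @return Dimensionless coverage fraction.
#' @export
coverage_fraction <- function(N, A, R, theta_a) {
  stopifnot(all(N > 0), all(A > 0), all(R > 0),
            all(theta_a > 0), all(theta_a <= 90))
  N * A^2 / (2 * R^2 * (1 + cos(deg2rad(theta_a))))
}

#' Hexagonal close-packing fraction, `pi * sqrt(3) / 6`
#' @export
hex_packing_fraction <- pi * sqrt(3) / 6

#' Flagellar number density on the chamber wall
#'
#' `N / (2 pi R^2 (1 + cos theta_a))`, flagella per unit wall area.
#'
#' @inheritParams coverage_fraction
#' @return Density (inverse area units of `R^2`).
#' @export
flagellar_density <- function(N, R, theta_a) {
  stopifnot(all(N > 0), all(R > 0), all(theta_a > 0), all(theta_a <= 90))
  N / (2 * pi * R^2 * (1 + cos(deg2rad(theta_a))))
}

#' Dimensionless wavenumber from measured waveform
#'
#' From the projected flagellar length and the wavelength of the projected
#' waveform, `k l / pi = 2 l / lambda`. With measurement SDs supplied, the
#' uncertainty is propagated to first order assuming independent errors.
#'
#' @param ell Projected flagellar length.
#' @param lambda Wavelength (same units).
#' @param ell_sd,lambda_sd Optional measurement SDs.
#' @return List with `kl_over_pi` and, when SDs are given, `sd_over_pi`.
#' @export
wavenumber_from_waveform <- function(ell, lambda, ell_sd = NULL,
                                     lambda_sd = NULL) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  v <- 2 * ell / lambda
  out <- list(kl_over_pi = v)
  if (!is.null(ell_sd) && !is.null(lambda_sd)) {
    out$sd_over_pi <- sqrt((2 / lambda * ell_sd)^2 +
                           (2 * ell / lambda^2 * lambda_sd)^2)
  }
  out
}

#' Hypothetical minimum chamber diameter
#'
#' The smallest chamber diameter for which adjacent flagella of beat
#' amplitude `A` do not touch. The binding constraint is at the flagellar
#' tips (radius `R - ell`), where the radial convergence makes the spacing
#' tightest; non-contact requires the nearest-neighbour tip separation to
#' reach `2 A`.
#'
#' Two packing criteria are provided: `"hex"` (default) assumes ideal
#' hexagonal packing of the `N` flagella on the available zone, giving the
#' closed form `D = 2 (ell + 2 A sqrt(sqrt(3) N / (4 pi (1 + cos
#' theta_a))))`; `"layout"` uses the minimum pairwise separation of the
#' quasi-uniform spiral lattice from [place_flagella()], which packs
#' slightly less tightly and so returns a somewhat larger diameter.
#'
#' @param N Number of flagella.
#' @param A Beat amplitude (micrometres).
#' @param ell Projected flagellar length (micrometres).
#' @param theta_a Opening angle, degrees.
#' @param method `"hex"` or `"layout"`.
#' @return Minimum chamber diameter, micrometres.
#' @export
min_chamber_diameter <- function(N, A, ell, theta_a, method = c("hex", "layout")) {
  method <- match.arg(method)
  stopifnot(N >= 2, A >= 0, ell > 0, theta_a > 0, theta_a <= 90)
  ct <- 1 + cos(deg2rad(theta_a))
  if (method == "hex") {
    r_tip <- 2 * A * sqrt(sqrt(3) * N / (4 * pi * ct))
  } else {
    u <- base_lattice(as.integer(N), theta_a)
    cmin <- min(dist(u))          # chord separation on the unit sphere
    r_tip <- 2 * A / cmin
  }
  2 * (ell + r_tip)
}

#' Convert model quantities to physical units
#'
#' Inverts the nondimensionalization `Q = Q* T / L^3` and `P = P* T / mu`:
#' with flagellar length `L_um` (micrometres), beat frequency `nu_Hz`
#' (1/T in Hz) and viscosity `mu_Pa_s`, a model flow rate maps to
#' `Q * L^3 * nu` cubic micrometres per second and a model pressure to
#' `P * mu * nu` pascals.
#'
#' @param Q,P Model flow rate / pressure (either may be `NULL`).
#' @param L_um Flagellar length in micrometres (default 13).
#' @param nu_Hz Beat frequency in Hz.
#' @param mu_Pa_s Dynamic viscosity in Pa s (default 1e-3, water).
#' @return List with `Q_um3_per_s` and/or `P_Pa`.
#' @export
dimensionalize <- function(Q = NULL, P = NULL, L_um = 13, nu_Hz,
                           mu_Pa_s = 1e-3) {
  stopifnot(L_um > 0, nu_Hz > 0, mu_Pa_s > 0)
  out <- list()
  if (!is.null(Q)) out$Q_um3_per_s <- Q * L_um^3 * nu_Hz
  if (!is.null(P)) out$P_Pa <- P * mu_Pa_s * nu_Hz
  out
}

#' Near-optimal opening-angle band
#'
#' From simulated efficiency curves `eta(theta_a)` at two or more flagellar
#' densities, finds for each density the opening-angle interval where the
#' efficiency is at least `frac` (default 0.9) of its maximum, then flags
#' each species whose (density, theta_a) pair falls inside the band
#' interpolated to the species' density.
#'
#' @param species Data frame with columns `species`, `theta_a` (degrees)
#'   and `density` (per square micrometre).
#' @param sim Data frame with columns `density`, `theta_a`, `eta` (at least
#'   two distinct densities, each with a sorted theta_a grid).
#' @param frac Fraction of the per-density maximum (default 0.9).
#' @return The species data frame with `band_lo`, `band_hi` and logical
#'   `near_optimal` columns.
#' @export
efficiency_band <- function(species, sim, frac = 0.9) {
  stopifnot(all(c("density", "theta_a", "eta") %in% names(sim)))
  dens <- sort(unique(sim$density))
  if (length(dens) < 2) stop("need eta(theta_a) curves at >= 2 densities")
  bands <- t(vapply(dens, function(dd) {
    cur <- sim[sim$density == dd, ]
    cur <- cur[order(cur$theta_a), ]
    if (nrow(cur) < 2 || any(duplicated(cur$theta_a)))
      stop("degenerate simulation surface")
    th <- seq(min(cur$theta_a), max(cur$theta_a), length.out = 512)
    et <- approx(cur$theta_a, cur$eta, th)$y
    ok <- which(et >= frac * max(et))
    c(lo = th[min(ok)], hi = th[max(ok)])
  }, numeric(2)))
  lo <- approx(dens, bands[, "lo"], species$density, rule = 2)$y
  hi <- approx(dens, bands[, "hi"], species$density, rule = 2)$y
  species$band_lo <- lo
  species$band_hi <- hi
  species$near_optimal <- species$theta_a >= lo & species$theta_a <= hi
  species
}

#' Compiled chamber morphometry across sponge species
#'
#' Loads the packaged table of published choanocyte-chamber measurements
#' (chamber diameter, apopyle diameter or area, choanocyte counts, and the
#' reported opening angle) and appends derived columns: the opening angle
#' recomputed with [opening_angle()], and where the inputs allow it the
#' flagellar number density.
#'
#' @param path Optional path to a CSV in the same schema (default: the
#'   packaged table).
#' @return Data frame, one row per species.
#' @export
morphometry_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "chamber_morphometry.csv",
                        package = "choanopump")
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "chamber_diameter_um")
  if (!all(need %in% names(x)))
    stop("morphometry CSV must contain at least: ", paste(need, collapse = ", "))
  d <- ifelse(is.na(x$apopyle_diameter_um) & !is.na(x$apopyle_area_um2),
              2 * sqrt(x$apopyle_area_um2 / pi), x$apopyle_diameter_um)
  x$theta_a_derived <- ifelse(is.na(d), NA_real_,
                              rad2deg(asin(d / x$chamber_diameter_um)))
  th <- ifelse(is.na(x$theta_a_derived), x$theta_a_reported, x$theta_a_derived)
  x$density_derived <- ifelse(
    is.na(x$choanocytes_per_chamber) | is.na(th), NA_real_,
    flagellar_density(x$choanocytes_per_chamber,
                      x$chamber_diameter_um / 2, th))
  x
}

#' Write a morphometry table
#'
#' @param x Data frame in the [morphometry_table()] schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
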