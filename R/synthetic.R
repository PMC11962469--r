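#' Synthetic morphometry specification
#'
#' Mean/SD pairs for per-chamber measurements, defaulting to the measured
#' values for *Ephydatia muelleri*: chamber diameter 34.7 +/- 5.0 um,
#' apopyle diameter 18.1 +/- 4.3 um, 112 +/- 31 choanocytes, beat frequency
#' 26.1 +/- 8.9 Hz, amplitude 1.58 +/- 0.21 um, projected length 9.83 +/-
#' 0.74 um, wavelength 5.98 +/- 0.48 um, flagellar length 12.9 +/- 1.1 um.
#' Samples are truncated-normal (all quantities positive) with the apopyle
#' smaller than the chamber enforced by rejection; the published tables
#' report only means +/- SD, so normality is an assumption.
#'
#' @param n_chambers Number of chambers to generate.
#' @param D,d,N,L,ell,lambda,A,nu `c(mean, sd)` pairs (micrometres, counts,
#'   Hz).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chambers = 100,
                           D = c(34.7, 5.0), d = c(18.1, 4.3),
                           N = c(112, 31), L = c(12.9, 1.1),
                           ell = c(9.83, 0.74), lambda = c(5.98, 0.48),
                           A = c(1.58, 0.21), nu = c(26.1, 8.9),
                           seed = 1L) {
  pars <- list(D = D, d = d, N = N, L = L, ell = ell, lambda = lambda,
               A = A, nu = nu)
  for (nm in names(pars)) {
    p <- pars[[nm]]
    if (length(p) != 2 || p[1] <= 0 || p[2] < 0)
      stop("each parameter needs c(mean > 0, sd >= 0): ", nm)
  }
  if (d[1] >= D[1]) stop("infeasible spec: mean apopyle exceeds mean chamber")
  structure(c(pars, list(n_chambers = as.integer(n_chambers),
                         seed = as.integer(seed))),
            class = "synthetic_spec")
}

rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Generate a synthetic morphometry table
#'
#' Draws a reproducible per-chamber table emulating microscopy
#' measurements, with derived columns (opening angle, flagellar density,
#' coverage fraction) appended. With all SDs zero every row equals the
#' means.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame with one row per chamber.
#' @export
generate_morphometry <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_chambers
  with_seed(spec$seed, {
    D <- rtruncnorm_pos(n, spec$D[1], spec$D[2])
    d <- rtruncnorm_pos(n, spec$d[1], spec$d[2])
    bad <- which(d >= D)
    while (length(bad)) {
      D[bad] <- rtruncnorm_pos(length(bad), spec$D[1], spec$D[2])
      d[bad] <- rtruncnorm_pos(length(bad), spec$d[1], spec$d[2])
      bad <- bad[d[bad] >= D[bad]]
    }
    out <- data.frame(
      chamber = seq_len(n),
      chamber_diameter_um = D,
      apopyle_diameter_um = d,
      choanocytes_per_chamber = round(rtruncnorm_pos(n, spec$N[1], spec$N[2])),
      flagellar_length_um = rtruncnorm_pos(n, spec$L[1], spec$L[2]),
      projected_length_um = rtruncnorm_pos(n, spec$ell[1], spec$ell[2]),
      wavelength_um = rtruncnorm_pos(n, spec$lambda[1], spec$lambda[2]),
      amplitude_um = rtruncnorm_pos(n, spec$A[1], spec$A[2]),
      beat_frequency_hz = rtruncnorm_pos(n, spec$nu[1], spec$nu[2]))
    out
  }) -> out
  out$theta_a_deg <- opening_angle(out$chamber_diameter_um,
                                   out$apopyle_diameter_um)
  out$density_per_um2 <- flagellar_density(out$choanocytes_per_chamber,
                                           out$chamber_diameter_um / 2,
                                           out$theta_a_deg)
  out$phi <- coverage_fraction(out$choanocytes_per_chamber,
                               out$amplitude_um,
                               out$chamber_diameter_um / 2,
                               out$theta_a_deg)
  out
}

#' Generate noisy flagellar waveform tracks
#'
#' Samples the node positions of one beating flagellum over a full period
#' in its beat-plane frame (base at the origin, x along the flagellar axis,
#' y transverse) and adds isotropic Gaussian positional noise, emulating
#' point tracks extracted from high-speed imaging.
#'
#' @param params A [waveform_params()].
#' @param noise_sd Positional noise SD (units of L).
#' @param seed Integer seed.
#' @param n_steps Frames per period (default 50).
#' @return Data frame with columns `flagellum`, `node`, `t`, `x`, `y`, `z`.
#' @export
generate_waveform_tracks <- function(params, noise_sd = 0, seed = 1L,
                                     n_steps = 50L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  entry <- list(base = c(0, 0, 0), e1 = c(1, 0, 0), e2 = c(0, 1, 0), phi = 0)
  ts <- (seq_len(n_steps) - 1) / n_steps
  rows <- lapply(ts, function(t0) {
    st <- flagellum_state(entry, params, t0)
    data.frame(flagellum = 1L, node = seq_len(nrow(st$positions)), t = t0,
               x = st$positions[, 1], y = st$positions[, 2],
               z = st$positions[, 3])
  })
  out <- do.call(rbind, rows)
  if (noise_sd > 0) {
    out[, c("x", "y", "z")] <- out[, c("x", "y", "z")] +
      with_seed(seed, matrix(rnorm(3 * nrow(out), 0, noise_sd), ncol = 3))
  }
  out
}

#' Estimate waveform parameters from node tracks
#'
#' Recovers the flagellar arc length, projected length, amplitude,
#' wavelength and dimensionless wavenumber from node tracks (as produced by
#' [generate_waveform_tracks()] or extracted from imaging). The wavenumber
#' comes from phase regression: the first temporal Fourier harmonic of each
#' segment's tangent angle has a phase linear in arc length with slope
#' `-k`; the wavelength is the mean axial wavelength `2 pi ell / (k L)`,
#' so that `2 ell / lambda` reproduces the dimensionless wavenumber.
#'
#' @param tracks Data frame with columns `node`, `t`, `x`, `y`.
#' @return List with `L`, `ell`, `A`, `lambda`, `kl_over_pi`.
#' @export
estimate_waveform <- function(tracks) {
  ts <- sort(unique(tracks$t))
  nodes <- sort(unique(tracks$node))
  nt <- length(ts); nn <- length(nodes)
  X <- matrix(tracks$x[order(tracks$t, tracks$node)], nn, nt)
  Y <- matrix(tracks$y[order(tracks$t, tracks$node)], nn, nt)
  dx <- X[-1, , drop = FALSE] - X[-nn, , drop = FALSE]
  dy <- Y[-1, , drop = FALSE] - Y[-nn, , drop = FALSE]
  seg <- sqrt(dx^2 + dy^2)
  L_hat <- mean(colSums(seg))
  ell_hat <- mean(X[nn, ] - X[1, ])
  A_hat <- max(abs(Y))
  tau <- atan2(dy, dx)                     # segments x times
  har <- tau %*% exp(-2i * pi * ts)        # first temporal harmonic
  phase <- Arg(har)
  # unwrap
  for (j in 2:length(phase)) {
    while (phase[j] - phase[j - 1] > pi) phase[j] <- phase[j] - 2 * pi
    while (phase[j] - phase[j - 1] < -pi) phase[j] <- phase[j] + 2 * pi
  }
  s_mid <- (c(0, cumsum(rowMeans(seg)))[-(nn)] + cumsum(rowMeans(seg))) / 2
  k_hat <- -stats::coef(stats::lm(phase ~ s_mid))[[2]]
  kl <- k_hat * L_hat
  list(L = L_hat, ell = ell_hat, A = A_hat,
       lambda = 2 * pi * ell_hat / kl, kl_over_pi = kl / pi)
}

#' Write waveform tracks as CSV
#'
#' @param tracks Data frame from [generate_waveform_tracks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}
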