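#' Flagellar waveform parameters
#'
#' Defines the planar traveling-wave beat of a flagellum of arc length
#' `L` (= 1 in model units) with angular frequency `omega` (= 2 pi, so the
#' beat period is T = 1). Two waveform families are available:
#'
#' * `"arclength"` (default): a tangent-angle traveling wave
#'   `tau(s, t) = Theta * cos(k s - omega t + phi)` along arc length `s`,
#'   integrated to a planar curve. Inextensible and base-clamped by
#'   construction; `Theta` is calibrated so the maximum lateral displacement
#'   equals `A`.
#' * `"projection"`: the explicit sine `y(x, t) = A g(x) sin(k x - omega t +
#'   phi)` along the projected axis, with the axial span chosen at every
#'   instant so the arc length equals `L` (nodes equally spaced in arc
#'   length). `g` is an optional clamping envelope (see `envelope`); with
#'   `envelope = "none"` the rigid transverse offset `y(0, t)` is subtracted
#'   so the base stays clamped.
#'
#' `kl` is the dimensionless wavenumber as it is measured from images:
#' `2 l / lambda` in units of `pi`, with `l` the projected flagellar length
#' and `lambda` the axial wavelength of the projected waveform. For the
#' projection family this equals `k * l` and `k` is found by solving the
#' arc-length constraint; for the arclength family the projected wavelength
#' contracts by the same factor `l / L` as the length, so the measured
#' quantity equals `k * L` and `k` is set directly. In either family,
#' because the arc length must cover the total transverse travel
#' `2 A * kl / pi`, `kl` cannot exceed about `pi * L / (2 A)` (`3.57 * pi`
#' at the default `A = 0.14`); infeasible requests are rejected.
#'
#' @param kl Target dimensionless wavenumber `k * l` (radians; e.g. `3 * pi`).
#' @param A Beat amplitude in units of `L` (maximum lateral displacement,
#'   half peak-to-peak). `A = 0` gives a straight flagellum.
#' @param n_nodes Discretization nodes per flagellum (>= 5).
#' @param family Waveform family, `"arclength"` or `"projection"`.
#' @param envelope For the projection family: `"none"` or `"exp"` (smooth
#'   growth `1 - exp(-(k x)^2)` from the base).
#' @param L Flagellar arc length (model unit, default 1).
#' @param omega Angular frequency (default `2 * pi`).
#' @return An object of class `waveform_params` with the solved `k`, the
#'   projected length `ell`, and (arclength family) the calibrated tangent
#'   amplitude `Theta`.
#' @export
waveform_params <- function(kl = 3 * pi, A = 0.14, n_nodes = 20,
                            family = c("arclength", "projection"),
                            envelope = c("none", "exp"),
                            L = 1, omega = 2 * pi) {
  family <- match.arg(family)
  envelope <- match.arg(envelope)
  if (n_nodes < 5) stop("n_nodes must be >= 5 (slender-body discretization)")
  if (A < 0) stop("A must be >= 0")
  if (kl <= 0) stop("kl must be > 0")
  if (A == 0) {
    p <- list(kl = kl, k = kl / L, ell = L, A = 0, Theta = 0,
              n_nodes = as.integer(n_nodes), family = family,
              envelope = envelope, L = L, omega = omega)
    return(structure(p, class = "waveform_params"))
  }
  infeasible_msg <- sprintf(
    paste0("requested kl = %.3g*pi is infeasible for amplitude A = %.3g: ",
           "inextensibility bounds kl below about pi*L/(2A) = %.3g*pi"),
    kl / pi, A, L / (2 * A))
  p <- list(kl = kl, A = A, n_nodes = as.integer(n_nodes), family = family,
            envelope = envelope, L = L, omega = omega)
  if (family == "arclength") {
    p$k <- kl / L
    p$Theta <- tryCatch(calibrate_theta(A, p$k, L),
                        error = function(e) stop(infeasible_msg, call. = FALSE))
  } else {
    if (kl >= pi * L / (2 * A)) stop(infeasible_msg, call. = FALSE)
    # solve k such that k * ell(k) = kl
    g <- function(k) {
      pk <- p; pk$k <- k
      k * projected_length_at_k(pk) - kl
    }
    k_lo <- kl / L            # ell <= L so k >= kl/L
    k_hi <- k_lo * 1.5
    while (g(k_hi) < 0) {
      k_hi <- k_hi * 1.4
      if (k_hi > 400) stop(infeasible_msg, call. = FALSE)
    }
    p$k <- uniroot(g, c(k_lo, k_hi), tol = 1e-10)$root
  }
  p$ell <- projected_length_at_k(p)
  structure(p, class = "waveform_params")
}

#' @export
print.waveform_params <- function(x, ...) {
  cat(sprintf("waveform_params [%s]: kl = %.4g*pi, A = %.3g, k = %.4g, ell = %.4g L\n",
              x$family, x$kl / pi, x$A, x$k, x$ell))
  invisible(x)
}

#' Projected flagellar length
#'
#' The end-to-end axial extent `l` of the undulating flagellum, which is
#' shorter than the arc length `L`. For the projection family `l` solves
#' `arclength(A sin(k x), x in [0, l]) = L` in the reference configuration
#' (t = 0 phase); for the arclength family it is the beat-phase average of
#' the axial extent. `l` decreases monotonically with `k`.
#'
#' @param params A [waveform_params()].
#' @return Projected length in units of `L`.
#' @export
projected_length <- function(params) {
  stopifnot(inherits(params, "waveform_params"))
  projected_length_at_k(params)
}

projected_length_at_k <- function(p) {
  if (p$A == 0) return(p$L)
  if (p$family == "projection") {
    f <- function(ell) {
      integrate(function(x) sqrt(1 + (p$A * p$k * cos(p$k * x))^2),
                0, ell, rel.tol = 1e-10)$value - p$L
    }
    if (f(p$L) < 0) stop("arc-length equation unsolvable: amplitude too large")
    uniroot(f, c(1e-8, p$L), tol = 1e-12)$root
  } else {
    Theta <- if (!is.null(p$Theta)) p$Theta else calibrate_theta(p$A, p$k, p$L)
    # phase-averaged axial extent of integral of cos(Theta cos(k s - c))
    s <- seq(0, p$L, length.out = 801)
    phases <- (seq_len(32) - 0.5) * 2 * pi / 32
    mean(vapply(phases, function(c0) {
      ct <- cos(Theta * cos(p$k * s - c0))
      sum((ct[-1] + ct[-length(s)]) / 2) * (s[2] - s[1])
    }, numeric(1)))
  }
}

# Calibrate the tangent-angle amplitude so max lateral displacement = A.
calibrate_theta <- function(A, k, L) {
  s <- seq(0, L, length.out = 801)
  ds <- s[2] - s[1]
  phases <- (seq_len(32) - 0.5) * 2 * pi / 32
  maxdisp <- function(Theta) {
    m <- 0
    for (c0 in phases) {
      st <- sin(Theta * cos(k * s - c0))
      y <- c(0, cumsum((st[-1] + st[-length(s)]) / 2)) * ds
      m <- max(m, max(abs(y)))
    }
    m
  }
  # small-amplitude guess 2*Theta/k = A; displacement grows with Theta
  hi <- 2.9
  if (maxdisp(hi) < A)
    stop("amplitude too large for requested wavenumber: tangent wave cannot reach it")
  uniroot(function(Th) maxdisp(Th) - A, c(1e-6, hi), tol = 1e-9)$root
}

#' Instantaneous flagellar shape and velocity
#'
#' Evaluates one flagellum's node positions and node velocities at time `t`
#' in the lab frame. The beat plane is spanned by the inward radial axis
#' (local x) and the `psi`-rotated transverse direction; the wave travels
#' base to tip (radially inward in the chamber), which sets the pumping
#' direction. The base node coincides with the base point at all times and
#' the shape is periodic with period `T = 2 pi / omega`.
#'
#' @param entry A list with `base` (3-vector), `e1` (unit inward axis),
#'   `e2` (unit transverse beat direction) and `phi` (beat phase). See
#'   [layout_entry()].
#' @param params A [waveform_params()].
#' @param t Time (units of the beat period when `omega = 2 pi`).
#' @return A list with `positions` and `velocities` (`n_nodes` x 3 matrices),
#'   arc-length quadrature weights `ds`, and `t`.
#' @export
flagellum_state <- function(entry, params, t) {
  p <- params
  n <- p$n_nodes
  sgrid <- seq(0, p$L, length.out = max(400L, 20L * n) + 1L)
  ds <- sgrid[2] - sgrid[1]
  wt <- p$omega * t - entry$phi
  if (p$A == 0) {
    xy <- cbind(sgrid, 0); vxy <- cbind(sgrid * 0, 0)
  } else if (p$family == "arclength") {
    tau <- p$Theta * cos(p$k * sgrid - wt)
    taut <- p$Theta * p$omega * sin(p$k * sgrid - wt)
    ctau <- cos(tau); stau <- sin(tau)
    x <- c(0, cumsum((ctau[-1] + ctau[-length(ctau)]) / 2)) * ds
    y <- c(0, cumsum((stau[-1] + stau[-length(stau)]) / 2)) * ds
    vxg <- -taut * stau; vyg <- taut * ctau
    vx <- c(0, cumsum((vxg[-1] + vxg[-length(vxg)]) / 2)) * ds
    vy <- c(0, cumsum((vyg[-1] + vyg[-length(vyg)]) / 2)) * ds
    xy <- cbind(x, y); vxy <- cbind(vx, vy)
  } else {
    # projection family: dense x-grid, arc-length reparameterization at each t
    xmax <- p$ell * 1.6
    xg <- seq(0, min(xmax, p$L * 1.2), length.out = length(sgrid))
    dx <- xg[2] - xg[1]
    if (p$envelope == "exp") {
      g <- 1 - exp(-(p$k * xg)^2); gp <- 2 * p$k^2 * xg * exp(-(p$k * xg)^2)
      shift <- 0; shift_t <- 0
    } else {
      g <- rep(1, length(xg)); gp <- rep(0, length(xg))
      shift <- p$A * sin(-wt); shift_t <- -p$A * p$omega * cos(-wt)
    }
    ph <- p$k * xg - wt
    y <- p$A * g * sin(ph) - shift
    y_t <- -p$A * p$omega * g * cos(ph) - shift_t
    y_x <- p$A * (gp * sin(ph) + g * p$k * cos(ph))
    y_xt <- -p$A * p$omega * (gp * cos(ph) - g * p$k * sin(ph))
    q <- sqrt(1 + y_x^2)
    s_of_x <- c(0, cumsum((q[-1] + q[-length(q)]) / 2)) * dx
    if (s_of_x[length(s_of_x)] < p$L)
      stop("internal: x-grid too short for arc length L")
    # d s / d t at fixed x, integrated: used for dx/dt at fixed s
    w <- y_x * y_xt / q
    s_t <- c(0, cumsum((w[-1] + w[-length(w)]) / 2)) * dx
    x_t <- -s_t / q
    xy <- cbind(xg, y)
    vxy <- cbind(x_t, y_x * x_t + y_t)
    attr(xy, "s") <- s_of_x   # arc length for equal-arc resampling below
  }
  s_dense <- if (p$family == "projection" && p$A > 0) attr(xy, "s") else sgrid
  s_nodes <- seq(0, p$L, length.out = n)
  px <- approx(s_dense, xy[, 1], xout = s_nodes, rule = 2)$y
  py <- approx(s_dense, xy[, 2], xout = s_nodes, rule = 2)$y
  vx <- approx(s_dense, vxy[, 1], xout = s_nodes, rule = 2)$y
  vy <- approx(s_dense, vxy[, 2], xout = s_nodes, rule = 2)$y
  pos <- matrix(entry$base, n, 3, byrow = TRUE) +
    outer(px, entry$e1) + outer(py, entry$e2)
  vel <- outer(vx, entry$e1) + outer(vy, entry$e2)
  dsn <- rep(p$L / (n - 1), n); dsn[c(1, n)] <- dsn[c(1, n)] / 2
  list(positions = pos, velocities = vel, ds = dsn, t = t)
}

#' Extract one flagellum's frame from a layout
#'
#' @param layout A [place_flagella()] result.
#' @param i Flagellum index.
#' @return A list with `base`, `e1` (inward axis), `e2` (beat direction,
#'   rotated by `psi[i]`), and `phi`.
#' @export
layout_entry <- function(layout, i) {
  e2 <- cos(layout$psi[i]) * layout$t1[i, ] + sin(layout$psi[i]) * layout$t2[i, ]
  list(base = layout$base_points[i, ], e1 = layout$radial_axes[i, ],
       e2 = e2, phi = layout$phi[i])
}

#' All flagellar nodes and velocities at one instant
#'
#' Stacks [flagellum_state()] over every flagellum of a layout.
#'
#' @param layout A [place_flagella()] result.
#' @param params A [waveform_params()].
#' @param t Time.
#' @return A list with `positions`, `velocities` (`N * n_nodes` x 3),
#'   quadrature weights `ds`, and `flagellum` index per node.
#' @export
flagella_states <- function(layout, params, t) {
  N <- layout$N; n <- params$n_nodes
  pos <- matrix(0, N * n, 3); vel <- matrix(0, N * n, 3)
  dsv <- numeric(N * n); fid <- integer(N * n)
  for (i in seq_len(N)) {
    st <- flagellum_state(layout_entry(layout, i), params, t)
    idx <- ((i - 1) * n + 1):(i * n)
    pos[idx, ] <- st$positions; vel[idx, ] <- st$velocities
    dsv[idx] <- st$ds; fid[idx] <- i
  }
  list(positions = pos, velocities = vel, ds = dsv, flagellum = fid, t = t)
}
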