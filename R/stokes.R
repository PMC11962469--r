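#' Assemble a resistance-problem scene
#'
#' Collects the collocation points of the coupled flagella + surface system:
#' regularized Stokeslets sit at every flagellar node (slender-body line
#' distribution) and at every no-slip surface-element centroid. Prescribed
#' velocities are the flagellar node velocities and zero on the surfaces.
#' The regularization length of each point is `eps_factor` times its local
#' spacing (node spacing along flagella, `sqrt(element area)` on surfaces).
#'
#' @param mesh A [build_chamber_mesh()] result, or `NULL` for free flagella.
#' @param states A [flagella_states()] result, or `NULL` for surfaces only.
#' @param eps_factor Regularization length over local spacing (default 0.5).
#' @param kernel `"free"` for unbounded fluid, `"wall"` for a no-slip plane
#'   z = 0 handled by the image system (no mesh needed for the plane).
#' @param forcing Optional known forcing: list with `points` (m x 3),
#'   `forces` (m x 3) and `eps` (length m), added to the flow before the
#'   no-slip conditions are imposed (used for the pressure-difference
#'   superposition).
#' @return An object of class `stokes_scene`.
#' @export
stokes_scene <- function(mesh = NULL, states = NULL, eps_factor = 0.5,
                         kernel = c("free", "wall"), forcing = NULL) {
  kernel <- match.arg(kernel)
  pts <- NULL; vel <- NULL; eps <- NULL; type <- NULL; wt <- NULL; fid <- NULL
  if (!is.null(states)) {
    nf <- nrow(states$positions)
    dsj <- states$ds
    pts <- states$positions; vel <- states$velocities
    eps <- eps_factor * rep(max(dsj), nf)
    type <- rep("flagellum", nf); wt <- dsj; fid <- states$flagellum
  }
  if (!is.null(mesh)) {
    keep <- mesh$region %in% noslip_regions
    ns <- sum(keep)
    pts <- rbind(pts, mesh$centroids[keep, , drop = FALSE])
    vel <- rbind(vel, matrix(0, ns, 3))
    eps <- c(eps, eps_factor * sqrt(mesh$areas[keep]))
    type <- c(type, rep("surface", ns)); wt <- c(wt, mesh$areas[keep])
    fid <- c(fid, rep(NA_integer_, ns))
  }
  if (is.null(pts)) stop("empty scene")
  structure(list(points = pts, velocities = vel, eps = eps, type = type,
                 weights = wt, flagellum = fid, kernel = kernel,
                 mesh = mesh, states = states, forcing = forcing),
            class = "stokes_scene")
}

#' Solve the resistance problem
#'
#' Given prescribed velocities at every collocation point (flagellar nodes
#' moving, surfaces at rest), solves the dense linear system of regularized
#' Stokeslets for the unknown point forces exerted on the fluid. With a
#' `forcing` term in the scene, its induced velocity is subtracted from the
#' boundary conditions first (superposition).
#'
#' @param scene A [stokes_scene()].
#' @param check_condition Estimate the reciprocal condition number (only
#'   attempted below 1500 unknowns; dense `rcond` is cubic).
#' @return An object of class `stokes_solution`: point `forces` (force on
#'   the fluid at each collocation point), the scene, and the boundary
#'   residual (max norm, relative to the velocity scale).
#' @export
solve_resistance <- function(scene, check_condition = FALSE) {
  pts <- scene$points
  n <- nrow(pts)
  A <- if (scene$kernel == "wall") cp_blake_matrix(pts, scene$eps)
       else cp_stokeslet_matrix(pts, scene$eps)
  rhs <- scene$velocities
  if (!is.null(scene$forcing)) {
    ind <- kernel_velocity(scene$kernel, scene$forcing$points,
                           scene$forcing$eps, scene$forcing$forces, pts)
    rhs <- rhs - ind
  }
  b <- as.vector(t(rhs))
  if (check_condition && 3 * n <= 1500) {
    rc <- rcond(A)
    if (rc < 1e-12)
      stop(sprintf("ill-conditioned resistance system (rcond = %.2e)", rc))
  }
  f <- tryCatch(solve(A, b), error = function(e)
    stop("singular resistance system: ", conditionMessage(e)))
  res <- max(abs(A %*% f - b))
  uscale <- max(abs(b), 1e-12)
  forces <- matrix(f, n, 3, byrow = TRUE)
  structure(list(forces = forces, points = pts, eps = scene$eps,
                 type = scene$type, weights = scene$weights,
                 flagellum = scene$flagellum, kernel = scene$kernel,
                 velocities = scene$velocities, forcing = scene$forcing,
                 residual = res / uscale, scene = scene),
            class = "stokes_solution")
}

kernel_velocity <- function(kernel, src, eps, forces, field) {
  if (kernel == "wall") cp_blake_velocity(src, eps, forces, field)
  else cp_stokeslet_velocity(src, eps, forces, field)
}

#' Evaluate the fluid velocity
#'
#' Superposes all solved singularity contributions (and any known forcing)
#' at arbitrary field points. Linear in the solution.
#'
#' @param sol A [solve_resistance()] result.
#' @param points Field points (m x 3 matrix or 3-vector).
#' @return m x 3 matrix of velocities.
#' @export
evaluate_velocity <- function(sol, points) {
  points <- rbind3(points)
  U <- kernel_velocity(sol$kernel, sol$points, sol$eps, sol$forces, points)
  if (!is.null(sol$forcing))
    U <- U + kernel_velocity(sol$kernel, sol$forcing$points, sol$forcing$eps,
                             sol$forcing$forces, points)
  U
}

#' Evaluate the fluid pressure
#'
#' Superposes the regularized point-force pressure kernels; the constant is
#' fixed by p -> 0 at infinity. Only available for the free-space kernel.
#'
#' @param sol A [solve_resistance()] result.
#' @param points Field points (m x 3 matrix or 3-vector).
#' @return Numeric vector of pressures.
#' @export
evaluate_pressure <- function(sol, points) {
  if (sol$kernel != "free")
    stop("pressure evaluation implemented for the free-space kernel only")
  points <- rbind3(points)
  P <- cp_stokeslet_pressure(sol$points, sol$eps, sol$forces, points)
  if (!is.null(sol$forcing))
    P <- P + cp_stokeslet_pressure(sol$forcing$points, sol$forcing$eps,
                                   sol$forcing$forces, points)
  P
}

rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, 1, 3) else as.matrix(x)
}

#' Net force balance of a solution
#'
#' Sum of all point forces on the fluid (flagella plus surface tractions),
#' relative to the L1 norm of the forces. Near zero for the nearly closed
#' chamber.
#'
#' @param sol A [solve_resistance()] result.
#' @return List with the net force vector and its magnitude relative to the
#'   L1 force norm.
#' @export
force_balance <- function(sol) {
  f <- sol$forces
  if (!is.null(sol$forcing)) f <- rbind(f, sol$forcing$forces)
  net <- colSums(f)
  l1 <- sum(abs(f))
  list(net = net, relative = sqrt(sum(net^2)) / max(l1, 1e-300))
}

#' Export velocity and pressure on a mid-plane grid as VTK
#'
#' Samples the solution on a regular grid in the x-z plane (the plane
#' containing the apopyle axis) and writes a legacy ASCII VTK structured
#' grid with the velocity vectors and pressure, for streamline/pressure
#' maps of the chamber cross-section.
#'
#' @param sol A [solve_resistance()] result (free-space kernel).
#' @param path Output file.
#' @param half_width Half-extent of the grid (units of L).
#' @param spacing Grid spacing (units of L).
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(sol, path, half_width = 2.5, spacing = 0.1) {
  g <- seq(-half_width, half_width, by = spacing)
  n1 <- length(g)
  grid <- as.matrix(expand.grid(x = g, y = 0, z = g))
  u <- evaluate_velocity(sol, grid)
  p <- evaluate_pressure(sol, grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "choanopump mid-plane field",
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d 1 %d", n1, n1),
               sprintf("POINTS %d double", n1 * n1)), con)
  writeLines(sprintf("%.6g %.6g %.6g", grid[, 1], grid[, 2], grid[, 3]), con)
  writeLines(c(sprintf("POINT_DATA %d", n1 * n1),
               "VECTORS velocity double"), con)
  writeLines(sprintf("%.6g %.6g %.6g", u[, 1], u[, 2], u[, 3]), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6g", p), con)
  invisible(path)
}
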