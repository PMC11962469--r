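#' Chamber specification
#'
#' Collects the geometric parameters of a model choanocyte chamber. All
#' lengths are in units of the flagellar arc length L; `L_um` gives the
#' physical value of L for unit conversion.
#'
#' @param R Chamber radius in units of L. The study range is 1.5--3.0; any
#'   R > 1 is accepted (flagella must fit inside).
#' @param theta_a Apopyle half-opening angle in degrees, in (0, 90].
#' @param N Number of flagella (>= 1).
#' @param A Flagellar beat amplitude in units of L (maximum lateral
#'   displacement, half peak-to-peak). Used for packing checks, reticulum
#'   apertures and prosopyle exclusion zones.
#' @param prosopyle_area_fraction Prosopyle area as a fraction of the full
#'   sphere area 4 pi R^2 (target ~1e-3). With `prosopyle_mode = "total"`
#'   (default) this is the total open inlet fraction, achieved within a
#'   factor 2; with `"per_hole"` it is the area of one prosopyle (a ~2.5 um
#'   hole at R = 1.5 L with L = 13 um, inside the anatomical 1--5 um range)
#'   and as many non-overlapping holes as possible are carved away from the
#'   flagellar bases.
#' @param reticulum_offset Collar length in micrometres separating the
#'   reticulum shell from the chamber wall (default 8.2).
#' @param L_um Physical flagellum length in micrometres (default 13).
#' @param cone_present Include the cone-cell ring surface at the apopyle?
#' @param mesh_resolution Approximate number of wall triangles.
#' @param aperture_factor Radius of the circular reticulum aperture around
#'   each flagellum, in units of A (default 1.2).
#' @param spacing_safety Reject layouts whose minimum flagellar spacing is
#'   below `2 A * spacing_safety` (default 0.7).
#'
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(R = 1.5, theta_a = 30, N = 143, A = 0.14,
                         prosopyle_area_fraction = 1e-3,
                         prosopyle_mode = c("total", "per_hole"),
                         reticulum_offset = 8.2, L_um = 13,
                         cone_present = TRUE, mesh_resolution = 500,
                         aperture_factor = 1.2, spacing_safety = 0.7) {
  prosopyle_mode <- match.arg(prosopyle_mode)
  stopifnot(is.numeric(R), length(R) == 1, is.numeric(theta_a), length(theta_a) == 1)
  if (R <= 1) stop("chamber radius R must exceed 1 (one flagellar length)")
  if (theta_a <= 0 || theta_a > 90) stop("theta_a must lie in (0, 90] degrees")
  if (N < 1) stop("N must be >= 1")
  r_ret <- R - reticulum_offset / L_um
  if (r_ret <= 0) stop("chamber too small for collar length: reticulum radius <= 0")
  if (r_ret >= R) stop("reticulum radius must be < R")
  structure(list(R = R, theta_a = theta_a, N = as.integer(N), A = A,
                 prosopyle_area_fraction = prosopyle_area_fraction,
                 prosopyle_mode = prosopyle_mode,
                 reticulum_offset = reticulum_offset, L_um = L_um,
                 cone_present = isTRUE(cone_present),
                 mesh_resolution = mesh_resolution,
                 aperture_factor = aperture_factor,
                 spacing_safety = spacing_safety),
            class = "chamber_spec")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("chamber_spec: R = %.3g L, theta_a = %.3g deg, N = %d, A = %.3g L\n",
              x$R, x$theta_a, x$N, x$A))
  cat(sprintf("  reticulum radius = %.4g L, target prosopyle fraction = %.2g\n",
              reticulum_radius(x), x$prosopyle_area_fraction))
  invisible(x)
}

#' Reticulum shell radius
#'
#' The reticulum is modelled as a concentric no-slip shell a constant collar
#' length inside the chamber wall: radius `R - reticulum_offset / L_um` in
#' units of L.
#'
#' @param spec A [chamber_spec()].
#' @return Radius in units of L.
#' @export
reticulum_radius <- function(spec) spec$R - spec$reticulum_offset / spec$L_um

# ---------------------------------------------------------------------------
# Triangulated spherical-zone meshes.
# ---------------------------------------------------------------------------

# Zipper triangulation between two vertex rings given by azimuth angle
# vectors; returns index triples into c(idxA, idxB).
ring_strip <- function(idxA, angA, idxB, angB) {
  mA <- length(idxA); mB <- length(idxB)
  # unwrap both rings starting from their smallest angle
  oA <- order(angA); idxA <- idxA[oA]; angA <- angA[oA]
  oB <- order(angB); idxB <- idxB[oB]; angB <- angB[oB]
  tri <- matrix(0L, mA + mB, 3)
  pa <- 1L; pb <- 1L; k <- 0L
  nextA <- function(p) if (p < mA) angA[p + 1] else angA[1] + 2 * pi
  nextB <- function(p) if (p < mB) angB[p + 1] else angB[1] + 2 * pi
  while (pa <= mA || pb <= mB) {
    advA <- if (pa > mA) FALSE
            else if (pb > mB) TRUE
            else nextA(pa) <= nextB(pb)
    k <- k + 1L
    if (advA) {
      a2 <- if (pa < mA) pa + 1L else 1L
      tri[k, ] <- c(idxA[pa], idxA[a2], idxB[if (pb <= mB) pb else 1L])
      pa <- pa + 1L
    } else {
      b2 <- if (pb < mB) pb + 1L else 1L
      tri[k, ] <- c(idxA[if (pa <= mA) pa else 1L], idxB[b2], idxB[pb])
      pb <- pb + 1L
    }
    if (k >= mA + mB) break
  }
  tri[seq_len(k), , drop = FALSE]
}

# Latitude-band triangulation of the spherical zone theta in [theta0, theta1]
# at given radius. Poles (sin theta ~ 0) collapse to a single vertex fan.
zone_mesh <- function(radius, theta0, theta1, dtheta) {
  stopifnot(theta1 > theta0)
  n_theta <- max(3L, ceiling((theta1 - theta0) / dtheta))
  thetas <- seq(theta0, theta1, length.out = n_theta + 1)
  dth <- thetas[2] - thetas[1]
  verts <- NULL
  rings <- vector("list", n_theta + 1)
  angs <- vector("list", n_theta + 1)
  nv <- 0L
  for (j in seq_along(thetas)) {
    th <- thetas[j]
    if (sin(th) < 1e-9) {
      z <- radius * cos(th)
      verts <- rbind(verts, c(0, 0, z))
      nv <- nv + 1L
      rings[[j]] <- nv; angs[[j]] <- 0
    } else {
      m <- max(6L, round(2 * pi * sin(th) / dth))
      a <- (seq_len(m) - 1 + 0.5 * (j %% 2)) * 2 * pi / m
      verts <- rbind(verts, cbind(radius * sin(th) * cos(a),
                                  radius * sin(th) * sin(a),
                                  radius * cos(th)))
      rings[[j]] <- nv + seq_len(m); angs[[j]] <- a
      nv <- nv + m
    }
  }
  tris <- NULL
  for (j in seq_len(n_theta)) {
    ia <- rings[[j]]; ib <- rings[[j + 1]]
    if (length(ia) == 1L) {
      m <- length(ib)
      tris <- rbind(tris, cbind(ia, ib[c(2:m, 1)], ib))
    } else if (length(ib) == 1L) {
      m <- length(ia)
      tris <- rbind(tris, cbind(ia, ia[c(2:m, 1)], ib))
    } else {
      tris <- rbind(tris, ring_strip(ia, angs[[j]], ib, angs[[j + 1]]))
    }
  }
  list(vertices = verts, triangles = tris)
}

# Conical frustum along the cone theta = theta_a between radial distances
# r0 < r1 from the origin.
cone_mesh <- function(r0, r1, theta_a, dtheta) {
  n_r <- max(2L, ceiling((r1 - r0) / (dtheta * (r0 + r1) / 2)))
  rs <- seq(r0, r1, length.out = n_r + 1)
  st <- sin(theta_a); ct <- cos(theta_a)
  verts <- NULL; rings <- vector("list", n_r + 1); angs <- vector("list", n_r + 1)
  nv <- 0L
  for (j in seq_along(rs)) {
    m <- max(6L, round(2 * pi * rs[j] * st / (dtheta * (r0 + r1) / 2)))
    a <- (seq_len(m) - 1 + 0.5 * (j %% 2)) * 2 * pi / m
    verts <- rbind(verts, cbind(rs[j] * st * cos(a), rs[j] * st * sin(a),
                                rs[j] * ct))
    rings[[j]] <- nv + seq_len(m); angs[[j]] <- a
    nv <- nv + m
  }
  tris <- NULL
  for (j in seq_len(n_r))
    tris <- rbind(tris, ring_strip(rings[[j]], angs[[j]],
                                   rings[[j + 1]], angs[[j + 1]]))
  list(vertices = verts, triangles = tris)
}

# Per-triangle centroids, areas, unit normals (oriented radially outward
# from the origin where possible).
tri_geometry <- function(vertices, triangles) {
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  cen <- (v1 + v2 + v3) / 3
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(nrm^2))
  area <- a2 / 2
  nrm <- nrm / a2
  flip <- rowSums(nrm * cen) < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  list(centroids = cen, areas = area, normals = nrm)
}

# Quasi-uniform base-point lattice on the zone theta in (theta_a, pi]:
# a Fibonacci (golden-angle) spiral restricted to the available zone.
# Deterministic in (N, theta_a); N = 1 sits at the pole opposite the apopyle.
base_lattice <- function(N, theta_a_deg) {
  tha <- deg2rad(theta_a_deg)
  if (N == 1L) return(matrix(c(0, 0, -1), 1, 3))
  zmax <- cos(tha)
  z <- zmax - (seq_len(N) - 0.5) * (1 + zmax) / N
  golden <- pi * (3 - sqrt(5))
  a <- (seq_len(N) - 1) * golden
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(a), s * sin(a), z)
}

#' Place flagella on the chamber wall
#'
#' Distributes `N` flagellar base points quasi-uniformly (golden-angle
#' spiral) on the spherical zone outside the apopyle cap, with each flagellum
#' directed toward the chamber center. Beat-plane rotation angles `psi` and
#' beat phases `phi` are drawn uniformly on `[0, 2*pi)` from the seeded
#' generator, so ensemble realizations differ only in the seed; the base
#' lattice itself is deterministic.
#'
#' @param spec A [chamber_spec()].
#' @param seed Integer seed for the phases and beat-plane angles.
#' @return An object of class `flagellum_layout` with base points (rows, at
#'   radius R), inward radial axes, beat-plane frames, `psi`, `phi` and the
#'   seed.
#' @export
place_flagella <- function(spec, seed = 1L) {
  u <- base_lattice(spec$N, spec$theta_a)
  base <- spec$R * u
  axes <- -u                              # inward
  # minimum geodesic spacing check (overpacking guard)
  if (spec$N > 1L) {
    ch <- as.matrix(dist(base))
    diag(ch) <- Inf
    dmin <- spec$R * 2 * asin(pmin(1, min(ch) / (2 * spec$R)))
    if (dmin < 2 * spec$A * spec$spacing_safety)
      stop(sprintf(paste0("overpacked layout: minimum flagellar spacing %.3g L ",
                          "is below %.3g L (2A x safety)"),
                   dmin, 2 * spec$A * spec$spacing_safety))
  }
  # beat-plane frame: t1, t2 orthogonal to the axis
  ref <- matrix(rep(c(0, 0, 1), spec$N), ncol = 3, byrow = TRUE)
  par <- abs(rowSums(axes * ref)) > 0.99
  ref[par, ] <- matrix(rep(c(1, 0, 0), sum(par)), ncol = 3, byrow = TRUE)
  t1 <- cross3(axes, ref)
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cross3(axes, t1)
  ang <- with_seed(seed, list(psi = runif(spec$N, 0, 2 * pi),
                              phi = runif(spec$N, 0, 2 * pi)))
  structure(list(base_points = base, radial_axes = axes, t1 = t1, t2 = t2,
                 psi = ang$psi, phi = ang$phi, rng_seed = as.integer(seed),
                 N = spec$N, R = spec$R, theta_a = spec$theta_a),
            class = "flagellum_layout")
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Build the triangulated chamber scene
#'
#' Constructs the no-slip surfaces of the model chamber: the spherical wall
#' zone outside the apopyle cap with prosopyle perforations carved out, the
#' concentric reticulum shell with one circular aperture per flagellum, and
#' the cone-cell frustum joining the reticulum rim to the chamber rim at the
#' apopyle. A spherical-cap mesh spanning the apopyle (`apopyle_surface`) is
#' included for flux integration only and carries no boundary condition;
#' the removed prosopyle patches are likewise retained (region `prosopyle`)
#' for inlet-flux integration.
#'
#' Prosopyles are realized by removing randomly chosen wall triangles
#' (seeded, reproducible), excluding triangles near flagellar bases, until
#' the target open-area fraction is met.
#'
#' @param spec A [chamber_spec()].
#' @param prosopyle_seed Seed for the prosopyle carving (fixed by default so
#'   that ensemble members share one chamber geometry).
#' @return An object of class `chamber_mesh`: vertices, triangle index
#'   triples, per-triangle `region` (wall | reticulum | cone |
#'   apopyle_surface | prosopyle), centroids, areas, outward normals, the
#'   achieved prosopyle fraction, and the spec.
#' @export
build_chamber_mesh <- function(spec, prosopyle_seed = 1L) {
  tha <- deg2rad(spec$theta_a)
  R <- spec$R
  r_ret <- reticulum_radius(spec)
  # angular resolution from the wall triangle budget
  dtheta <- sqrt(4 * pi * (1 + cos(tha)) / spec$mesh_resolution)
  wall <- zone_mesh(R, tha, pi, dtheta)
  gw <- tri_geometry(wall$vertices, wall$triangles)

  # --- prosopyles: carve wall openings away from flagellar bases (seeded)
  base <- R * base_lattice(spec$N, spec$theta_a)
  keep_clear <- 1.2 * spec$A             # clearance around bases
  nT <- nrow(wall$triangles)
  dbase <- cp_min_dist(base, gw$centroids)
  if (spec$prosopyle_mode == "total") {
    target <- spec$prosopyle_area_fraction * 4 * pi * R^2
    cand <- which(dbase >= keep_clear)
    if (max(gw$areas) > 2 * target)
      stop("mesh resolution too coarse to carve prosopyles within the target band")
    cand <- with_seed(prosopyle_seed, sample(cand))
    cum <- cumsum(gw$areas[cand])
    n_rm <- which(cum >= target)[1]
    if (is.na(n_rm)) stop("not enough wall area available for prosopyles")
    pros_idx <- cand[seq_len(n_rm)]
  } else {
    # one circular hole of the target area per prosopyle, as many as fit
    r_p <- 2 * R * sqrt(spec$prosopyle_area_fraction)
    # on crowded walls prosopyles squeeze between cells: relax the base
    # clearance stepwise until at least a few sites fit
    centers <- NULL
    for (clear in keep_clear * c(1, 0.75, 0.5, 0.25)) {
      centers <- with_seed(prosopyle_seed, {
        zmax <- cos(tha); acc <- NULL
        for (i in seq_len(4000L)) {
          z <- runif(1, -1, zmax); a <- runif(1, 0, 2 * pi)
          pt <- R * c(sqrt(1 - z^2) * cos(a), sqrt(1 - z^2) * sin(a), z)
          if (min(sqrt(rowSums((base - matrix(pt, nrow(base), 3,
                                              byrow = TRUE))^2))) <
              clear + r_p) next
          if (!is.null(acc) &&
              min(sqrt(rowSums((acc - matrix(pt, nrow(acc), 3,
                                             byrow = TRUE))^2))) < 3 * r_p)
            next
          acc <- rbind(acc, pt)
        }
        acc
      })
      if (!is.null(centers) && nrow(centers) >= 3) break
    }
    if (is.null(centers)) stop("no prosopyle sites available (overpacked wall)")
    dhole <- cp_min_dist(centers, gw$centroids)
    pros_idx <- which(dhole < r_p & dbase >= clear)
    if (length(pros_idx) == 0) {
      # at coarse resolution a prosopyle is realized as one wall element:
      # take the nearest clear triangle to each hole center
      ok <- which(dbase >= clear)
      pros_idx <- unique(vapply(seq_len(nrow(centers)), function(j) {
        d <- sqrt(colSums((t(gw$centroids[ok, , drop = FALSE]) -
                             centers[j, ])^2))
        ok[which.min(d)]
      }, integer(1)))
    }
  }
  achieved <- sum(gw$areas[pros_idx]) / (4 * pi * R^2)

  region <- rep("wall", nT)
  region[pros_idx] <- "prosopyle"

  verts <- wall$vertices
  tris <- wall$triangles
  regs <- region

  # --- reticulum shell with per-flagellum apertures
  dtheta_ret <- dtheta * R / r_ret       # comparable physical element size
  ret <- zone_mesh(r_ret, tha, pi, dtheta_ret)
  gr <- tri_geometry(ret$vertices, ret$triangles)
  ubase <- base / R
  # aperture radius: the collar-tip opening each flagellum passes through;
  # capped below half the flagellar spacing at the shell so that dense
  # chambers keep a connected reticulum (collars abut, they do not merge)
  ap_rad <- spec$aperture_factor * spec$A
  if (spec$N > 1L) {
    spacing_shell <- min(dist(ubase)) * r_ret
    ap_rad <- min(ap_rad, 0.45 * spacing_shell)
  }
  keep <- vapply(seq_len(nrow(ret$triangles)), function(i) {
    c_u <- gr$centroids[i, ] / sqrt(sum(gr$centroids[i, ]^2))
    ang <- acos(pmin(1, pmax(-1, ubase %*% c_u)))
    min(ang) * r_ret > ap_rad
  }, logical(1))
  tris <- rbind(tris, ret$triangles[keep, , drop = FALSE] + nrow(verts))
  regs <- c(regs, rep("reticulum", sum(keep)))
  verts <- rbind(verts, ret$vertices)

  # --- cone-cell frustum from reticulum rim to chamber rim
  if (spec$cone_present) {
    cone <- cone_mesh(r_ret, R, tha, dtheta)
    tris <- rbind(tris, cone$triangles + nrow(verts))
    regs <- c(regs, rep("cone", nrow(cone$triangles)))
    verts <- rbind(verts, cone$vertices)
  }

  # --- apopyle flux surface: spherical cap (integration only)
  cap <- zone_mesh(R, 0, tha, min(dtheta, tha / 6))
  tris <- rbind(tris, cap$triangles + nrow(verts))
  regs <- c(regs, rep("apopyle_surface", nrow(cap$triangles)))
  verts <- rbind(verts, cap$vertices)

  g <- tri_geometry(verts, tris)
  structure(list(vertices = verts, triangles = tris, region = regs,
                 centroids = g$centroids, areas = g$areas,
                 normals = g$normals,
                 prosopyle_fraction = achieved,
                 spec = spec),
            class = "chamber_mesh")
}

#' @export
print.chamber_mesh <- function(x, ...) {
  tab <- table(x$region)
  cat("chamber_mesh:", nrow(x$triangles), "triangles\n")
  for (r in names(tab)) cat(sprintf("  %-16s %5d\n", r, tab[[r]]))
  cat(sprintf("  prosopyle open fraction: %.3g (target %.3g)\n",
              x$prosopyle_fraction, x$spec$prosopyle_area_fraction))
  invisible(x)
}

#' Total mesh area of a region
#'
#' @param mesh A [build_chamber_mesh()] result.
#' @param region Region label(s); default all no-slip regions.
#' @return Summed triangle area.
#' @export
mesh_area <- function(mesh, region = c("wall", "reticulum", "cone")) {
  sum(mesh$areas[mesh$region %in% region])
}

noslip_regions <- c("wall", "reticulum", "cone")

#' Export a mesh to Wavefront OBJ
#'
#' @param mesh A `chamber_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.8g %.8g %.8g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}

#' Export a mesh to legacy ASCII VTK
#'
#' Writes the triangulation with an integer cell field encoding the region.
#'
#' @param mesh A `chamber_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "choanopump chamber mesh",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.8g %.8g %.8g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nt, 4 * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  writeLines(c(sprintf("CELL_DATA %d", nt), "SCALARS region int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$region))), con)
  invisible(path)
}
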