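# Shared small scenes, cached per test run.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

# A small chamber: few flagella, coarse mesh; cheap enough for many tests.
small_spec <- function(...) {
  chamber_spec(N = 24, mesh_resolution = 260, prosopyle_mode = "per_hole",
               ...)
}

small_scene_solution <- function() {
  cached("small_sol", {
    sp <- small_spec()
    p <- waveform_params(kl = 3 * pi, n_nodes = 8)
    mesh <- build_chamber_mesh(sp)
    lay <- place_flagella(sp, 1)
    st <- flagella_states(lay, p, 0.3)
    sol <- solve_resistance(stokes_scene(mesh, st))
    list(spec = sp, params = p, mesh = mesh, layout = lay, states = st,
         sol = sol)
  })
}

# Unit-sphere collocation mesh (internal helpers reused across tests).
unit_sphere_points <- function(n_target = 700, a = 1) {
  sph <- choanopump:::zone_mesh(a, 1e-6, pi - 1e-6, sqrt(4 * pi * 2 / n_target))
  choanopump:::tri_geometry(sph$vertices, sph$triangles)
}
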