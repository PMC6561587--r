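# Shared helpers for the suite: tiny geometries and an analytic
# face-bookkeeping oracle for membrane areas of the composed solid.

tiny_geo <- function() {
  cell_geometry(size_O = c(16, 6, 6), size_WE = c(2, 2, 2),
                size_SN = c(4, 2, 4))
}

tiny_mesh <- function(n_cells = 2, dx = 1, dy = 1, dz = 1,
                      geo = tiny_geo(), padding = c(4, 4, 3)) {
  build_strand(geo, strand_layout(n_cells, padding = padding),
               grid_spec(dx, dy, dz))
}

# Analytic surface area (um^2) of the composed solid as meshed: bookkeeping
# of every exposed rectangle of the O/W/E/S/N cuboids.  `ends` counts how
# many cell x-end connector faces are free (not fused into a disc).
analytic_cell_area <- function(size_O, size_WE = c(0, 0, 0),
                               size_SN = c(0, 0, 0), free_w = TRUE,
                               free_e = TRUE) {
  O <- size_O; WE <- size_WE; SN <- size_SN
  a <- 2 * O[2] * O[3] + 2 * O[1] * O[2] + 2 * O[1] * O[3]
  if (WE[1] > 0) {
    # each connector: lateral faces + far face if free; its footprint is
    # carved out of the O end face
    lat <- 2 * WE[1] * WE[2] + 2 * WE[1] * WE[3]
    far_w <- if (free_w) WE[2] * WE[3] else 0
    far_e <- if (free_e) WE[2] * WE[3] else 0
    a <- a + 2 * lat + far_w + far_e - 2 * WE[2] * WE[3]
  }
  if (SN[1] > 0) {
    add <- SN[1] * SN[3] +              # outer y face
      2 * SN[1] * SN[2] +               # z-normal sides
      2 * SN[2] * SN[3]                 # x-normal sides
    a <- a + 2 * (add - 0) - 2 * SN[1] * SN[3]  # minus covered footprints
  }
  a
}

# quick deterministic run of the reduced model on a small mesh
quick_run <- function(mesh, t_end = 8, dt = 0.02, p = 0,
                      region = "horizontal_ends", params = emi_params(),
                      stim_cells = 1, probes = NULL, ...) {
  model <- reduced_test_model()
  gna <- assign_gna(mesh, channel_distribution(p, region), model)
  emi_run(mesh, model, gna, params, t_end = t_end, dt = dt,
          stimulus = stimulus_protocol(cells = stim_cells),
          probes = probes, ...)
}
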