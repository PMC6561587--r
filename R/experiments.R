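# Scripted in-silico experiments: scaled-down reproductions of the
# simulator's standard protocols, each a named function returning a tidy
# table plus metadata.  The `scale` note records how far each run sits from
# the full-resolution protocol (strand length, spacing, time step).

.default_scale <- function() {
  list(n_cells = 7, dx = 2, dy = 2, dz = 2, dt = 0.01,
       measure = c(3, 6), stim_cells = c(1, 2),
       geometry = cell_geometry())
}

# keep the measurement pair inside short strands
.fit_scale <- function(sc) {
  if (max(sc$measure) > sc$n_cells) {
    sc$measure <- c(max(2L, sc$n_cells - 2L), sc$n_cells)
  }
  sc
}

#' Conduction velocity against channel localization
#'
#' Sweeps the fraction p of sodium channels moved to the horizontal cell
#' ends along a strand and measures CV between two interior cell centers at
#' the v = 0 mV crossing.
#'
#' @param p fractions to sweep.
#' @param model ionic model (epicardial reference by default).
#' @param scale list overriding the desk-scale defaults (n_cells, dx, dy,
#'   dz, dt, measure, stim_cells).
#' @param params physical parameters.
#' @param t_end simulated time per run (ms).
#' @return data.frame(p, cv, blocked) with the scale as attribute.
#' @export
cv_vs_localization <- function(p = c(0, 0.25, 0.5, 0.75, 1),
                               model = grandi_epicardial(),
                               scale = list(), params = emi_params(),
                               t_end = 5) {
  sc <- .fit_scale(utils::modifyList(.default_scale(), scale))
  mesh <- build_strand(sc$geometry,
                       strand_layout(n_cells = sc$n_cells),
                       grid_spec(sc$dx, sc$dy, sc$dz))
  sys <- emi_assemble(mesh, params, sc$dt)
  rows <- lapply(p, function(pp) {
    gna <- assign_gna(mesh, channel_distribution(pp, "horizontal_ends"),
                      model)
    res <- emi_run(mesh, model, gna, params, t_end = t_end, dt = sc$dt,
                   stimulus = stimulus_protocol(cells = sc$stim_cells),
                   system = sys)
    cv <- conduction_velocity(res, sc$measure[1], sc$measure[2])
    data.frame(p = pp, cv = cv$cv, blocked = cv$blocked)
  })
  out <- do.call(rbind, rows)
  attr(out, "scale") <- sc
  out
}

#' Gap-junction delay against coupling resistance
#'
#' Increases R_g on one disc by the given factors and measures the delay
#' between the flanking membrane nodes for the uniform and the end-localized
#' (p = 1) distributions.
#'
#' @param factors multiplicative R_g factors for the target disc.
#' @param junction target disc index.
#' @param model ionic model.
#' @param scale scale overrides (default 7 cells; the full protocol uses 10).
#' @param t_end simulated time per run (ms).
#' @return data.frame(factor, delay_U, delay_NU, blocked_U, blocked_NU)
#' @export
delay_vs_rg <- function(factors = c(1, 10, 30, 50, 70), junction = 3,
                        model = grandi_epicardial(), scale = list(),
                        t_end = 30) {
  sc <- .fit_scale(utils::modifyList(.default_scale(), scale))
  mesh <- build_strand(sc$geometry,
                       strand_layout(n_cells = sc$n_cells),
                       grid_spec(sc$dx, sc$dy, sc$dz))
  flank <- probe_gap_flank(mesh, junction)
  gna_U <- assign_gna(mesh, channel_distribution(0), model)
  gna_NU <- assign_gna(mesh, channel_distribution(1, "horizontal_ends"),
                       model)
  rows <- lapply(factors, function(fc) {
    rgf <- rep(1, sc$n_cells - 1)
    rgf[junction] <- fc
    params <- emi_params(rg_factor = rgf)
    one <- function(gna) {
      res <- emi_run(mesh, model, gna, params, t_end = t_end, dt = sc$dt,
                     stimulus = stimulus_protocol(cells = sc$stim_cells),
                     probes = flank)
      gap_delay(res$time, res$v[, 1], res$v[, 2])
    }
    dU <- one(gna_U); dNU <- one(gna_NU)
    data.frame(factor = fc, delay_U = dU$delay, delay_NU = dNU$delay,
               blocked_U = dU$blocked, blocked_NU = dNU$blocked)
  })
  out <- do.call(rbind, rows)
  attr(out, "scale") <- sc
  out
}

#' Conduction velocity against cell length
#'
#' Varies the Omega_O length with the channel count per cell held constant
#' (conductance densities computed with the default-cell area), for the
#' uniform and end-localized distributions.  For cell lengths below 20 um
#' the Omega_S/N x-extent shrinks to (length - 6 um) so the slabs fit.
#'
#' @param lengths total cell lengths (um), connectors included.
#' @param model ionic model.
#' @param scale scale overrides.
#' @param t_end simulated time per run (ms).
#' @return data.frame(length, cv_U, cv_NU, ...block flags)
#' @export
cv_vs_cell_length <- function(lengths = c(60, 104, 150, 210),
                              model = grandi_epicardial(), scale = list(),
                              t_end = 6) {
  sc <- .fit_scale(utils::modifyList(.default_scale(), scale))
  ref_mesh <- build_strand(cell_geometry(), strand_layout(1),
                          grid_spec(sc$dx, sc$dy, sc$dz))
  A_ref <- membrane_areas(ref_mesh)$A_c[1]
  rows <- lapply(lengths, function(L) {
    LO <- L - 4  # Omega_W + Omega_E contribute 4 um
    sn_x <- if (L < 20) max(L - 6, sc$dx) else 14
    geo <- cell_geometry(size_O = c(LO, 18, 18),
                         size_WE = c(2, 14, 14),
                         size_SN = c(sn_x, 2, 14))
    mesh <- build_strand(geo, strand_layout(n_cells = sc$n_cells),
                         grid_spec(sc$dx, sc$dy, sc$dz))
    sys <- emi_assemble(mesh, emi_params(), sc$dt)
    one <- function(p) {
      dist <- rescale_for_cell_length(
        channel_distribution(p, "horizontal_ends"), A_ref)
      gna <- assign_gna(mesh, dist, model)
      res <- emi_run(mesh, model, gna, t_end = t_end, dt = sc$dt,
                     stimulus = stimulus_protocol(cells = sc$stim_cells),
                     system = sys)
      conduction_velocity(res, sc$measure[1], sc$measure[2])
    }
    u <- one(0); nu <- one(1)
    data.frame(length = L, cv_U = u$cv, cv_NU = nu$cv,
               blocked_U = u$blocked, blocked_NU = nu$blocked)
  })
  out <- do.call(rbind, rows)
  attr(out, "scale") <- sc
  out
}

# reduced two-cell cleft geometry (nanometre junction experiments):
# Omega_O 100 x 12 x 12 um, Omega_W/E (d/2) x 4 x 4 um, Omega_S/N
# 4 x 2 x 4 um, dz = 1 um, dt = 0.01 ms, x graded to d/4 in the cleft.
.cleft_mesh <- function(d_um, dx = 2, dy = 1, dz = 1, padding = c(10, 10, 4)) {
  geo <- cell_geometry(size_O = c(100, 12, 12),
                       size_WE = c(d_um / 2, 4, 4),
                       size_SN = c(4, 2, 4))
  build_strand(geo, strand_layout(2, padding = padding),
               grid_spec(dx, dy, dz))
}

# probe: first membrane node of cell 2 after the discs (on the vertical end
# face next to the junction)
.cleft_probe <- function(mesh) probe_gap_flank(mesh, 1)[["after"]]

#' Ephaptic coupling across closed gap junctions
#'
#' Two-cell reduced geometry with zero gap-junction conductance; the first
#' half of the first cell is stimulated and the potentials are recorded at
#' the first membrane node of the second cell after the closed discs.  With
#' channels on the vertical cell ends (NU) the cleft potential grows as the
#' cell distance d shrinks; for the uniform distribution it stays near flat.
#'
#' @param d cell distances to sweep (um; e.g. 0.005 for 5 nm).
#' @param distribution `"NU"` (vertical ends, p = 1) or `"U"`.
#' @param sigma_e extracellular conductivity (mS/cm).
#' @param model ionic model.
#' @param t_end simulated time (ms).
#' @param dt implicit step (ms).
#' @param dy,dz cross-section spacings (um).
#' @return data.frame(d, min_ue, max_ui, peak_v_after, propagated)
#' @export
ephaptic_closed_junction <- function(d = c(0.16, 0.08, 0.04, 0.02, 0.01,
                                           0.005),
                                     distribution = c("NU", "U"),
                                     sigma_e = 20,
                                     model = grandi_epicardial(),
                                     t_end = 12, dt = 0.01,
                                     dy = 1, dz = 1) {
  distribution <- match.arg(distribution)
  rows <- lapply(d, function(dd) {
    mesh <- .cleft_mesh(dd, dy = dy, dz = dz)
    dist <- if (distribution == "NU") {
      channel_distribution(1, "vertical_ends")
    } else channel_distribution(0)
    gna <- assign_gna(mesh, dist, model)
    params <- emi_params(sigma_e = sigma_e, rg_factor = Inf)
    probe <- .cleft_probe(mesh)
    stim <- stimulus_protocol(cells = 1,
                              x_below = mesh$cells$x_center[1])
    res <- emi_run(mesh, model, gna, params, t_end = t_end, dt = dt,
                   stimulus = stim, probes = probe)
    data.frame(d = dd,
               min_ue = min(res$ue),
               max_ui = max(res$ui),
               peak_v_after = max(res$v),
               propagated = max(res$v) > 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "distribution") <- distribution
  attr(out, "sigma_e") <- sigma_e
  out
}

#' Sodium-current dynamics against cell distance (open junctions)
#'
#' Same reduced two-cell geometry as the closed-junction protocol but with
#' the default gap-junction resistance: records I_Na, u_i and u_e at the
#' start of the second cell for each cell distance and integrates the
#' whole-cell I_Na influx of the second cell over the upstroke.
#'
#' @inheritParams ephaptic_closed_junction
#' @return data.frame(d, act_time, ui_at_activation, influx, peak_ina)
#' @export
ina_dynamics_vs_distance <- function(d = c(0.16, 0.01, 0.005),
                                     distribution = c("NU", "U"),
                                     model = grandi_epicardial(),
                                     t_end = 8, dt = 0.01,
                                     dy = 1, dz = 1) {
  distribution <- match.arg(distribution)
  rows <- lapply(d, function(dd) {
    mesh <- .cleft_mesh(dd, dy = dy, dz = dz)
    dist <- if (distribution == "NU") {
      channel_distribution(1, "vertical_ends")
    } else channel_distribution(0)
    gna <- assign_gna(mesh, dist, model)
    probe2 <- which(mesh$memb$cell == 2)
    res <- emi_run(mesh, model, gna, emi_params(), t_end = t_end, dt = dt,
                   stimulus = stimulus_protocol(
                     cells = 1, x_below = mesh$cells$x_center[1]),
                   probes = probe2, record_ina = TRUE)
    quadA <- mesh$memb$A[probe2]
    ii <- integrated_ina(res$time, res$ina, quadA)
    # activation of I_Na in cell 2: first frame where total inward current
    # exceeds 5% of its peak
    tot <- ii$total
    pk <- min(tot)
    on <- which(tot < 0.05 * pk)[1]
    act <- if (is.na(on)) NA_real_ else res$time[on]
    ui_at <- if (is.na(on)) NA_real_ else {
      jn <- which.min(mesh$memb$x[probe2])
      res$ui[on, jn]
    }
    data.frame(d = dd, act_time = act, ui_at_activation = ui_at,
               influx = ii$influx, peak_ina = pk)
  })
  out <- do.call(rbind, rows)
  attr(out, "distribution") <- distribution
  out
}

#' Conduction-velocity gap against extracellular conductivity
#'
#' Reruns the localization sweep at several sigma_e values (4 um cell
#' distance) and reports CV per (p, sigma_e) plus the maximum magnitude of
#' u_e seen at the probes, to check that the NU-U CV difference does not
#' depend on the extracellular-potential magnitude at this cell distance.
#'
#' @param sigma_e extracellular conductivities (mS/cm).
#' @param p localization fractions.
#' @param model ionic model.
#' @param scale scale overrides.
#' @param t_end simulated time per run (ms).
#' @return data.frame(sigma_e, p, cv, max_abs_ue)
#' @export
cv_vs_sigma_e <- function(sigma_e = c(10, 20, 40), p = c(0, 1),
                          model = grandi_epicardial(), scale = list(),
                          t_end = 5) {
  sc <- .fit_scale(utils::modifyList(.default_scale(), scale))
  mesh <- build_strand(sc$geometry,
                       strand_layout(n_cells = sc$n_cells),
                       grid_spec(sc$dx, sc$dy, sc$dz))
  rows <- list()
  for (se in sigma_e) {
    params <- emi_params(sigma_e = se)
    sys <- emi_assemble(mesh, params, sc$dt)
    for (pp in p) {
      gna <- assign_gna(mesh, channel_distribution(pp, "horizontal_ends"),
                        model)
      res <- emi_run(mesh, model, gna, params, t_end = t_end, dt = sc$dt,
                     stimulus = stimulus_protocol(cells = sc$stim_cells),
                     system = sys)
      cv <- conduction_velocity(res, sc$measure[1], sc$measure[2])
      rows[[length(rows) + 1L]] <- data.frame(
        sigma_e = se, p = pp, cv = cv$cv, max_abs_ue = max(abs(res$ue)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "scale") <- sc
  out
}
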