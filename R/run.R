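# High-level simulation driver: advance the split scheme from rest, record
# probe traces and optional field snapshots, return an emi_result.

#' Locate standard probe nodes
#'
#' `cell_centers`: for each cell, the membrane node nearest the cell-center
#' x at mid-y on the top z face (v is defined on the membrane, so "cell
#' center" probes sit on the membrane at the axial center).  `gap_flank`:
#' the last membrane node of cell `j` before disc j/j+1 and the first
#' membrane node of cell j+1 after it (ties broken toward mid-y, top-z).
#'
#' @param mesh an `emi_mesh`.
#' @return `probe_cell_centers`: integer vector (one membrane row per cell).
#' @export
probe_cell_centers <- function(mesh) {
  vapply(seq_len(mesh$n_cells), function(k) {
    mm <- which(mesh$memb$cell == k)
    xc <- mesh$cells$x_center[k]
    yc <- mean(range(mesh$memb$y[mm]))
    zc <- max(mesh$memb$z[mm])
    mm[which.min((mesh$memb$x[mm] - xc)^2 + (mesh$memb$y[mm] - yc)^2 +
                   (mesh$memb$z[mm] - zc)^2)]
  }, integer(1))
}

#' @rdname probe_cell_centers
#' @param junction disc index j (between cells j and j+1).
#' @export
probe_gap_flank <- function(mesh, junction) {
  if (junction < 1 || junction >= mesh$n_cells) stop("no such junction")
  pick <- function(cell, side) {
    mm <- which(mesh$memb$cell == cell)
    xx <- mesh$memb$x[mm]
    xbest <- if (side == "before") max(xx) else min(xx)
    mm <- mm[abs(xx - xbest) < 1e-9]
    yc <- mean(range(mesh$memb$y[mm])); zc <- max(mesh$memb$z[mm])
    mm[which.min((mesh$memb$y[mm] - yc)^2 + (mesh$memb$z[mm] - zc)^2)]
  }
  c(before = pick(junction, "before"), after = pick(junction + 1, "after"))
}

#' Run an EMI simulation
#'
#' Advances the coupled system from the resting state (w = 0, ionic model
#' defaults) with the two-step splitting, recording the membrane potential,
#' the two potential traces and optionally the sodium current density at the
#' probe membrane nodes every `record_every` steps.  Deterministic given its
#' arguments.
#'
#' @param mesh an `emi_mesh`.
#' @param model an `emi_ionic_model`.
#' @param gna conductance field from [assign_gna()] (or a scalar, recycled).
#' @param params an [emi_params()] object.
#' @param t_end end time (ms).
#' @param dt implicit step (ms); the ODE substep is `min(0.001, dt)`.
#' @param stimulus an [stimulus_protocol()] object or `NULL`.
#' @param probes integer vector of membrane rows to record (default: cell
#'   centers).
#' @param record_every record every n-th step.
#' @param record_ina also record I_Na at the probes.
#' @param record_balance record the per-cell discrete charge balance at
#'   every implicit step.
#' @param snapshot_times times (ms) at which to store full potential fields.
#' @param v_init optional initial membrane potential override (mV), e.g.
#'   -55 for threshold-trigger protocols (applied to v and u_i).
#' @param system optional pre-assembled `emi_system` (must match mesh,
#'   params, dt); reused across runs that share the operator.
#' @return An `emi_result`: list with `time`, `v`, `ue`, `ui` (time x probe
#'   matrices), probe metadata, optional `ina`, `balance`, `snapshots`,
#'   `final_state`, and the run configuration.
#' @export
emi_run <- function(mesh, model, gna, params = emi_params(),
                    t_end = 10, dt = 0.01,
                    stimulus = stimulus_protocol(),
                    probes = NULL, record_every = 1L,
                    record_ina = FALSE, record_balance = FALSE,
                    snapshot_times = numeric(0), v_init = NULL,
                    system = NULL) {
  nm <- length(mesh$memb$node)
  gna <- rep_len(gna, nm)
  if (is.null(system)) {
    system <- emi_assemble(mesh, params, dt)
  }
  state <- emi_init_state(system, model)
  if (!is.null(v_init)) {
    state$v[] <- v_init
    lay <- system$lay
    state$u[lay$ui[lay$ui > 0]] <- v_init
    if (length(mesh$disc$node)) {
      state$u[lay$dL[mesh$disc$node]] <- v_init
      state$u[lay$dR[mesh$disc$node]] <- v_init
    }
  }
  if (is.null(probes)) probes <- probe_cell_centers(mesh)
  stim_nodes <- NULL; stim_current <- 0; stim_window <- c(0, 0)
  if (!is.null(stimulus)) {
    stim_nodes <- mesh$memb$cell %in% stimulus$cells
    if (!is.null(stimulus$x_below)) {
      stim_nodes <- stim_nodes & mesh$memb$x < stimulus$x_below
    }
    stim_current <- stimulus$amplitude
    stim_window <- stimulus$onset + c(0, stimulus$duration)
  }
  n_steps <- as.integer(round(t_end / dt))
  rec_idx <- seq(0L, n_steps, by = record_every)
  nrec <- length(rec_idx)
  np <- length(probes)
  lay <- system$lay
  pnode <- mesh$memb$node[probes]
  Vm <- matrix(NA_real_, nrec, np)
  Ue <- matrix(NA_real_, nrec, np)
  Ui <- matrix(NA_real_, nrec, np)
  Ina <- if (record_ina) matrix(NA_real_, nrec, np) else NULL
  Bal <- if (record_balance) {
    matrix(NA_real_, n_steps, mesh$n_cells)
  } else NULL
  snaps <- list()
  times <- numeric(nrec)
  rec <- function(ri, state) {
    times[ri] <<- state$t
    Vm[ri, ] <<- state$v[probes]
    Ue[ri, ] <<- state$u[lay$ue[pnode]]
    Ui[ri, ] <<- state$u[lay$ui[pnode]]
    if (record_ina) {
      r <- model$rhs(state$v[probes],
                     state$S[probes, , drop = FALSE], gna[probes])
      Ina[ri, ] <<- r$I_Na
    }
  }
  ri <- 1L
  rec(ri, state)
  snap_steps <- unique(as.integer(round(snapshot_times / dt)))
  for (i in seq_len(n_steps)) {
    state <- emi_step(state, system, model, gna,
                      stim_current = stim_current, stim_nodes = stim_nodes,
                      stim_window = stim_window)
    if (record_balance) {
      b <- emi_membrane_current(state, system)
      Bal[i, ] <- abs(b$balance) / pmax(b$abs_total, 1e-9)
    }
    if (i %in% rec_idx) {
      ri <- ri + 1L
      rec(ri, state)
    }
    if (i %in% snap_steps) {
      snaps[[length(snaps) + 1L]] <- list(t = state$t, u = state$u,
                                          v = state$v, w = state$w)
    }
  }
  structure(list(
    time = times, v = Vm, ue = Ue, ui = Ui, ina = Ina, balance = Bal,
    probes = probes, probe_node = pnode,
    probe_x = mesh$memb$x[probes],
    snapshots = snaps, final_state = state,
    mesh = mesh, gna = gna, params = params, dt = dt, model = model$name
  ), class = "emi_result")
}

#' @export
print.emi_result <- function(x, ...) {
  cat(sprintf(
    "EMI run (%s): %.3g ms, dt = %g ms, %d probes, %d samples\n",
    x$model, max(x$time), x$dt, ncol(x$v), nrow(x$v)))
  invisible(x)
}
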