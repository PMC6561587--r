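# Membrane kinetics contract and the explicit ODE half-step of the operator
# splitting.
#
# An ionic model is a list of class "emi_ionic_model" with fields
#   name        model identifier
#   n_state     number of state variables besides v
#   state_names character vector
#   v_rest      resting membrane potential (mV)
#   gbar_na     default sodium conductance density (mS/cm^2)
#   init(n)     n x n_state matrix of default initial state
#   rhs(v, S, gna) -> list(I_ion, dS, I_Na)
# with I_ion in uA/cm^2 (outward positive), dS in 1/ms, and the fast sodium
# component I_Na separately retrievable.  Evaluation is deterministic and
# local to each node; scaling gna by c scales I_Na by c at fixed (v, S).

new_ionic_model <- function(name, state_names, v_rest, gbar_na, init, rhs) {
  structure(list(name = name, n_state = length(state_names),
                 state_names = state_names, v_rest = v_rest,
                 gbar_na = gbar_na, init = init, rhs = rhs),
            class = "emi_ionic_model")
}

#' @export
print.emi_ionic_model <- function(x, ...) {
  cat(sprintf("ionic model '%s': %d state variables, v_rest = %.2f mV, ",
              x$name, x$n_state, x$v_rest))
  cat(sprintf("gbar_Na = %g mS/cm^2\n", x$gbar_na))
  invisible(x)
}

#' Stimulus protocol
#'
#' @param amplitude stimulus current in A/F (default 80); applied as an
#'   inward current of `amplitude * C_m` uA/cm^2.
#' @param duration stimulus duration in ms.
#' @param onset stimulus onset in ms.
#' @param cells integer vector of stimulated cells (all membrane nodes of
#'   those cells receive the stimulus).
#' @param x_below optional x cut (cm): only membrane nodes with x below it
#'   are stimulated (e.g. the first half of the first cell).
#' @return An object of class `emi_stimulus`.
#' @export
stimulus_protocol <- function(amplitude = 80, duration = 1, onset = 0,
                              cells = c(1, 2), x_below = NULL) {
  structure(list(amplitude = amplitude, duration = duration, onset = onset,
                 cells = as.integer(cells), x_below = x_below),
            class = "emi_stimulus")
}

#' Explicit membrane substeps
#'
#' Advances the ionic state and, with I_m = 0, the membrane potential
#' (dv/dt = -I_ion / C_m) by m = dt/dt_ode forward-Euler substeps.  The
#' stimulus enters as an inward (negative) contribution to I_ion on the
#' stimulated nodes while the substep time lies inside the stimulus window.
#'
#' @param model an `emi_ionic_model`.
#' @param v membrane potential per node (mV).
#' @param S state matrix (nodes x n_state).
#' @param gna per-node sodium conductance density (mS/cm^2).
#' @param dt full PDE step (ms).
#' @param dt_ode substep; the default replicates min(0.001 ms, dt).
#' @param C_m membrane capacitance (uF/cm^2).
#' @param t0 time at the start of the step (ms).
#' @param stim_current stimulus amplitude (A/F), 0 for none.
#' @param stim_nodes index/logical over nodes receiving the stimulus.
#' @param stim_window c(onset, end) in ms.
#' @return list(v, S) after the substeps.
#' @export
ode_substeps <- function(model, v, S, gna, dt, dt_ode = min(0.001, dt),
                         C_m = 1, t0 = 0, stim_current = 0,
                         stim_nodes = NULL, stim_window = c(0, 0)) {
  m <- max(1L, as.integer(round(dt / dt_ode)))
  h <- dt / m
  has_stim <- stim_current != 0 && !is.null(stim_nodes)
  for (s in seq_len(m)) {
    r <- model$rhs(v, S, gna)
    I <- r$I_ion
    if (has_stim) {
      ts <- t0 + (s - 1) * h
      if (ts >= stim_window[1] && ts < stim_window[2]) {
        if (is.logical(stim_nodes)) {
          I[stim_nodes] <- I[stim_nodes] - stim_current * C_m
        } else {
          I[stim_nodes] <- I[stim_nodes] - stim_current * C_m
        }
      }
    }
    v <- v - (h / C_m) * I
    S <- S + h * r$dS
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      stop(sprintf("non-finite membrane state at node %d, t = %.4f ms",
                   bad, t0 + s * h))
    }
  }
  list(v = v, S = S)
}
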