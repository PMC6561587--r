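# Measurement pipeline: every metric is a pure function of recorded traces,
# so re-running the analysis on saved output is bit-identical.

#' Activation times
#'
#' First time each trace crosses the threshold from below, linearly
#' interpolated between the bracketing samples; `NaN` for traces that never
#' cross.
#'
#' @param time sample times (ms).
#' @param v trace matrix (time x nodes) or vector.
#' @param threshold crossing threshold (mV), 0 by default.
#' @return Numeric vector of activation times (ms).
#' @export
activation_times <- function(time, v, threshold = 0) {
  v <- as.matrix(v)
  vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    up <- which(x[-1] >= threshold & x[-length(x)] < threshold)
    if (!length(up)) {
      if (x[1] >= threshold) return(time[1])
      return(NaN)
    }
    i <- up[1]
    time[i] + (threshold - x[i]) / (x[i + 1] - x[i]) * (time[i + 1] - time[i])
  }, numeric(1))
}

#' Conduction velocity between two cell centers
#'
#' Center-to-center x-distance divided by the activation-time difference at
#' the v = 0 mV crossing, in cm/s.  Returns a `blocked` flag instead of a
#' number when either cell never activates.
#'
#' @param result an `emi_result` with cell-center probes (the default of
#'   [emi_run()]), or a list with `time`, `v`.
#' @param mesh the mesh (taken from the result when omitted).
#' @param cell_a,cell_b probe indices (cells) to measure between.
#' @param threshold crossing threshold (mV).
#' @return list(cv, dt, blocked, direction)
#' @export
conduction_velocity <- function(result, cell_a, cell_b, mesh = result$mesh,
                                threshold = 0) {
  act <- activation_times(result$time, result$v, threshold)
  ta <- act[cell_a]; tb <- act[cell_b]
  if (!is.finite(ta) || !is.finite(tb)) {
    return(list(cv = NA_real_, dt = NA_real_, blocked = TRUE,
                direction = NA_integer_))
  }
  dx <- mesh$cells$x_center[cell_b] - mesh$cells$x_center[cell_a]
  dtt <- tb - ta
  if (dtt == 0) {
    return(list(cv = Inf, dt = 0, blocked = FALSE, direction = 0L))
  }
  list(cv = abs(dx / dtt) * 1000,   # cm/ms -> cm/s
       dt = abs(dtt),
       blocked = FALSE,
       direction = as.integer(sign(dx / dtt)))
}

#' Gap-junction conduction delay
#'
#' Difference between the activation times of the last membrane node before
#' a disc and the first membrane node after it.  A downstream node that
#' never activates reports an infinite delay (propagation block).
#'
#' @param time sample times (ms).
#' @param v_before,v_after traces at the flanking nodes.
#' @param threshold crossing threshold (mV).
#' @return list(delay, blocked)
#' @export
gap_delay <- function(time, v_before, v_after, threshold = 0) {
  tb <- activation_times(time, v_before, threshold)
  ta <- activation_times(time, v_after, threshold)
  if (!is.finite(tb)) {
    return(list(delay = NA_real_, blocked = TRUE))
  }
  if (!is.finite(ta)) {
    return(list(delay = Inf, blocked = TRUE))
  }
  list(delay = ta - tb, blocked = FALSE)
}

#' Upstroke velocity
#'
#' Centered finite difference of a uniformly sampled trace and its maximum
#' (mV/ms).
#'
#' @param time sample times (ms), uniform.
#' @param v trace vector.
#' @return list(dvdt (vector, same length, one-sided at the ends), max)
#' @export
upstroke_velocity <- function(time, v) {
  n <- length(v)
  if (n < 3) stop("need at least 3 samples")
  h <- time[2] - time[1]
  dv <- numeric(n)
  dv[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  dv[1] <- (v[2] - v[1]) / h
  dv[n] <- (v[n] - v[n - 1]) / h
  list(dvdt = dv, max = max(dv))
}

#' Whole-membrane sodium current and influx
#'
#' Quadrature-weighted total I_Na over a cell membrane per recorded frame
#' (uA; negative = inward), and its trapezoidal time integral over a window
#' (charge, uA ms = nC).
#'
#' @param time frame times (ms).
#' @param ina matrix (time x membrane nodes of the cell) of I_Na densities
#'   (uA/cm^2).
#' @param A quadrature weights for those nodes (cm^2).
#' @param window integration window c(t0, t1) (ms); default all.
#' @return list(total (uA per frame), influx (nC))
#' @export
integrated_ina <- function(time, ina, A, window = range(time)) {
  tot <- as.numeric(ina %*% A)
  s <- time >= window[1] & time <= window[2]
  tt <- time[s]; yy <- tot[s]
  influx <- if (length(tt) > 1) {
    sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
  } else 0
  list(total = tot, influx = influx)
}

#' Inverse-distance fit of the cleft potential extremum
#'
#' Least-squares slope through the origin of min u_e against 1/d, for the
#' ephaptic closed-junction distance sweep: min u_e ~ a / d.
#'
#' @param d cell distances (um).
#' @param min_ue minimum extracellular potentials (mV).
#' @return list(a (mV um), fitted)
#' @export
cleft_extremum_fit <- function(d, min_ue) {
  if (length(d) < 2) stop("need at least 2 distances")
  x <- 1 / d
  a <- sum(x * min_ue) / sum(x * x)
  list(a = a, fitted = a / d)
}
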