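# Reduced three-gate excitable membrane model.
#
# A compact surrogate with cardiac-like resting potential, a fast sodium
# current with Hodgkin-Huxley m^3 h gating (kinetics of the fast I_Na of
# human ventricular models), an inward-rectifier-type background potassium
# current pinning the resting potential, and a slow delayed-rectifier gate
# for repolarization.  Meant for fast solver/fixture work; the full
# epicardial model is the physiological reference.

#' Reduced excitable test model
#'
#' Three gating states (m, h, n).  I_Na = g_Na m^3 h (v - E_Na) with
#' g_Na = 23 mS/cm^2 by default (same density as the epicardial reference
#' model so channel-distribution experiments transfer), an
#' inward-rectifier-like I_K1 and a slow repolarizing I_K.
#'
#' @return An `emi_ionic_model`.
#' @export
reduced_test_model <- function() {
  E_Na <- 65; E_K <- -87
  gbar_na <- 23
  g_K1 <- 0.62; g_K <- 0.9; g_b <- 0.05; E_b <- -20

  minf <- function(v) 1 / (1 + exp(-(56.86 + v) / 9.03))^2
  taum <- function(v) {
    0.1292 * exp(-((v + 45.79) / 15.54)^2) +
      0.06487 * exp(-((v - 4.823) / 51.12)^2)
  }
  hinf <- function(v) 1 / (1 + exp((v + 71.55) / 7.43))^2
  tauh <- function(v) {
    lo <- v < -40
    ah <- ifelse(lo, 0.057 * exp(-(v + 80) / 6.8), 0)
    bh <- ifelse(lo,
                 2.7 * exp(0.079 * v) + 3.1e5 * exp(0.3485 * v),
                 0.77 / (0.13 * (1 + exp(-(v + 10.66) / 11.1))))
    1 / (ah + bh)
  }
  ninf <- function(v) 1 / (1 + exp(-(v + 30) / 5))
  tau_n <- 90

  # resting potential: root of the steady-state whole-membrane current
  i_ss <- function(v) {
    gbar_na * minf(v)^3 * hinf(v) * (v - E_Na) +
      g_K1 * (v - E_K) / (1 + exp((v + 65) / 12)) +
      g_K * ninf(v) * (v - E_K) +
      g_b * (v - E_b)
  }
  v_rest <- stats::uniroot(i_ss, c(-95, -65), tol = 1e-10)$root

  init <- function(n) {
    v <- v_rest
    matrix(c(minf(v), hinf(v), ninf(v)), nrow = n, ncol = 3, byrow = TRUE,
           dimnames = list(NULL, c("m", "h", "n")))
  }

  rhs <- function(v, S, gna) {
    m <- S[, 1]; h <- S[, 2]; n <- S[, 3]
    I_Na <- gna * m^3 * h * (v - E_Na)
    x1 <- 1 / (1 + exp((v + 65) / 12))
    I_K1 <- g_K1 * x1 * (v - E_K)
    I_K <- g_K * n * (v - E_K)
    I_b <- g_b * (v - E_b)
    dS <- cbind((minf(v) - m) / taum(v),
                (hinf(v) - h) / tauh(v),
                (ninf(v) - n) / tau_n)
    list(I_ion = I_Na + I_K1 + I_K + I_b, dS = dS, I_Na = I_Na)
  }

  new_ionic_model("reduced", c("m", "h", "n"), v_rest, gbar_na, init, rhs)
}
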