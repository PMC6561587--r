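# Membrane models and the explicit substep integrator.

test_that("ode substeps implement forward Euler with the m = dt/dt* rule", {
  null_model <- emir:::new_ionic_model(
    "null", "s0", -80, 1,
    init = function(n) matrix(0, n, 1),
    rhs = function(v, S, gna) list(I_ion = rep(0, length(v)),
                                   dS = matrix(0, length(v), 1),
                                   I_Na = rep(0, length(v))))
  o <- ode_substeps(null_model, c(-80, -20), null_model$init(2), 1, 0.01)
  expect_identical(o$v, c(-80, -20))  # I_ion = 0 leaves v unchanged
  cst <- emir:::new_ionic_model(
    "cst", "s0", -80, 1,
    init = function(n) matrix(0, n, 1),
    rhs = function(v, S, gna) list(I_ion = rep(3, length(v)),
                                   dS = matrix(1, length(v), 1),
                                   I_Na = rep(0, length(v))))
  # one substep of size dt* = dt: v' = v - (dt*/C_m) I_ion
  o1 <- ode_substeps(cst, 0, cst$init(1), 1, dt = 0.001, dt_ode = 0.001,
                     C_m = 2)
  expect_equal(o1$v, -0.001 / 2 * 3)
  # dt = 0.01 with the default substep runs m = 10 Euler steps
  o10 <- ode_substeps(cst, 0, cst$init(1), 1, dt = 0.01)
  expect_equal(o10$v, -0.01 * 3)
  expect_equal(as.numeric(o10$S), 0.01)
})

test_that("node permutation permutes outputs identically", {
  model <- reduced_test_model()
  set.seed(7)
  v <- runif(12, -85, 20)
  S <- model$init(12) + matrix(runif(36, -0.01, 0.01), 12)
  g <- runif(12, 10, 30)
  r <- model$rhs(v, S, g)
  pm <- sample(12)
  rp <- model$rhs(v[pm], S[pm, ], g[pm])
  expect_equal(rp$I_ion, r$I_ion[pm])
  expect_equal(rp$dS, r$dS[pm, ])
})

test_that("sodium current scales linearly with g_Na at fixed state", {
  for (model in list(reduced_test_model(), grandi_epicardial())) {
    v <- c(-40, 0, 20)
    S <- model$init(3)
    r1 <- model$rhs(v, S, model$gbar_na)
    r2 <- model$rhs(v, S, 2 * model$gbar_na)
    r0 <- model$rhs(v, S, 0)
    expect_equal(r2$I_Na, 2 * r1$I_Na)
    expect_equal(r0$I_Na, rep(0, 3))
    # scaling only touches the sodium component
    expect_equal(r2$I_ion - r1$I_ion, r1$I_Na)
  }
})

test_that("the reduced model rests, fires and recovers", {
  model <- reduced_test_model()
  v <- model$v_rest; S <- model$init(1)
  # rest stability at the Euler substep
  for (i in 1:5000) {
    r <- model$rhs(v, S, model$gbar_na)
    v <- v - 0.001 * r$I_ion; S <- S + 0.001 * r$dS
  }
  expect_lt(abs(v - model$v_rest), 0.01)
  # suprathreshold step fires a regenerative upstroke
  v <- -55; S <- model$init(1)
  dvmax <- 0; vpeak <- v
  for (i in 1:4000) {
    r <- model$rhs(v, S, model$gbar_na)
    dv <- -r$I_ion
    dvmax <- max(dvmax, dv); vpeak <- max(vpeak, v)
    v <- v + 0.001 * dv; S <- S + 0.001 * r$dS
  }
  expect_gt(dvmax, 50)   # mV/ms
  expect_gt(vpeak, 10)
  # subthreshold step decays back toward rest
  v <- -75; S <- model$init(1)
  for (i in 1:4000) {
    r <- model$rhs(v, S, model$gbar_na)
    v <- v - 0.001 * r$I_ion; S <- S + 0.001 * r$dS
  }
  expect_lt(abs(v - model$v_rest), 1)
})

test_that("the epicardial model holds its resting state", {
  model <- grandi_epicardial()
  fn <- function(t, y, p) {
    r <- model$rhs(y[1], matrix(y[-1], nrow = 1), model$gbar_na)
    list(c(-r$I_ion, as.numeric(r$dS)))
  }
  y0 <- c(model$v_rest, as.numeric(model$init(1)))
  out <- deSolve::lsoda(y0, c(0, 1000), fn, NULL, rtol = 1e-8,
                        atol = 1e-10)
  rel <- abs(out[2, -1] - out[1, -1]) / pmax(abs(out[1, -1]), 1e-12)
  expect_lt(max(rel), 0.01)  # < 1% drift per variable over 1000 ms
})

test_that("the epicardial I_Na activates and inactivates under clamp", {
  model <- grandi_epicardial()
  v <- 0; S <- model$init(1)
  peak <- 0; tpeak <- NA
  for (i in 1:4000) {
    r <- model$rhs(v, S, model$gbar_na)
    S <- S + 0.001 * r$dS
    if (r$I_Na < peak) { peak <- r$I_Na; tpeak <- i * 0.001 }
  }
  expect_lt(peak, -100)      # large inward transient
  expect_lt(tpeak, 2)        # peaks within 2 ms
  expect_gt(r$I_Na, -1)      # inactivated by 4 ms
})

test_that("the epicardial model produces a ventricular action potential", {
  model <- grandi_epicardial()
  fn <- function(t, y, p) {
    r <- model$rhs(y[1], matrix(y[-1], nrow = 1), model$gbar_na)
    stim <- if (t > 1 && t < 2) -80 else 0
    list(c(-(r$I_ion + stim), as.numeric(r$dS)))
  }
  y0 <- c(model$v_rest, as.numeric(model$init(1)))
  out <- deSolve::lsoda(y0, seq(0, 400, by = 0.5), fn, NULL,
                        rtol = 1e-6, atol = 1e-8)
  v <- out[, 2]
  expect_gt(max(v), 20)                      # overshoot
  expect_lt(v[1], -80)                       # polarized rest
  apd <- local({
    vr <- v[1]; vp <- max(v)
    thr <- vp - 0.9 * (vp - vr)
    t_after <- out[out[, 1] > 5 & v < thr, 1][1]
    t_after - 2
  })
  expect_gt(apd, 150); expect_lt(apd, 350)   # epicardial APD90 range
})

test_that("halving the substep refines the single-node upstroke time", {
  model <- reduced_test_model()
  act_at <- function(h) {
    v <- -55; S <- model$init(1); t <- 0
    repeat {
      r <- model$rhs(v, S, model$gbar_na)
      v <- v - h * r$I_ion; S <- S + h * r$dS; t <- t + h
      if (v >= 0 || t > 20) break
    }
    t
  }
  a4 <- act_at(0.004); a2 <- act_at(0.002); a1 <- act_at(0.001)
  # first-order: successive differences shrink by about half
  expect_lt(abs(a2 - a1), abs(a4 - a2))
  expect_lt(abs(a4 - a1), 0.3)
})
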