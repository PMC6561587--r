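# Measurement pipeline on constructed traces.

test_that("activation times interpolate the first upward crossing", {
  t <- 0:20
  v <- -80 + 10 * t
  expect_equal(activation_times(t, v), 8)
  expect_true(is.nan(activation_times(t, rep(-80, 21))))
  # two-node fixture offset by 0.37 ms, sampled at 0.05 ms
  ts <- seq(0, 5, by = 0.05)
  up <- function(t0) -80 + 160 / (1 + exp(-(ts - t0) / 0.2))
  act <- activation_times(ts, cbind(up(2), up(2.37)))
  expect_equal(act[2] - act[1], 0.37, tolerance = 0.01)
})

test_that("conduction velocity is distance over activation-time difference", {
  # synthetic: centers 500 um apart, 1 ms apart in activation
  fake_mesh <- list(cells = list(x_center = c(0, 500e-4)))
  res <- list(time = 0:20, v = cbind(-80 + 10 * (0:20),
                                     -80 + 10 * ((0:20) - 1)),
              mesh = fake_mesh)
  cv <- conduction_velocity(res, 1, 2)
  expect_false(cv$blocked)
  expect_equal(cv$cv, 50)
  expect_equal(cv$direction, 1L)
  # reversed propagation keeps the magnitude, flags direction
  cvr <- conduction_velocity(list(time = res$time, v = res$v[, 2:1],
                                  mesh = fake_mesh), 1, 2)
  expect_equal(cvr$cv, 50)
  expect_equal(cvr$direction, -1L)
  # non-activation is reported as blocked, not as a number
  resb <- list(time = res$time, v = cbind(res$v[, 1], rep(-80, 21)),
               mesh = fake_mesh)
  expect_true(conduction_velocity(resb, 1, 2)$blocked)
})

test_that("gap delay reads the flanking activation difference", {
  t <- seq(0, 10, by = 0.01)
  up <- function(t0) -80 + 160 / (1 + exp(-(t - t0) / 0.1))
  expect_equal(gap_delay(t, up(3), up(3))$delay, 0)
  d <- gap_delay(t, up(3), up(4.2))
  expect_equal(d$delay, 1.2, tolerance = 1e-3)
  expect_false(d$blocked)
  b <- gap_delay(t, up(3), rep(-80, length(t)))
  expect_identical(b$delay, Inf)
  expect_true(b$blocked)
})

test_that("upstroke velocity matches analytic derivatives", {
  t <- seq(0, 10, by = 0.01)
  lin <- upstroke_velocity(t, -80 + 10 * t)
  expect_equal(lin$dvdt, rep(10, length(t)))
  expect_equal(lin$max, 10)
  s <- upstroke_velocity(t, 30 * sin(2 * t))
  expect_equal(s$max, 60, tolerance = 1e-3)  # amplitude x frequency
})

test_that("integrated sodium current weighs nodes by quadrature area", {
  t <- seq(0, 2, by = 0.1)
  A <- c(1e-6, 2e-6, 3e-6)
  zero <- integrated_ina(t, matrix(0, length(t), 3), A)
  expect_true(all(zero$total == 0) && zero$influx == 0)
  cst <- integrated_ina(t, matrix(-5, length(t), 3), A)
  expect_equal(cst$total, rep(-5 * sum(A), length(t)))
  expect_equal(cst$influx, -5 * sum(A) * 2)
})

test_that("cleft extremum fit recovers an inverse-distance law", {
  d <- c(0.16, 0.08, 0.04, 0.02, 0.01, 0.005)
  exact <- cleft_extremum_fit(d, -0.15 / d)
  expect_equal(exact$a, -0.15)
  set.seed(42)
  noisy <- -0.15 / d * (1 + rnorm(length(d), sd = 0.05))
  fit <- cleft_extremum_fit(d, noisy)
  expect_lt(abs(fit$a - (-0.15)) / 0.15, 0.1)
  expect_error(cleft_extremum_fit(d[1], -1), "at least 2")
})
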