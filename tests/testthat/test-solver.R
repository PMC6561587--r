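# Coupled-system assembly and the operator-splitting advance.

test_that("operator rows match the unknown-layout enumeration", {
  m <- tiny_mesh(2)
  sys <- emi_assemble(m, emi_params(), dt = 0.02, factorize = FALSE)
  n_ue <- sum(m$cls %in% c(0L, 1L, 2L, 4L))
  n_ui <- sum(m$cls %in% c(3L, 4L))
  n_d <- length(m$disc$node)
  expect_identical(sys$lay$n, n_ue + n_ui + 2L * n_d)
  expect_identical(dim(sys$A), c(sys$lay$n, sys$lay$n))
  # every unknown has exactly one equation: no empty rows or columns
  expect_true(all(Matrix::rowSums(abs(sys$A)) > 0))
  expect_true(all(Matrix::colSums(abs(sys$A)) > 0))
})

test_that("interior stencils annihilate a manufactured linear field", {
  m <- tiny_mesh(1)
  sys <- emi_assemble(m, emi_params(), dt = 0.02, factorize = FALSE)
  lay <- sys$lay
  x <- numeric(lay$n)
  # linear extracellular field in x; constant intracellular field
  xs_of <- m$xs[emir:::.node_ijk(m, seq_along(m$cls))[, 1]]
  sel_ue <- lay$ue > 0
  x[lay$ue[sel_ue]] <- 3 + 40 * xs_of[sel_ue] / max(m$xs)
  sel_ui <- lay$ui > 0
  x[lay$ui[sel_ui]] <- -20
  r <- as.numeric(sys$A %*% x)
  # second differences of a linear field vanish on any (graded) lattice
  ext_rows <- lay$ue[m$cls == 0L]
  int_rows <- lay$ui[m$cls == 3L]
  scale <- max(abs(sys$A))
  expect_lt(max(abs(r[ext_rows])) / scale, 1e-12)
  expect_lt(max(abs(r[int_rows])) / scale, 1e-12)
})

test_that("a resting strand stays at rest and respects the boundary", {
  m <- tiny_mesh(2)
  model <- reduced_test_model()
  sys <- emi_assemble(m, emi_params(), dt = 0.02)
  s <- emi_init_state(sys, model)
  gna <- rep(model$gbar_na, length(m$memb$node))
  for (i in 1:250) s <- emi_step(s, sys, model, gna)  # 5 ms
  expect_lt(max(abs(s$v - model$v_rest)), 0.5)
  expect_lt(max(abs(s$w)), 0.5)
  # Dirichlet exactness on the outer x/y boundary
  dir_u <- s$u[sys$lay$ue[m$cls == 1L]]
  expect_identical(max(abs(dir_u)), 0)
  # the state invariants v = ui - ue and w = uiL - uiR hold by construction
  mn <- m$memb$node
  expect_equal(s$v, s$u[sys$lay$ui[mn]] - s$u[sys$lay$ue[mn]])
})

test_that("stimulated two-cell strand propagates; closed junctions block", {
  m <- tiny_mesh(2)
  model <- reduced_test_model()
  gna <- assign_gna(m, channel_distribution(0), model)
  run_until <- function(rgf, t_end, dt = 0.02) {
    sys <- emi_assemble(m, emi_params(rg_factor = rgf), dt = dt)
    s <- emi_init_state(sys, model)
    stim <- m$memb$cell == 1
    a1 <- NA; a2 <- NA
    for (i in seq_len(round(t_end / dt))) {
      s <- emi_step(s, sys, model, gna, stim_current = 80,
                    stim_nodes = stim, stim_window = c(0, 1))
      if (is.na(a1) && max(s$v[m$memb$cell == 1]) > 0) a1 <- s$t
      if (is.na(a2) && max(s$v[m$memb$cell == 2]) > 0) a2 <- s$t
    }
    c(a1, a2)
  }
  a <- run_until(1, 8)
  expect_false(any(is.na(a)))
  expect_lt(a[2] - a[1], 5)      # downstream cell fires within 5 ms
  expect_gt(a[2], a[1])          # and strictly after the stimulated cell
  ab <- run_until(Inf, 30, dt = 0.05)
  expect_false(is.na(ab[1]))
  expect_true(is.na(ab[2]))      # no ephaptic rescue at a 4 um junction
})

test_that("discrete charge balance holds per cell at every implicit step", {
  m <- tiny_mesh(2)
  model <- reduced_test_model()
  sys <- emi_assemble(m, emi_params(), dt = 0.02)
  s <- emi_init_state(sys, model)
  gna <- assign_gna(m, channel_distribution(0), model)
  stim <- m$memb$cell == 1
  worst <- 0
  for (i in 1:250) {  # 5 ms spanning stimulus, upstroke and transfer
    s <- emi_step(s, sys, model, gna, stim_current = 80,
                  stim_nodes = stim, stim_window = c(0, 1))
    bal <- emi_membrane_current(s, sys)
    # relative to the total absolute interface current of the cell, with a
    # floor that keeps the resting (zero-current) state from dividing 0/0
    cur <- max(abs(bal$balance) / pmax(bal$abs_total, 1e-9))
    worst <- max(worst, cur)
  }
  expect_lt(worst, 1e-8)
})

test_that("runs are deterministic and symmetric under y/z mirroring", {
  m <- tiny_mesh(2)
  r1 <- quick_run(m, t_end = 3)
  r2 <- quick_run(m, t_end = 3)
  expect_identical(r1$v, r2$v)
  expect_identical(r1$ue, r2$ue)
  # symmetric stimulus: the membrane-potential field equals its own
  # y- and z-mirror at the final state
  model <- reduced_test_model()
  sys <- emi_assemble(m, emi_params(), dt = 0.02)
  s <- emi_init_state(sys, model)
  gna <- assign_gna(m, channel_distribution(0), model)
  for (i in 1:100) {
    s <- emi_step(s, sys, model, gna, stim_current = 80,
                  stim_nodes = m$memb$cell == 1, stim_window = c(0, 1))
  }
  ijk <- emir:::.node_ijk(m, m$memb$node)
  mirror <- function(axis) {
    n <- c(m$nx, m$ny, m$nz)[axis]
    idx <- ijk
    idx[, axis] <- n + 1L - idx[, axis]
    id <- idx[, 1] + m$nx * (idx[, 2] - 1L) + m$nx * m$ny * (idx[, 3] - 1L)
    match(id, m$memb$node)
  }
  for (axis in 2:3) {
    mm <- mirror(axis)
    expect_false(anyNA(mm))
    expect_lt(max(abs(s$v - s$v[mm])), 1e-9)
  }
})
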