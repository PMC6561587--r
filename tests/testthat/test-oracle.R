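# Sparse production solve against the independent dense reference.

test_that("sparse and dense implicit solves agree on fixtures", {
  params <- emi_params()
  dt <- 0.02
  for (name in c("cuboid1", "mini2")) {
    mesh <- emi_fixture(name, dx = if (name == "mini2") 1 else 2,
                        dy = if (name == "mini2") 1 else 2,
                        dz = if (name == "mini2") 1 else 2)
    sys <- emi_assemble(mesh, params, dt)
    nm <- length(mesh$memb$node)
    nd <- length(mesh$disc$node)
    # deterministic non-trivial post-ODE state
    v_star <- -80 + 30 * sin(seq_len(nm))
    w_n <- if (nd) 0.5 * cos(seq_len(nd)) else numeric(0)
    b <- numeric(sys$lay$n)
    b[sys$rhs_vi_rows] <- -sys$v_coefs * v_star
    b[sys$rhs_ve_rows] <- sys$v_coefs * v_star
    if (nd) {
      b[sys$rhs_wl_rows] <- -sys$w_coefs * w_n
      b[sys$rhs_wr_rows] <- sys$w_coefs * w_n
    }
    u_sparse <- as.numeric(Matrix::solve(sys$fac, sys$rsc * b))
    u_dense <- dense_reference_solve(mesh, params, dt, v_star, w_n)
    scale <- max(abs(u_dense))
    expect_lt(max(abs(u_sparse - u_dense)) / scale, 1e-10)
  }
})

test_that("zero drive yields identically zero fields", {
  mesh <- emi_fixture("cuboid1", dx = 2, dy = 2, dz = 2)
  u <- dense_reference_solve(mesh, emi_params(), 0.02,
                             rep(0, length(mesh$memb$node)), numeric(0))
  expect_equal(max(abs(u)), 0)
})

test_that("a passive two-cell strand tracks the dense stepper", {
  # passive membrane: I_ion = (v - v0)/R_m, linear, so the whole scheme is
  # linear and an independently advanced dense path must match tightly
  v0 <- -80; R_m <- 20  # kOhm cm^2 -> I in uA/cm^2 with v in mV
  passive <- emir:::new_ionic_model(
    "passive", "dummy", v0, 1,
    init = function(n) matrix(0, n, 1),
    rhs = function(v, S, gna) list(I_ion = (v - v0) / R_m,
                                   dS = matrix(0, length(v), 1),
                                   I_Na = rep(0, length(v))))
  mesh <- emi_fixture("mini2")
  params <- emi_params()
  dt <- 0.01
  sys <- emi_assemble(mesh, params, dt)
  s <- emi_init_state(sys, passive)
  nm <- length(mesh$memb$node)
  nd <- length(mesh$disc$node)
  # start displaced from equilibrium in cell 1
  s$v[mesh$memb$cell == 1] <- v0 + 25
  gna <- rep(1, nm)
  v_d <- s$v; w_d <- s$w
  lay <- sys$lay
  m_sub <- round(dt / min(0.001, dt))
  h <- dt / m_sub
  for (i in 1:10) {
    s <- emi_step(s, sys, passive, gna)
    # dense path: same splitting, independent solve
    for (k in seq_len(m_sub)) v_d <- v_d - h * (v_d - v0) / R_m
    u_d <- dense_reference_solve(mesh, params, dt, v_d, w_d)
    mn <- mesh$memb$node
    v_d <- u_d[lay$ui[mn]] - u_d[lay$ue[mn]]
    w_d <- u_d[lay$dL[mesh$disc$node]] - u_d[lay$dR[mesh$disc$node]]
    expect_lt(max(abs(s$v - v_d)), 1e-8)
    expect_lt(max(abs(s$w - w_d)), 1e-8)
  }
})
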