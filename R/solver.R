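# Coupled EMI system: assembly of the implicit operator and the two-step
# operator-splitting advance.
#
# Discrete layout: Laplace 7-point stencils (graded-spacing aware) for the
# extracellular and intracellular potentials; each membrane node carries an
# extracellular trace and an intracellular trace coupled by one-sided normal
# flux differences (flux continuity) and a backward-Euler update of
# C_m dv/dt = I_m; each disc node carries the two intracellular traces with
# C_1,2 dw/dt = I_1,2 - w/R_g.  The operator depends only on mesh, parameters
# and dt, so it is assembled and factorised once per run.

#' Physical parameters
#'
#' Defaults: sigma_i = 4 mS/cm, sigma_e = 20 mS/cm, C_m = 1 uF/cm^2,
#' C_disc = 0.5 uF/cm^2, R_g = 0.0045 kOhm cm^2.
#'
#' @param sigma_i,sigma_e intracellular / extracellular conductivity (mS/cm).
#' @param C_m membrane capacitance (uF/cm^2).
#' @param C_disc intercalated-disc capacitance (uF/cm^2).
#' @param R_g gap-junction resistance (kOhm cm^2); per-disc values are
#'   `R_g * rg_factor[j]`.
#' @param rg_factor multiplicative factor per junction (recycled); may be
#'   `Inf` for closed gap junctions.
#' @return An object of class `emi_params`.
#' @export
emi_params <- function(sigma_i = 4, sigma_e = 20, C_m = 1, C_disc = 0.5,
                       R_g = 0.0045, rg_factor = 1) {
  if (any(c(sigma_i, sigma_e, C_m, C_disc, R_g) <= 0)) {
    stop("all physical parameters must be positive")
  }
  if (any(rg_factor <= 0)) stop("rg_factor must be positive (Inf allowed)")
  structure(list(sigma_i = sigma_i, sigma_e = sigma_e, C_m = C_m,
                 C_disc = C_disc, R_g = R_g, rg_factor = rg_factor),
            class = "emi_params")
}

# Unknown layout:
#   u_e: classes EXT, DIR, NEU, MEM
#   u_i: classes INT, MEM (trace); disc nodes have two traces (L, R)
.emi_layout <- function(mesh) {
  N <- length(mesh$cls)
  ue_col <- integer(N); ui_col <- integer(N)
  dL_col <- integer(N); dR_col <- integer(N)
  has_ue <- mesh$cls %in% c(CL_EXT, CL_DIR, CL_NEU, CL_MEM)
  has_ui <- mesh$cls %in% c(CL_INT, CL_MEM)
  n_ue <- sum(has_ue); n_ui <- sum(has_ui)
  ue_col[has_ue] <- seq_len(n_ue)
  ui_col[has_ui] <- n_ue + seq_len(n_ui)
  nd <- length(mesh$disc$node)
  if (nd) {
    dL_col[mesh$disc$node] <- n_ue + n_ui + seq_len(nd)
    dR_col[mesh$disc$node] <- n_ue + n_ui + nd + seq_len(nd)
  }
  list(ue = ue_col, ui = ui_col, dL = dL_col, dR = dR_col,
       n = n_ue + n_ui + 2L * nd)
}

# column of the intracellular potential of cell `cell` at node `nb`
.ui_col_of <- function(mesh, lay, nb, cell) {
  cls <- mesh$cls[nb]
  col <- integer(length(nb))
  s <- cls %in% c(CL_INT, CL_MEM)
  col[s] <- lay$ui[nb[s]]
  if (any(mesh$c1[nb[s]] != cell[s])) {
    stop("internal error: intracellular stencil crosses a cell boundary")
  }
  sd <- cls == CL_DSC
  if (any(sd)) {
    left <- mesh$c1[nb[sd]] == cell[sd]
    col[sd] <- ifelse(left, lay$dL[nb[sd]], lay$dR[nb[sd]])
    if (any(!left & mesh$c2[nb[sd]] != cell[sd])) {
      stop("internal error: intracellular stencil crosses a cell boundary")
    }
  }
  if (any(col == 0L)) {
    stop("internal error: intracellular stencil without an unknown")
  }
  col
}

#' Assemble the implicit EMI operator
#'
#' @param mesh an `emi_mesh`.
#' @param params an [emi_params()] object.
#' @param dt implicit (PDE) time step in ms.
#' @return An object of class `emi_system` holding the sparse operator, its
#'   factorisation, the unknown layout and index maps used by [emi_step()].
#' @export
emi_assemble <- function(mesh, params, dt, factorize = TRUE) {
  stopifnot(inherits(mesh, "emi_mesh"), dt > 0)
  p <- params
  lay <- .emi_layout(mesh)
  nx <- mesh$nx; ny <- mesh$ny; nz <- mesh$nz
  off_axis <- c(1L, nx, nx * ny)
  hs <- list(mesh$hx, mesh$hy, mesh$hz)
  ns <- c(nx, ny, nz)
  ijk <- .node_ijk(mesh, seq_along(mesh$cls))

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  addt <- function(i, j, v) {
    ti <<- c(ti, i); tj <<- c(tj, j); tv <<- c(tv, v)
  }

  ## Dirichlet rows: u_e = 0
  dn <- which(mesh$cls == CL_DIR)
  addt(lay$ue[dn], lay$ue[dn], rep(1, length(dn)))

  ## Laplacian rows (extracellular incl. Neumann mirror; intracellular)
  lap_rows <- function(nodes, sigma, intra) {
    row <- if (intra) lay$ui[nodes] else lay$ue[nodes]
    cell <- if (intra) mesh$c1[nodes] else NULL
    diag_acc <- numeric(length(nodes))
    for (a in 1:3) {
      ia <- ijk[nodes, a]
      h <- hs[[a]]
      hm <- ifelse(ia > 1, h[pmax(ia - 1, 1)], NA_real_)
      hp <- ifelse(ia < ns[a], h[pmin(ia, length(h))], NA_real_)
      for (dirn in c(-1, 1)) {
        hh <- if (dirn < 0) hm else hp
        hov <- if (dirn < 0) hp else hm
        # mirrored ghost at the outer z-faces (Neumann): fold the missing
        # neighbour onto the interior one at the mirror distance
        mirr <- is.na(hh)
        hh[mirr] <- hov[mirr]
        hov[is.na(hov)] <- hh[is.na(hov)]  # mirror spacing on the ghost side
        cm <- 2 / (hh * (hh + hov))
        nb <- nodes + as.integer(dirn * off_axis[a])
        nb[mirr] <- nodes[mirr] - as.integer(dirn * off_axis[a])
        if (intra) {
          col <- .ui_col_of(mesh, lay, nb, cell)
        } else {
          # disc rim nodes carry no extracellular trace: the in-plane
          # contact at the triple line reflects (zero tangential flux)
          drop <- mesh$cls[nb] == CL_DSC
          if (any(!(mesh$cls[nb] %in% c(CL_EXT, CL_DIR, CL_NEU, CL_MEM,
                                        CL_DSC)))) {
            stop("internal error: extracellular stencil reaches an ",
                 "intracellular node")
          }
          cm[drop] <- 0
          nb[drop] <- nodes[drop]
          col <- lay$ue[nb]
        }
        addt(row, col, sigma * cm)
        diag_acc <- diag_acc + sigma * cm
      }
    }
    addt(row, row, -diag_acc)
  }
  en <- which(mesh$cls %in% c(CL_EXT, CL_NEU))
  lap_rows(en, p$sigma_e, intra = FALSE)
  inn <- which(mesh$cls == CL_INT)
  lap_rows(inn, p$sigma_i, intra = TRUE)

  ## membrane rows: conservative control-volume form.  For each membrane
  ## node, the intracellular-side inflow from all adjacent same-cell
  ## unknowns balances the capacitive membrane current A_i C_m dv/dt, and
  ## the extracellular-side inflow balances its negative:
  ##   sum_j a_j sigma_i (u_j - ui)/h_j - A_i (C_m/dt)(v - v*) = 0
  ##   sum_j a_j sigma_e (u_j - ue)/h_j + A_i (C_m/dt)(v - v*) = 0
  ## Tangential couplings run within each layer (ui-ui, ue-ue traces of
  ## adjacent membrane nodes), which is what makes the per-cell charge
  ## balance an exact algebraic identity of the solved system.
  mem <- mesh$memb
  nm <- length(mem$node)
  in_any <- mesh$c1 > 0L
  # per-node face-axis flags: TRUE when the node has a face normal to that
  # axis (its one-sided normal access runs along it)
  face_ax <- matrix(FALSE, nm, 3)
  face_ax[cbind(mesh$faces$mrow, mesh$faces$axis)] <- TRUE
  mrow_of_node <- integer(length(mesh$cls))
  mrow_of_node[mem$node] <- seq_len(nm)
  # enumerate the 6 neighbours of every membrane node.  Couplings between
  # two membrane traces are kept only when the coupling axis is a face
  # normal of at least one endpoint (corner and edge nodes reach the
  # interior through their neighbours); purely tangential trace-trace
  # contacts are dropped symmetrically, so no artificial conduction sheet
  # forms along the membrane (which would, e.g., shunt nanometre clefts).
  mem_intra <- list(row = integer(0), trace = integer(0), col = integer(0),
                    c = numeric(0), mrow = integer(0))
  for (q in seq_len(6)) {
    a <- c(1L, 1L, 2L, 2L, 3L, 3L)[q]
    dirn <- c(-1L, 1L, -1L, 1L, -1L, 1L)[q]
    nodes <- mem$node
    nb <- nodes + dirn * off_axis[a]
    ia <- ijk[nodes, a]
    h <- hs[[a]]
    hh <- if (dirn < 0) h[ia - 1L] else h[ia]
    # perpendicular column area (product of mean spacings)
    aperp <- switch(a,
                    mesh$my[ijk[nodes, 2]] * mesh$mz[ijk[nodes, 3]],
                    mesh$mx[ijk[nodes, 1]] * mesh$mz[ijk[nodes, 3]],
                    mesh$mx[ijk[nodes, 1]] * mesh$my[ijk[nodes, 2]])
    cn <- mesh$cls[nb]
    nb_mrow <- mrow_of_node[pmax(nb, 1L)]
    normal_pair <- face_ax[, a] |
      (cn == CL_MEM & nb_mrow > 0L & face_ax[pmax(nb_mrow, 1L), a])
    # intracellular-side membership: interior/membrane traces belong to
    # their c1 cell; disc nodes expose one trace per side.  A membrane
    # node of another cell (across a junction line) has no trace for this
    # cell: that contact reflects on the i-layer.
    intra_ok <- ((cn == CL_INT & mesh$c1[nb] == mem$cell) |
                   (cn == CL_MEM & mesh$c1[nb] == mem$cell & normal_pair) |
                   (cn == CL_DSC &
                      (mesh$c1[nb] == mem$cell | mesh$c2[nb] == mem$cell)))
    if (any(cn == CL_INT & mesh$c1[nb] != mem$cell)) {
      stop("internal error: membrane node adjacent to a foreign interior")
    }
    s <- which(intra_ok)
    if (length(s)) {
      col <- .ui_col_of(mesh, lay, nb[s], mem$cell[s])
      mem_intra$row <- c(mem_intra$row, lay$ui[nodes[s]])
      mem_intra$trace <- c(mem_intra$trace, lay$ui[nodes[s]])
      mem_intra$col <- c(mem_intra$col, col)
      mem_intra$c <- c(mem_intra$c, p$sigma_i * aperp[s] / hh[s])
      mem_intra$mrow <- c(mem_intra$mrow, s)
    }
    # extracellular-side couplings: outside nodes always; the ue trace of
    # an adjacent membrane node only across a shared face normal
    e <- which(!in_any[nb] | (cn == CL_MEM & normal_pair))
    if (length(e)) {
      ce <- p$sigma_e * aperp[e] / hh[e]
      addt(lay$ue[nodes[e]], lay$ue[nb[e]], ce)
      addt(lay$ue[nodes[e]], lay$ue[nodes[e]], -ce)
    }
  }
  addt(mem_intra$row, mem_intra$col, mem_intra$c)
  addt(mem_intra$row, mem_intra$trace, -mem_intra$c)
  # capacitive terms, both rows
  vw <- mem$A * p$C_m / dt
  row_i <- lay$ui[mem$node]; row_e <- lay$ue[mem$node]
  addt(row_i, lay$ui[mem$node], -vw); addt(row_i, lay$ue[mem$node], vw)
  addt(row_e, lay$ui[mem$node], vw); addt(row_e, lay$ue[mem$node], -vw)

  ## disc rows: same control-volume form per side, with the disc current
  ## (C12 dw/dt + w/Rg) as the interface sink; lateral couplings run within
  ## each side's trace layer (ui-k traces of rim membrane nodes included on
  ## the left side; the rim has no right-side trace, so those couplings
  ## reflect)
  d <- mesh$disc
  nd <- length(d$node)
  disc_intra <- list(row = integer(0), trace = integer(0), col = integer(0),
                     c = numeric(0))
  if (nd) {
    rgf <- rep_len(p$rg_factor, max(d$junction))
    G <- ifelse(is.infinite(rgf[d$junction]), 0,
                1 / (p$R_g * rgf[d$junction]))
    rL <- lay$dL[d$node]; rR <- lay$dR[d$node]
    add_disc <- function(row, trace, col, c) {
      disc_intra$row <<- c(disc_intra$row, row)
      disc_intra$trace <<- c(disc_intra$trace, trace)
      disc_intra$col <<- c(disc_intra$col, col)
      disc_intra$c <<- c(disc_intra$c, c)
    }
    # axial couplings into each cell (full column areas, matching the
    # interior stencil weights; the clipped disc area applies only to the
    # interface-current term)
    a_ax <- mesh$my[ijk[d$node, 2]] * mesh$mz[ijk[d$node, 3]]
    cinL <- .ui_col_of(mesh, lay, d$in_L, d$cellL)
    cinR <- .ui_col_of(mesh, lay, d$in_R, d$cellR)
    add_disc(rL, rL, cinL, a_ax * p$sigma_i / d$h_L)
    add_disc(rR, rR, cinR, a_ax * p$sigma_i / d$h_R)
    # in-plane disc contacts are tangential to the disc normal and are
    # reflected (no lateral conduction sheet within the zero-thickness
    # disc); current spreads through the adjoining connector volumes
    for (q in 3:6) {
      a <- c(1L, 1L, 2L, 2L, 3L, 3L)[q]
      dirn <- c(-1L, 1L, -1L, 1L, -1L, 1L)[q]
      nb <- d$node + dirn * off_axis[a]
      if (any(mesh$cls[nb] == CL_INT)) {
        stop("internal error: disc node laterally adjacent to an ",
             "interior node")
      }
    }
    addt(disc_intra$row, disc_intra$col, disc_intra$c)
    addt(disc_intra$row, disc_intra$trace, -disc_intra$c)
    # disc current terms, both rows
    dw <- d$a_col * (p$C_disc / dt + G)
    addt(rL, rL, -dw); addt(rL, rR, dw)
    addt(rR, rL, dw); addt(rR, rR, -dw)
  }

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(lay$n, lay$n))
  # row equilibration (units differ by ~1e9 between Laplacian and
  # capacitive rows); the scaled system has the same solution with
  # b scaled by the same factors
  rsc <- 1 / Matrix::rowSums(abs(A))
  As <- Matrix::Diagonal(x = rsc) %*% A
  fac <- if (factorize) {
    tryCatch(Matrix::lu(As), error = function(e) {
      stop("singular EMI operator (check boundary conditions): ",
           conditionMessage(e))
    })
  } else NULL

  structure(list(
    A = A, fac = fac, rsc = rsc, lay = lay, mesh = mesh, params = params,
    dt = dt,
    rhs_vi_rows = lay$ui[mem$node],  # intracellular-side membrane rows
    rhs_ve_rows = lay$ue[mem$node],  # extracellular-side membrane rows
    v_coefs = vw,                    # A_i C_m / dt per membrane node
    rhs_wl_rows = if (nd) lay$dL[d$node] else integer(0),
    rhs_wr_rows = if (nd) lay$dR[d$node] else integer(0),
    w_coefs = if (nd) d$a_col * p$C_disc / dt else numeric(0),
    mem_intra = mem_intra,           # flux caches for currents/balance
    disc_intra = disc_intra
  ), class = "emi_system")
}

#' Simulation state
#'
#' Creates the resting state: u_e = 0, u_i at the ionic model's resting
#' potential, v at rest on all membrane nodes, w = 0 on all disc nodes, and
#' the ionic model's default state on every membrane node.
#'
#' @param system an `emi_system`.
#' @param model an ionic model (see [grandi_epicardial()],
#'   [reduced_test_model()]).
#' @return An object of class `emi_state`.
#' @export
emi_init_state <- function(system, model) {
  mesh <- system$mesh
  lay <- system$lay
  nm <- length(mesh$memb$node)
  nd <- length(mesh$disc$node)
  u <- numeric(lay$n)
  v0 <- model$v_rest
  u[lay$ui[lay$ui > 0]] <- v0
  if (nd) {
    u[lay$dL[mesh$disc$node]] <- v0
    u[lay$dR[mesh$disc$node]] <- v0
  }
  structure(list(
    u = u,
    v = rep(v0, nm),
    w = rep(0, nd),
    S = model$init(nm),
    t = 0
  ), class = "emi_state")
}

#' One operator-splitting step
#'
#' Step 1 advances the membrane ODEs (ionic state and v, with I_m = 0) by
#' forward-Euler substeps of size `dt_ode`; step 2 performs the implicit
#' solve of the coupled potential system with I_ion = 0, restoring
#' v = u_i - u_e and the disc jump w exactly by construction.
#'
#' @param state an `emi_state`.
#' @param system an `emi_system`.
#' @param model the ionic model.
#' @param gna per-membrane-node sodium conductance density (mS/cm^2).
#' @param dt_ode ODE substep (ms); defaults to `min(0.001, dt)`.
#' @param stim_current stimulus amplitude added as inward current (A/F),
#'   applied to `stim_nodes` while `t` is inside the stimulus window.
#' @param stim_nodes logical or integer index over membrane nodes.
#' @param stim_window c(onset, end) in ms.
#' @return The advanced `emi_state`.
#' @export
emi_step <- function(state, system, model, gna,
                     dt_ode = NULL,
                     stim_current = 0, stim_nodes = NULL,
                     stim_window = c(0, 0)) {
  dt <- system$dt
  if (is.null(dt_ode)) dt_ode <- min(0.001, dt)
  in_window <- stim_current != 0 && !is.null(stim_nodes) &&
    state$t + dt > stim_window[1] && state$t < stim_window[2]
  o <- ode_substeps(model, state$v, state$S, gna, dt, dt_ode,
                    C_m = system$params$C_m, t0 = state$t,
                    stim_current = if (in_window) stim_current else 0,
                    stim_nodes = stim_nodes, stim_window = stim_window)
  ## implicit solve
  b <- numeric(system$lay$n)
  b[system$rhs_vi_rows] <- -system$v_coefs * o$v
  b[system$rhs_ve_rows] <- system$v_coefs * o$v
  if (length(system$rhs_wl_rows)) {
    b[system$rhs_wl_rows] <- -system$w_coefs * state$w
    b[system$rhs_wr_rows] <- system$w_coefs * state$w
  }
  u <- as.numeric(Matrix::solve(system$fac, system$rsc * b))
  if (!all(is.finite(u))) {
    stop(sprintf("linear solve produced non-finite values at t = %.4f ms",
                 state$t))
  }
  mesh <- system$mesh
  lay <- system$lay
  mn <- mesh$memb$node
  state$u <- u
  state$v <- u[lay$ui[mn]] - u[lay$ue[mn]]
  if (length(state$w)) {
    state$w <- u[lay$dL[mesh$disc$node]] - u[lay$dR[mesh$disc$node]]
  }
  state$S <- o$S
  state$t <- state$t + dt
  state
}

# Membrane current I_m per membrane node (uA/cm^2) — the net conduction
# inflow from the intracellular side divided by the node area — plus the
# per-cell discrete charge balance (sum of I_m A over the membrane and
# I_1,2 A over the discs of the closed intracellular boundary), which the
# conservative control-volume discretization satisfies exactly.
emi_membrane_current <- function(state, system) {
  mesh <- system$mesh
  lay <- system$lay
  u <- state$u
  mi <- system$mem_intra
  inflow_term <- mi$c * (u[mi$col] - u[mi$trace])
  inflow <- as.numeric(rowsum(inflow_term, mi$mrow))
  Im <- inflow / mesh$memb$A
  bal <- as.numeric(rowsum(inflow, mesh$memb$cell))
  abs_m <- as.numeric(rowsum(abs(inflow_term), mi$mrow))
  abs_tot <- as.numeric(rowsum(abs_m, mesh$memb$cell))
  d <- mesh$disc
  I12 <- numeric(0)
  if (length(d$node)) {
    di <- system$disc_intra
    term <- di$c * (u[di$col] - u[di$trace])
    rowL <- lay$dL[d$node]
    # inflow into the left and right side of each disc node
    key <- match(di$row, c(rowL, lay$dR[d$node]))
    nd <- length(d$node)
    side_in <- numeric(2 * nd)
    agg <- rowsum(term, key)
    side_in[as.integer(rownames(agg))] <- agg
    inL <- side_in[seq_len(nd)]; inR <- side_in[nd + seq_len(nd)]
    I12 <- inL / d$a_col
    for (k in seq_len(mesh$n_cells)) {
      sL <- d$cellL == k; sR <- d$cellR == k
      bal[k] <- bal[k] + sum(inL[sL]) + sum(inR[sR])
      abs_tot[k] <- abs_tot[k] + sum(abs(inL[sL])) + sum(abs(inR[sR]))
    }
  }
  list(Im = Im, I12 = I12, balance = bal, abs_total = abs_tot,
       balance_rel = bal / pmax(abs_tot, 1e-300))
}
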