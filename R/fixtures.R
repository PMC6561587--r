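# Deterministic fixtures and independent oracles.
#
# The dense reference assembles the same discrete equations as the sparse
# production path, but by plain scalar loops over nodes with its own unknown
# bookkeeping and a dense solve; it shares no assembly code with
# emi_assemble and exists so solver defects cannot hide in vectorised index
# arithmetic.

#' Named tiny fixtures
#'
#' Small meshes (a few thousand nodes) that run in seconds with the reduced
#' ionic model: `"cuboid1"` a single plain cuboid cell, `"mini2"` a minimal
#' two-cell pair (small enough for the dense oracle), `"two_cell"` two
#' connected cells with side slabs, `"three_cell"` a short strand for
#' convergence work.
#'
#' @param name fixture name.
#' @param dx,dy,dz spacing overrides (um).
#' @return An `emi_mesh`.
#' @export
emi_fixture <- function(name = c("cuboid1", "mini2", "two_cell",
                                 "three_cell"),
                        dx = 1, dy = 1, dz = 1) {
  name <- match.arg(name)
  sp <- grid_spec(dx, dy, dz)
  switch(name,
    cuboid1 = build_strand(
      cell_geometry(size_O = c(12, 6, 6), size_WE = 0, size_SN = 0),
      strand_layout(1, padding = c(4, 4, 4)), sp),
    mini2 = build_strand(
      cell_geometry(size_O = c(8, 4, 4), size_WE = c(2, 2, 2),
                    size_SN = 0),
      strand_layout(2, padding = c(3, 3, 3)), sp),
    two_cell = build_strand(
      cell_geometry(size_O = c(16, 6, 6), size_WE = c(2, 2, 2),
                    size_SN = c(4, 2, 4)),
      strand_layout(2, padding = c(4, 4, 4)), sp),
    three_cell = build_strand(
      cell_geometry(size_O = c(16, 6, 6), size_WE = c(2, 2, 2),
                    size_SN = 0),
      strand_layout(3, padding = c(4, 4, 4)), sp))
}

#' Independent dense reference solve
#'
#' Rebuilds the implicit-step equations node by node (scalar loops, dense
#' matrix) and solves for the potentials given the post-ODE membrane
#' potential `v_star` and the current disc jumps `w_n`.  Returns the full
#' unknown vector in the production layout for direct comparison with one
#' [emi_step()] implicit solve.
#'
#' @param mesh a small `emi_mesh`.
#' @param params an [emi_params()].
#' @param dt implicit step (ms).
#' @param v_star membrane potential after the ODE half-step, per membrane
#'   node.
#' @param w_n disc jump at the previous step, per disc node.
#' @return Numeric vector of unknowns (same layout as `emi_system`).
#' @export
dense_reference_solve <- function(mesh, params, dt, v_star, w_n) {
  p <- params
  cls <- mesh$cls
  N <- length(cls)
  nx <- mesh$nx; ny <- mesh$ny
  # independent unknown bookkeeping (same ordering convention)
  ue_ix <- integer(N); ui_ix <- integer(N)
  dL_ix <- integer(N); dR_ix <- integer(N)
  k <- 0L
  for (n in seq_len(N)) {
    if (cls[n] %in% c(CL_EXT, CL_DIR, CL_NEU, CL_MEM)) {
      k <- k + 1L; ue_ix[n] <- k
    }
  }
  for (n in seq_len(N)) {
    if (cls[n] %in% c(CL_INT, CL_MEM)) {
      k <- k + 1L; ui_ix[n] <- k
    }
  }
  dn <- mesh$disc$node
  for (n in dn) { k <- k + 1L; dL_ix[n] <- k }
  for (n in dn) { k <- k + 1L; dR_ix[n] <- k }
  nun <- k
  M <- matrix(0, nun, nun)
  b <- numeric(nun)

  ijk <- .node_ijk(mesh, seq_len(N))
  hs <- list(mesh$hx, mesh$hy, mesh$hz)
  ns <- c(mesh$nx, mesh$ny, mesh$nz)
  offs <- c(1L, nx, nx * ny)
  mrow_of <- integer(N); mrow_of[mesh$memb$node] <- seq_along(mesh$memb$node)
  drow_of <- integer(N); drow_of[dn] <- seq_along(dn)

  # intracellular column of cell `cell` at node nb
  uicol <- function(nb, cell) {
    if (cls[nb] %in% c(CL_INT, CL_MEM)) return(ui_ix[nb])
    if (cls[nb] == CL_DSC) {
      if (mesh$c1[nb] == cell) return(dL_ix[nb])
      if (mesh$c2[nb] == cell) return(dR_ix[nb])
    }
    stop("dense oracle: broken intracellular stencil")
  }

  for (n in seq_len(N)) {
    cl <- cls[n]
    if (cl == CL_DIR) {
      M[ue_ix[n], ue_ix[n]] <- 1
      next
    }
    if (cl %in% c(CL_EXT, CL_NEU)) {
      row <- ue_ix[n]
      for (a in 1:3) {
        ia <- ijk[n, a]
        for (dirn in c(-1L, 1L)) {
          # spacing toward the neighbour; mirror at missing z-sides
          hh <- if (dirn < 0) {
            if (ia > 1) hs[[a]][ia - 1] else NA
          } else {
            if (ia < ns[a]) hs[[a]][ia] else NA
          }
          hov <- if (dirn < 0) {
            if (ia < ns[a]) hs[[a]][ia] else NA
          } else {
            if (ia > 1) hs[[a]][ia - 1] else NA
          }
          nb <- n + dirn * offs[a]
          if (is.na(hh)) { hh <- hov; nb <- n - dirn * offs[a] }
          if (is.na(hov)) hov <- hh
          if (cls[nb] == CL_DSC) next  # rim triple line: reflect
          cc <- p$sigma_e * 2 / (hh * (hh + hov))
          M[row, ue_ix[nb]] <- M[row, ue_ix[nb]] + cc
          M[row, ue_ix[n]] <- M[row, ue_ix[n]] - cc
        }
      }
      next
    }
    if (cl == CL_INT) {
      row <- ui_ix[n]
      cell <- mesh$c1[n]
      for (a in 1:3) {
        ia <- ijk[n, a]
        for (dirn in c(-1L, 1L)) {
          hh <- if (dirn < 0) hs[[a]][ia - 1] else hs[[a]][ia]
          hov <- if (dirn < 0) hs[[a]][ia] else hs[[a]][ia - 1]
          nb <- n + dirn * offs[a]
          cc <- p$sigma_i * 2 / (hh * (hh + hov))
          cb <- uicol(nb, cell)
          M[row, cb] <- M[row, cb] + cc
          M[row, ui_ix[n]] <- M[row, ui_ix[n]] - cc
        }
      }
      next
    }
    if (cl == CL_MEM) {
      mr <- mrow_of[n]
      cell <- mesh$memb$cell[mr]
      rowI <- ui_ix[n]; rowE <- ue_ix[n]
      has_face <- function(node, axis) {
        r <- mrow_of[node]
        r > 0 && any(mesh$faces$mrow == r & mesh$faces$axis == axis)
      }
      for (a in 1:3) {
        ia <- ijk[n, a]
        for (dirn in c(-1L, 1L)) {
          nb <- n + dirn * offs[a]
          hh <- if (dirn < 0) hs[[a]][ia - 1] else hs[[a]][ia]
          aw <- prod(c(mesh$mx[ijk[n, 1]], mesh$my[ijk[n, 2]],
                       mesh$mz[ijk[n, 3]])[-a])
          nb_mem <- cls[nb] == CL_MEM
          normal_pair <- !nb_mem || has_face(n, a) || has_face(nb, a)
          same <- ((cls[nb] == CL_INT && mesh$c1[nb] == cell) ||
                     (nb_mem && mesh$c1[nb] == cell && normal_pair) ||
                     (cls[nb] == CL_DSC &&
                        (mesh$c1[nb] == cell || mesh$c2[nb] == cell)))
          if (same) {
            cin <- uicol(nb, cell)
            wi <- aw * p$sigma_i / hh
            M[rowI, cin] <- M[rowI, cin] + wi
            M[rowI, ui_ix[n]] <- M[rowI, ui_ix[n]] - wi
          }
          if (cls[nb] %in% c(CL_EXT, CL_DIR, CL_NEU) ||
              (nb_mem && normal_pair)) {
            we <- aw * p$sigma_e / hh
            M[rowE, ue_ix[nb]] <- M[rowE, ue_ix[nb]] + we
            M[rowE, ue_ix[n]] <- M[rowE, ue_ix[n]] - we
          }
        }
      }
      vw <- mesh$memb$A[mr] * p$C_m / dt
      M[rowI, ui_ix[n]] <- M[rowI, ui_ix[n]] - vw
      M[rowI, ue_ix[n]] <- M[rowI, ue_ix[n]] + vw
      M[rowE, ui_ix[n]] <- M[rowE, ui_ix[n]] + vw
      M[rowE, ue_ix[n]] <- M[rowE, ue_ix[n]] - vw
      b[rowI] <- -vw * v_star[mr]
      b[rowE] <- vw * v_star[mr]
      next
    }
    if (cl == CL_DSC) {
      dr <- drow_of[n]
      rgf <- rep_len(p$rg_factor, max(mesh$disc$junction))
      G <- if (is.infinite(rgf[mesh$disc$junction[dr]])) 0 else {
        1 / (p$R_g * rgf[mesh$disc$junction[dr]])
      }
      rowL <- dL_ix[n]; rowR <- dR_ix[n]
      aw_ax <- mesh$my[ijk[n, 2]] * mesh$mz[ijk[n, 3]]
      cinL <- uicol(mesh$disc$in_L[dr], mesh$disc$cellL[dr])
      cinR <- uicol(mesh$disc$in_R[dr], mesh$disc$cellR[dr])
      wL <- aw_ax * p$sigma_i / mesh$disc$h_L[dr]
      wR <- aw_ax * p$sigma_i / mesh$disc$h_R[dr]
      M[rowL, cinL] <- M[rowL, cinL] + wL
      M[rowL, rowL] <- M[rowL, rowL] - wL
      M[rowR, cinR] <- M[rowR, cinR] + wR
      M[rowR, rowR] <- M[rowR, rowR] - wR
      # in-plane disc contacts reflect (no lateral sheet in the disc)
      a_w <- mesh$disc$a_col[dr]  # clipped disc-area weight
      dw <- a_w * (p$C_disc / dt + G)
      M[rowL, rowL] <- M[rowL, rowL] - dw
      M[rowL, rowR] <- M[rowL, rowR] + dw
      M[rowR, rowL] <- M[rowR, rowL] + dw
      M[rowR, rowR] <- M[rowR, rowR] - dw
      b[rowL] <- -a_w * p$C_disc / dt * w_n[dr]
      b[rowR] <- a_w * p$C_disc / dt * w_n[dr]
      next
    }
  }
  # row equilibration: conduction and capacitive rows differ by ~1e9
  sc <- 1 / rowSums(abs(M))
  solve(M * sc, b * sc)
}

#' Temporal and spatial convergence report
#'
#' Runs a refinement ladder on the `three_cell` fixture with the reduced
#' model: halving dt across `dts` and refining the lattice across `dxs`,
#' reporting cell-2 -> cell-3 activation-time differences and conduction
#' velocities.  Used by the test suite to assert first-order-in-dt
#' activation times and monotone CV convergence.
#'
#' @param dts implicit steps to try (ms).
#' @param dxs spacings to try (um).
#' @param t_end simulated time per run (ms).
#' @return list(dt_table, dx_table) data frames.
#' @export
convergence_suite <- function(dts = c(0.04, 0.02, 0.01, 0.005),
                              dxs = c(2, 1),
                              t_end = 8) {
  model <- reduced_test_model()
  run_one <- function(dx, dt) {
    mesh <- emi_fixture("three_cell", dx = dx, dy = dx, dz = dx)
    gna <- assign_gna(mesh, channel_distribution(0), model)
    res <- emi_run(mesh, model, gna, t_end = t_end, dt = dt,
                   stimulus = stimulus_protocol(cells = 1))
    cvo <- conduction_velocity(res, 2, 3)
    act <- activation_times(res$time, res$v)
    data.frame(dx = dx, dt = dt, act2 = act[2], act3 = act[3],
               cv = cvo$cv)
  }
  dt_table <- do.call(rbind, lapply(dts, function(dt) run_one(dxs[1], dt)))
  dx_table <- do.call(rbind, lapply(dxs, function(dx) {
    run_one(dx, min(dts))
  }))
  list(dt_table = dt_table, dx_table = dx_table)
}
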