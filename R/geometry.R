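# Geometry: strand-of-cells computational domain on a (possibly x-graded) lattice.
#
# Each cell is a composition of five rectangular cuboids: a main body Omega_O,
# two connector cuboids Omega_W / Omega_E at the x-ends, and two thin slabs
# Omega_S / Omega_N on the y-sides.  Cells are joined in a single row along x;
# abutting connector faces form the intercalated discs.  All lengths are
# stored internally in cm; constructors accept micrometres.

UM <- 1e-4  # 1 um in cm
NM <- 1e-7  # 1 nm in cm

#' Cell geometry (cuboid composition)
#'
#' Defines the five-cuboid composition of a single cardiomyocyte: the main
#' body `size_O`, the end connectors `size_WE` (west/east, joined to
#' neighbouring cells), and the side slabs `size_SN` (south/north).  A zero
#' vector drops the corresponding cuboids, so `cell_geometry(size_WE = 0,
#' size_SN = 0)` is a plain cuboid cell.
#'
#' @param size_O length-3 vector, x/y/z extent of the main body in um.
#' @param size_WE length-3 vector, extent of each end connector in um
#'   (x-size is the half cell-to-cell distance), or 0 to omit.
#' @param size_SN length-3 vector, extent of each side slab in um, or 0.
#' @return An object of class `emi_cell_geometry` (lengths in cm).
#' @export
cell_geometry <- function(size_O = c(100, 18, 18),
                          size_WE = c(2, 14, 14),
                          size_SN = c(14, 2, 14)) {
  norm3 <- function(v, what) {
    if (length(v) == 1 && v == 0) v <- c(0, 0, 0)
    if (length(v) != 3 || any(v < 0)) {
      stop(sprintf("'%s' must be a non-negative length-3 vector", what))
    }
    if (any(v == 0) && !all(v == 0)) {
      stop(sprintf("'%s' must be all-zero or all-positive", what))
    }
    v
  }
  size_O <- norm3(size_O, "size_O")
  size_WE <- norm3(size_WE, "size_WE")
  size_SN <- norm3(size_SN, "size_SN")
  if (all(size_O == 0)) stop("size_O must be positive")
  if (any(size_WE[2:3] > size_O[2:3])) {
    stop("Omega_W/E cross-section must fit within the Omega_O y-z face")
  }
  if (size_SN[1] > size_O[1] || size_SN[3] > size_O[3]) {
    stop("Omega_S/N footprint must fit on Omega_O")
  }
  structure(list(size_O = size_O * UM, size_WE = size_WE * UM,
                 size_SN = size_SN * UM),
            class = "emi_cell_geometry")
}

#' Strand layout
#'
#' @param n_cells number of cells in the row (>= 1).
#' @param padding extracellular padding between the intracellular domain and
#'   the outer boundary, per axis, in um.  Defaults 10 um (x, y), 4 um (z).
#' @param gap extracellular gap between consecutive cell bodies in um.  With
#'   connectors present the default 0 means cells abut and share a disc; a
#'   positive gap (used with `size_WE = 0`) separates the cells by an open
#'   extracellular cleft with no disc.
#' @return An object of class `emi_strand_layout`.
#' @export
strand_layout <- function(n_cells = 1, padding = c(10, 10, 4), gap = 0) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (length(padding) != 3 || any(padding <= 0)) {
    stop("padding must be three positive lengths (um)")
  }
  if (gap < 0) stop("gap must be >= 0")
  structure(list(n_cells = as.integer(n_cells), padding = padding * UM,
                 gap = gap * UM),
            class = "emi_strand_layout")
}

#' Lattice spacing specification
#'
#' @param dx,dy,dz bulk lattice spacings in um.
#' @param cleft_dx spacing used across each junction (connectors and
#'   extracellular gaps) in um.  The default `NULL` resolves to d/4 where d
#'   is the combined junction length, capped at `dx`; spacing is graded
#'   geometrically (ratio <= 2 per step) from the junction to the bulk.
#' @return An object of class `emi_grid_spec`.
#' @export
grid_spec <- function(dx = 1, dy = 1, dz = 2, cleft_dx = NULL) {
  if (any(c(dx, dy, dz) <= 0)) stop("spacings must be positive")
  if (!is.null(cleft_dx) && cleft_dx <= 0) stop("cleft_dx must be positive")
  structure(list(dx = dx * UM, dy = dy * UM, dz = dz * UM,
                 cleft_dx = if (is.null(cleft_dx)) NULL else cleft_dx * UM),
            class = "emi_grid_spec")
}

# ---- axis grid construction -------------------------------------------------

.tol <- 1e-12  # cm; well below 1 pm

# Uniform fill of [0, L] with target spacing h; strict divisibility check.
.fill_uniform <- function(L, h, axis) {
  n <- L / h
  if (abs(n - round(n)) > 1e-6) {
    stop(sprintf("length %.6g um is not divisible by the %s-spacing %.6g um",
                 L / UM, axis, h / UM), call. = FALSE)
  }
  n <- max(1L, as.integer(round(n)))
  seq_len(n) * (L / n)
}

# Graded fill of [0, L]: spacing h_left at the left edge and h_right at the
# right edge, growing geometrically (factor 2) toward h_max, uniform middle.
.fill_graded <- function(L, h_left, h_right, h_max) {
  ladder <- function(h0) {
    s <- numeric(0)
    h <- h0
    while (h < h_max * (1 - 1e-9)) {
      s <- c(s, h)
      h <- 2 * h
    }
    s
  }
  left <- ladder(h_left)
  right <- ladder(h_right)
  # trim ladders (largest steps first) until a middle remains
  repeat {
    mid <- L - sum(left) - sum(right)
    if (mid > -.tol) break
    if (length(left) >= length(right) && length(left) > 0) {
      left <- left[-length(left)]
    } else if (length(right) > 0) {
      right <- right[-length(right)]
    } else break
  }
  mid <- L - sum(left) - sum(right)
  steps <- left
  if (mid > .tol) {
    n <- max(1L, as.integer(ceiling(mid / h_max - 1e-9)))
    steps <- c(steps, rep(mid / n, n))
  }
  steps <- c(steps, rev(right))
  if (abs(sum(steps) - L) > 1e-9 * max(L, 1e-6)) {
    stop("internal error: graded interval fill does not close")
  }
  cumsum(steps)
}

# Build one axis from interval breakpoints `planes` (sorted, cm) and per-
# interval spacing requests: list of (h, h_left, h_right) with h the bulk cap.
.build_axis <- function(planes, fills, axis) {
  stopifnot(length(fills) == length(planes) - 1)
  out <- planes[1]
  for (i in seq_along(fills)) {
    L <- planes[i + 1] - planes[i]
    f <- fills[[i]]
    pts <- if (f$h_left < f$h * (1 - 1e-9) || f$h_right < f$h * (1 - 1e-9)) {
      .fill_graded(L, f$h_left, f$h_right, f$h)
    } else if (!is.null(f$n_min) && L / f$h < f$n_min) {
      n <- f$n_min
      seq_len(n) * (L / n)
    } else {
      .fill_uniform(L, f$h, axis)
    }
    out <- c(out, planes[i] + pts)
  }
  out
}

.plane_index <- function(grid, x, what = "plane") {
  i <- which(abs(grid - x) <= 1e-9 + 1e-9 * abs(x))
  if (length(i) != 1) {
    stop(sprintf("internal error: %s at %.9g um not on the lattice",
                 what, x / UM))
  }
  i
}

# ---- mesh builder -----------------------------------------------------------

# node class codes
CL_EXT <- 0L  # extracellular
CL_DIR <- 1L  # outer boundary, Dirichlet (x/y faces)
CL_NEU <- 2L  # outer boundary, Neumann (z faces)
CL_INT <- 3L  # intracellular interior
CL_MEM <- 4L  # membrane (carries u_e and u_i traces, v, ionic state)
CL_DSC <- 5L  # intercalated disc (carries both intracellular traces, w)

#' Build the strand mesh
#'
#' Lays the cuboid-composed cells on a lattice, classifies every node as
#' extracellular, intracellular, membrane, disc or outer boundary, and
#' precomputes the membrane quadrature and one-sided flux stencil data used
#' by the solver.
#'
#' Membrane nodes carry both an extracellular and an intracellular potential
#' trace so that the jump v = u_i - u_e is well defined on the zero-thickness
#' interface; disc nodes carry the two intracellular traces and w.  The
#' intercalated disc is the full overlap face of the abutting connectors,
#' rim included: every node shared by two cells is a disc node, even where
#' it touches the extracellular cleft.
#'
#' @param geometry an [cell_geometry()] object.
#' @param layout a [strand_layout()] object.
#' @param spacing a [grid_spec()] object.
#' @return An object of class `emi_mesh`.
#' @export
build_strand <- function(geometry = cell_geometry(),
                         layout = strand_layout(),
                         spacing = grid_spec()) {
  g <- geometry; lay <- layout; sp <- spacing
  Ox <- g$size_O[1]; Oy <- g$size_O[2]; Oz <- g$size_O[3]
  WEx <- g$size_WE[1]; WEy <- g$size_WE[2]; WEz <- g$size_WE[3]
  SNx <- g$size_SN[1]; SNy <- g$size_SN[2]; SNz <- g$size_SN[3]
  has_we <- WEx > 0; has_sn <- SNx > 0
  nc <- lay$n_cells
  pad <- lay$padding
  gap <- lay$gap
  if (!has_we && nc > 1 && gap <= 0) {
    stop("cells without connectors (size_WE = 0) require a positive gap")
  }

  d_junc <- 2 * WEx + gap  # combined junction length (O-face to O-face)
  fine <- if (!is.null(sp$cleft_dx)) sp$cleft_dx else {
    if (d_junc > 0) min(sp$dx, d_junc / 4) else sp$dx
  }

  ## ---- x axis ----
  Lcell <- 2 * WEx + Ox
  pitch <- Lcell + gap
  x_cell0 <- pad[1] + (seq_len(nc) - 1) * pitch
  hW <- if (has_we) min(fine, WEx / 2) else sp$dx
  hG <- if (gap > 0) min(fine, gap / 4) else sp$dx
  fl <- function(h, h_left = h, h_right = h, n_min = NULL) {
    list(h = h, h_left = h_left, h_right = h_right, n_min = n_min)
  }
  # interval list: ends (cm) plus the fill request, in x order
  iv_end <- numeric(0); iv_fill <- list()
  push <- function(x1, f) {
    iv_end <<- c(iv_end, x1)
    iv_fill <<- c(iv_fill, list(f))
  }
  push(pad[1], fl(sp$dx, h_right = if (has_we) hW else sp$dx))
  for (k in seq_len(nc)) {
    x0 <- x_cell0[k]
    if (has_we) push(x0 + WEx, fl(hW, n_min = 2L))
    o_left <- if (has_we) hW else if (k > 1 && gap > 0) hG else sp$dx
    o_right <- if (has_we) hW else if (k < nc && gap > 0) hG else sp$dx
    push(x0 + WEx + Ox, fl(sp$dx, h_left = o_left, h_right = o_right))
    if (has_we) push(x0 + Lcell, fl(hW, n_min = 2L))
    if (k < nc && gap > 0) push(x0 + pitch, fl(hG, n_min = 4L))
  }
  Ltot <- iv_end[length(iv_end)] + pad[1]
  push(Ltot, fl(sp$dx, h_left = if (has_we) hW else sp$dx))
  xs <- .build_axis(c(0, iv_end), iv_fill, "x")

  ## ---- y axis ----
  yO0 <- pad[2] + (if (has_sn) SNy else 0)
  yO1 <- yO0 + Oy
  ytop <- yO1 + (if (has_sn) SNy else 0) + pad[2]
  yWE0 <- yO0 + (Oy - WEy) / 2; yWE1 <- yWE0 + WEy
  ypl <- sort(unique(c(0, pad[2], if (has_sn) yO0,
                       if (has_we) c(yWE0, yWE1),
                       yO1, if (has_sn) yO1 + SNy, ytop)))
  yfl <- rep(list(list(h = sp$dy, h_left = sp$dy, h_right = sp$dy,
                       n_min = NULL)), length(ypl) - 1)
  ys <- .build_axis(ypl, yfl, "y")

  ## ---- z axis ----
  zO0 <- pad[3]; zO1 <- zO0 + Oz
  zWE0 <- zO0 + (Oz - WEz) / 2; zWE1 <- zWE0 + WEz
  zSN0 <- zO0 + (Oz - SNz) / 2; zSN1 <- zSN0 + SNz
  zpl <- sort(unique(c(0, zO0, if (has_we) c(zWE0, zWE1),
                       if (has_sn) c(zSN0, zSN1), zO1, zO1 + pad[3])))
  zfl <- rep(list(list(h = sp$dz, h_left = sp$dz, h_right = sp$dz,
                       n_min = NULL)), length(zpl) - 1)
  zs <- .build_axis(zpl, zfl, "z")

  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  N <- nx * ny * nz

  ## ---- per-cell cuboid boxes (cm coordinate ranges) ----
  snap_x <- function(x) xs[which.min(abs(xs - x))]
  boxes <- vector("list", nc)
  for (k in seq_len(nc)) {
    x0 <- x_cell0[k]
    bl <- list()
    bl$O <- c(x0 + WEx, x0 + WEx + Ox, yO0, yO1, zO0, zO1)
    if (has_we) {
      bl$W <- c(x0, x0 + WEx, yWE0, yWE1, zWE0, zWE1)
      bl$E <- c(x0 + WEx + Ox, x0 + Lcell, yWE0, yWE1, zWE0, zWE1)
    }
    if (has_sn) {
      xs0 <- snap_x(x0 + WEx + (Ox - SNx) / 2)
      xs1 <- snap_x(xs0 + SNx)
      bl$S <- c(xs0, xs1, yO0 - SNy, yO0, zSN0, zSN1)
      bl$N <- c(xs0, xs1, yO1, yO1 + SNy, zSN0, zSN1)
    }
    boxes[[k]] <- bl
  }

  ## ---- classification ----
  c1 <- integer(N); c2 <- integer(N)
  box_cube <- function(b) {
    i0 <- .plane_index(xs, b[1], "x"); i1 <- .plane_index(xs, b[2], "x")
    j0 <- .plane_index(ys, b[3], "y"); j1 <- .plane_index(ys, b[4], "y")
    l0 <- .plane_index(zs, b[5], "z"); l1 <- .plane_index(zs, b[6], "z")
    list(i0:i1, j0:j1, l0:l1)
  }
  a1 <- array(c1, c(nx, ny, nz)); a2 <- array(c2, c(nx, ny, nz))
  for (k in seq_len(nc)) {
    inK <- array(FALSE, c(nx, ny, nz))
    for (b in boxes[[k]]) {
      cu <- box_cube(b)
      inK[cu[[1]], cu[[2]], cu[[3]]] <- TRUE
    }
    new1 <- inK & a1 == 0L
    shared <- inK & a1 != 0L & a1 != k
    a1[new1] <- k
    a2[shared] <- k
  }
  c1 <- as.integer(a1); c2 <- as.integer(a2)
  rm(a1, a2)

  in_any <- c1 > 0L
  ix <- rep.int(seq_len(nx), ny * nz)
  iy <- rep.int(rep(seq_len(ny), each = nx), nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  on_dir <- (ix == 1L | ix == nx | iy == 1L | iy == ny) & !in_any
  on_neu <- (iz == 1L | iz == nz) & !in_any & !on_dir
  if (any(in_any & (ix == 1L | ix == nx | iy == 1L | iy == ny |
                    iz == 1L | iz == nz))) {
    stop("internal error: intracellular domain touches the outer boundary")
  }

  offs <- c(xm = -1L, xp = 1L,
            ym = -nx, yp = nx,
            zm = -nx * ny, zp = nx * ny)
  axis_of <- c(1L, 1L, 2L, 2L, 3L, 3L)
  dir_of <- c(-1L, 1L, -1L, 1L, -1L, 1L)

  cin <- which(in_any)
  out_nb <- matrix(FALSE, length(cin), 6)
  for (q in 1:6) out_nb[, q] <- !in_any[cin + offs[q]]
  is_memb_node <- rowSums(out_nb) > 0

  cls <- integer(N)
  cls[!in_any] <- CL_EXT
  cls[on_dir] <- CL_DIR
  cls[on_neu] <- CL_NEU
  cls[cin[is_memb_node]] <- CL_MEM
  inner <- cin[!is_memb_node]
  cls[inner] <- ifelse(c2[inner] > 0L, CL_DSC, CL_INT)
  # the intercalated disc is the full overlap face of the abutting
  # connectors, rim included: nodes shared by two cells are disc nodes even
  # where they touch the extracellular cleft
  cls[cin][c2[cin] > 0L] <- CL_DSC

  ## ---- spacings / mean spacings ----
  hx <- diff(xs); hy <- diff(ys); hz <- diff(zs)
  mx <- c(hx[1] / 2, (hx[-1] + hx[-length(hx)]) / 2, hx[length(hx)] / 2)
  my <- c(hy[1] / 2, (hy[-1] + hy[-length(hy)]) / 2, hy[length(hy)] / 2)
  mz <- c(hz[1] / 2, (hz[-1] + hz[-length(hz)]) / 2, hz[length(hz)] / 2)

  ## ---- membrane face table ----
  mem_mask <- is_memb_node & c2[cin] == 0L
  mem_nodes <- cin[mem_mask]
  mem_cell <- c1[mem_nodes]
  fnode <- integer(0); faxis <- integer(0); fdir <- integer(0)
  for (q in 1:6) {
    sel <- mem_nodes[out_nb[mem_mask, q]]
    fnode <- c(fnode, sel)
    faxis <- c(faxis, rep(axis_of[q], length(sel)))
    fdir <- c(fdir, rep(dir_of[q], length(sel)))
  }
  o <- order(fnode, faxis, fdir)
  fnode <- fnode[o]; faxis <- faxis[o]; fdir <- fdir[o]
  off_axis <- c(1L, nx, nx * ny)
  fout <- fnode + fdir * off_axis[faxis]
  fin <- fnode - fdir * off_axis[faxis]
  fix <- ix[fnode]; fiy <- iy[fnode]; fiz <- iz[fnode]
  # spacing toward out / in along the face axis
  sp_along <- function(axis, idx, dirn) {
    # spacing between node idx and idx+dirn along `axis`
    h <- switch(axis, hx, hy, hz)
    ifelse(dirn > 0, h[idx], h[idx - 1])
  }
  h_out <- numeric(length(fnode)); h_in <- numeric(length(fnode))
  for (a in 1:3) {
    s <- faxis == a
    ia <- switch(a, fix, fiy, fiz)[s]
    h_out[s] <- sp_along(a, ia, fdir[s])
    h_in[s] <- sp_along(a, ia, -fdir[s])
  }
  a_col <- numeric(length(fnode))
  a_col[faxis == 1] <- my[fiy[faxis == 1]] * mz[fiz[faxis == 1]]
  a_col[faxis == 2] <- mx[fix[faxis == 2]] * mz[fiz[faxis == 2]]
  a_col[faxis == 3] <- mx[fix[faxis == 3]] * my[fiy[faxis == 3]]

  # validity: the inward neighbour must belong to the same cell
  fin_ok <- (c1[fin] == c1[fnode]) | (c2[fin] == c1[fnode]) |
    (c2[fnode] > 0L & (c1[fin] == c2[fnode] | c2[fin] == c2[fnode]))
  if (!all(fin_ok)) {
    stop("internal-consistency failure: membrane node without an ",
         "intracellular neighbour along its normal")
  }
  if (any(cls[fout] %in% c(CL_INT, CL_DSC))) {
    stop("internal-consistency failure: membrane outward neighbour is ",
         "intracellular")
  }

  mrow <- match(fnode, mem_nodes)
  nf <- tabulate(mrow, nbins = length(mem_nodes))
  A_i <- as.numeric(rowsum(a_col, mrow)) / nf

  memb <- list(node = mem_nodes, cell = mem_cell, A = A_i, nf = nf,
               x = xs[ix[mem_nodes]], y = ys[iy[mem_nodes]],
               z = zs[iz[mem_nodes]])
  faces <- list(mrow = mrow, node = fnode, axis = faxis, dir = fdir,
                in_node = fin, out_node = fout,
                h_in = h_in, h_out = h_out, a_col = a_col)

  ## ---- disc table ----
  dn <- which(cls == CL_DSC)
  disc <- NULL
  if (length(dn)) {
    dL <- dn - 1L; dR <- dn + 1L
    okL <- c1[dL] == c1[dn] | c2[dL] == c1[dn]
    okR <- c1[dR] == c2[dn] | c2[dR] == c2[dn]
    if (!all(okL & okR)) {
      stop("internal-consistency failure: disc node neighbours")
    }
    # transverse quadrature bands clipped to the disc extent so the total
    # disc area equals the geometric overlap of the abutting connectors
    clipw <- function(pos, hlo, hhi, lo, hi) {
      pmax(0, pmin(pos + hhi / 2, hi) - pmax(pos - hlo / 2, lo))
    }
    wy <- clipw(ys[iy[dn]], hy[pmax(iy[dn] - 1, 1)],
                hy[pmin(iy[dn], length(hy))], yWE0, yWE1)
    wz <- clipw(zs[iz[dn]], hz[pmax(iz[dn] - 1, 1)],
                hz[pmin(iz[dn], length(hz))], zWE0, zWE1)
    disc <- list(node = dn, cellL = c1[dn], cellR = c2[dn],
                 junction = c1[dn],
                 in_L = dL, in_R = dR,
                 h_L = hx[ix[dn] - 1], h_R = hx[ix[dn]],
                 a_col = wy * wz,
                 x = xs[ix[dn]], y = ys[iy[dn]], z = zs[iz[dn]])
  } else if (nc > 1 && gap <= 0) {
    stop("internal error: connected strand without disc nodes; ",
         "refine the cross-section spacing")
  }

  cells <- list(
    x0 = x_cell0, x1 = x_cell0 + Lcell,
    x_center = x_cell0 + Lcell / 2,
    we_x = if (has_we) {
      cbind(W0 = x_cell0, W1 = x_cell0 + WEx,
            E0 = x_cell0 + WEx + Ox, E1 = x_cell0 + Lcell)
    } else NULL
  )

  structure(list(
    xs = xs, ys = ys, zs = zs, nx = nx, ny = ny, nz = nz,
    hx = hx, hy = hy, hz = hz, mx = mx, my = my, mz = mz,
    cls = cls, c1 = c1, c2 = c2,
    we_cross = c(yWE0, yWE1, zWE0, zWE1),
    memb = memb, faces = faces, disc = disc,
    n_cells = nc, cells = cells,
    geometry = g, layout = lay, spacing = sp,
    d_junc = d_junc
  ), class = "emi_mesh")
}

#' @export
print.emi_mesh <- function(x, ...) {
  cat(sprintf("EMI mesh: %d cell(s), %d x %d x %d lattice (%d nodes)\n",
              x$n_cells, x$nx, x$ny, x$nz, x$nx * x$ny * x$nz))
  tab <- table(factor(x$cls, levels = 0:5,
                      labels = c("extracellular", "dirichlet", "neumann",
                                 "intracellular", "membrane", "disc")))
  print(tab)
  invisible(x)
}

# node id -> (ix, iy, iz)
.node_ijk <- function(mesh, node) {
  nxy <- mesh$nx * mesh$ny
  iz <- (node - 1L) %/% nxy + 1L
  r <- (node - 1L) %% nxy
  iy <- r %/% mesh$nx + 1L
  ix <- r %% mesh$nx + 1L
  cbind(ix = ix, iy = iy, iz = iz)
}

#' Membrane quadrature areas
#'
#' Area weights A_i for every membrane node, following the seven-case rule:
#' the product of the two transverse spacings for nodes interior to a face,
#' the mean of two such products on face-intersection edges, and one third of
#' the three products at corners.  `A_c` sums the weights per cell.
#'
#' @param mesh an `emi_mesh`.
#' @return A list with `A` (per membrane node, cm^2), `node`, `cell`, and
#'   `A_c` (per-cell totals, cm^2).
#' @export
membrane_areas <- function(mesh) {
  A_c <- as.numeric(rowsum(mesh$memb$A, mesh$memb$cell))
  list(A = mesh$memb$A, node = mesh$memb$node, cell = mesh$memb$cell,
       A_c = A_c)
}

#' Junctional membrane region
#'
#' Selects the membrane-node subset carrying the elevated sodium-channel
#' density.  `horizontal_ends` picks the connector (Omega_W / Omega_E) faces
#' parallel to the x-axis; `vertical_ends` picks the x-normal end faces of
#' each cell (used for nanometre-cleft ephaptic runs).  Disc nodes carry no
#' ionic current and are never part of the region.
#'
#' @param mesh an `emi_mesh`.
#' @param mode `"horizontal_ends"` or `"vertical_ends"`.
#' @return Logical vector over membrane nodes (parallel to `mesh$memb$node`).
#' @export
junction_region <- function(mesh, mode = c("horizontal_ends",
                                           "vertical_ends")) {
  mode <- match.arg(mode)
  f <- mesh$faces
  tol <- 1e-9
  if (mode == "horizontal_ends") {
    we <- mesh$cells$we_x
    if (is.null(we)) {
      stop("horizontal_ends requires a geometry with Omega_W/Omega_E")
    }
    fc <- mesh$memb$cell[f$mrow]
    fx <- mesh$memb$x[f$mrow]
    fy <- mesh$memb$y[f$mrow]
    fz <- mesh$memb$z[f$mrow]
    inW <- fx >= we[fc, "W0"] - tol & fx <= we[fc, "W1"] + tol
    inE <- fx >= we[fc, "E0"] - tol & fx <= we[fc, "E1"] + tol
    # restrict to the connector surface itself: the main-body side walls
    # share x-values with the connectors but lie outside their
    # cross-section
    wc <- mesh$we_cross
    on_cross <- fy >= wc[1] - tol & fy <= wc[2] + tol &
      fz >= wc[3] - tol & fz <= wc[4] + tol
    sel_face <- f$axis != 1L & (inW | inE) & on_cross
  } else {
    # x-normal faces at the cell ends only (the Omega_O end planes and any
    # free connector end face); x-normal faces of the side slabs sit
    # mid-cell and are not part of the cell ends
    fc <- mesh$memb$cell[f$mrow]
    fx <- mesh$memb$x[f$mrow]
    wex <- mesh$geometry$size_WE[1]
    x_lo <- mesh$cells$x0[fc] + wex
    x_hi <- mesh$cells$x1[fc] - wex
    sel_face <- f$axis == 1L & (fx <= x_lo + tol | fx >= x_hi - tol)
  }
  sel <- rep(FALSE, length(mesh$memb$node))
  sel[unique(f$mrow[sel_face])] <- TRUE
  counts <- tabulate(mesh$memb$cell[sel], nbins = mesh$n_cells)
  if (any(counts == 0)) {
    stop(sprintf(
      "no %s membrane nodes for cell(s) %s (end faces fully connected?)",
      mode, paste(which(counts == 0), collapse = ", ")))
  }
  sel
}
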