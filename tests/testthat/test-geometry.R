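# Mesh construction, node classification and membrane quadrature.

test_that("default single cell has the documented extents", {
  m <- build_strand(cell_geometry(), strand_layout(1), grid_spec(1, 1, 2))
  expect_equal(diff(range(m$xs)) / 1e-4, 124)           # 104 um cell + 2x10
  expect_equal((m$cells$x1[1] - m$cells$x0[1]) / 1e-4, 104)
  expect_equal(diff(range(m$ys)) / 1e-4, 42)            # 18 + 2x2 + 2x10
  expect_equal(diff(range(m$zs)) / 1e-4, 26)            # 18 + 2x4
})

test_that("node classification partitions the lattice", {
  for (m in list(tiny_mesh(2), tiny_mesh(1, geo = cell_geometry(
    size_O = c(12, 6, 6), size_WE = 0, size_SN = 0)))) {
    N <- m$nx * m$ny * m$nz
    expect_identical(length(m$cls), N)
    expect_true(all(m$cls %in% 0:5))
    # membrane + disc + interior node counts match the cell bookkeeping
    expect_identical(sort(unique(m$memb$cell)), seq_len(m$n_cells))
    # class sets are disjoint by construction (single array); interfaces
    # lie on lattice planes: every membrane face has in/out neighbours
    f <- m$faces
    expect_true(all(m$cls[f$out_node] %in% c(0L, 1L, 2L, 4L)))
    expect_true(all(m$cls[f$in_node] %in% c(3L, 4L, 5L)))
  }
})

test_that("degenerate composition gives a plain cuboid cell", {
  geo <- cell_geometry(size_O = c(12, 6, 6), size_WE = 0, size_SN = 0)
  m <- build_strand(geo, strand_layout(1, padding = c(4, 4, 3)),
                    grid_spec(1, 1, 1))
  # membrane nodes are exactly the cuboid surface lattice nodes
  n_surface <- function(nx, ny, nz) nx * ny * nz - (nx - 2) * (ny - 2) *
    (nz - 2)
  expect_equal(length(m$memb$node), n_surface(13, 7, 7))
  expect_equal(sum(m$cls == 3L), (13 - 2) * (7 - 2) * (7 - 2))
  expect_null(m$disc)
})

test_that("detached cells leave >= 3 extracellular planes in a graded cleft", {
  geo <- cell_geometry(size_O = c(12, 6, 6), size_WE = 0, size_SN = 0)
  m <- build_strand(geo, strand_layout(2, gap = 0.005,
                                       padding = c(4, 4, 3)),
                    grid_spec(1, 1, 1))
  in_cleft <- m$xs > m$cells$x1[1] + 1e-12 & m$xs < m$cells$x0[2] - 1e-12
  expect_gte(sum(in_cleft), 3)
  # those planes are extracellular across the facing area
  ijk <- emir:::.node_ijk(m, seq_along(m$cls))
  mid <- which(in_cleft)[1]
  sel <- ijk[, 1] == mid & m$cls != 1L & m$cls != 2L
  expect_true(all(m$cls[sel] == 0L))
})

test_that("geometry not representable on the lattice is rejected", {
  geo <- cell_geometry(size_O = c(13, 6, 6), size_WE = 0, size_SN = 0)
  expect_error(build_strand(geo, strand_layout(1), grid_spec(2, 1, 1)),
               "x-spacing")
  geo2 <- cell_geometry(size_O = c(12, 7, 6), size_WE = 0, size_SN = 0)
  expect_error(build_strand(geo2, strand_layout(1), grid_spec(1, 2, 1)),
               "y-spacing")
})

test_that("membrane quadrature follows the seven-case area rule", {
  geo <- cell_geometry(size_O = c(12, 6, 6), size_WE = 0, size_SN = 0)
  m <- build_strand(geo, strand_layout(1, padding = c(4, 4, 4)),
                    grid_spec(1, 1, 2))
  q <- membrane_areas(m)
  um2 <- (1e-4)^2
  # plane-interior node on a z-constant face: dx dy
  plane_z <- m$memb$nf == 1 &
    vapply(seq_along(m$memb$node), function(i) {
      all(m$faces$axis[m$faces$mrow == i] == 3L)
    }, logical(1))
  expect_true(any(plane_z))
  expect_equal(q$A[plane_z] / um2, rep(1, sum(plane_z)))
  # corner nodes: (dx dy + dx dz + dy dz)/3 = (1 + 2 + 2)/3
  corners <- m$memb$nf == 3
  expect_identical(sum(corners), 8L)
  expect_equal(q$A[corners] / um2, rep(5 / 3, 8))
  # edge nodes: mean of the two adjoining products
  edge_xy <- vapply(seq_along(m$memb$node), function(i) {
    ax <- m$faces$axis[m$faces$mrow == i]
    length(ax) == 2 && setequal(ax, c(1L, 2L))
  }, logical(1))
  expect_equal(q$A[edge_xy] / um2, rep((2 + 2) / 2, sum(edge_xy)))
})

test_that("quadrature total approaches the analytic composed-solid area", {
  exact <- analytic_cell_area(c(100, 18, 18), c(2, 14, 14), c(14, 2, 14))
  m1 <- build_strand(cell_geometry(), strand_layout(1), grid_spec(1, 1, 2))
  A1 <- membrane_areas(m1)$A_c[1] / (1e-4)^2
  # the deficit is the half-spacing band along the concave junction lines:
  # 4 connector rims + 4 slab rims, each of perimeter 4x14 um (z bands
  # doubled by dz = 2)
  expect_lt(abs(A1 - exact) / exact, 0.04)
  m2 <- build_strand(cell_geometry(), strand_layout(1),
                     grid_spec(1, 1, 1))
  A2 <- membrane_areas(m2)$A_c[1] / (1e-4)^2
  expect_lt(abs(A2 - exact), abs(A1 - exact))  # refinement converges
  expect_lt(abs(A2 - exact) / exact, 0.03)
})

test_that("junction regions select the documented faces", {
  # degenerate cuboid: vertical ends are the two x-normal faces
  geo <- cell_geometry(size_O = c(12, 6, 6), size_WE = 0, size_SN = 0)
  m <- build_strand(geo, strand_layout(1, padding = c(4, 4, 3)),
                    grid_spec(1, 1, 1))
  sel <- junction_region(m, "vertical_ends")
  A_j <- sum(m$memb$A[sel]) / (1e-4)^2
  expect_equal(A_j, 2 * 7 * 7)  # quadrature area of two 6x6 faces (7x7
  # nodes; edge/corner weights extend half a band beyond each face)
  expect_error(junction_region(m, "horizontal_ends"), "Omega_W")

  # two connected cells: horizontal ends are connector side faces only
  m2 <- tiny_mesh(2)
  sel2 <- junction_region(m2, "horizontal_ends")
  we <- m2$cells$we_x
  expect_true(all(
    (m2$memb$x[sel2] >= we[m2$memb$cell[sel2], "W0"] - 1e-12 &
       m2$memb$x[sel2] <= we[m2$memb$cell[sel2], "W1"] + 1e-12) |
      (m2$memb$x[sel2] >= we[m2$memb$cell[sel2], "E0"] - 1e-12 &
         m2$memb$x[sel2] <= we[m2$memb$cell[sel2], "E1"] + 1e-12)))
  # never disc nodes (disc carries no ionic current)
  expect_false(any(m2$memb$node[sel2] %in% m2$disc$node))
  # vertical ends are the x-normal faces at the cell x-extremes; the
  # x-normal side walls of the mid-cell slabs are not cell ends
  sel3 <- junction_region(m2, "vertical_ends")
  f <- m2$faces
  fc <- m2$memb$cell[f$mrow]
  fx <- m2$memb$x[f$mrow]
  wex <- m2$geometry$size_WE[1]
  at_ends <- fx <= m2$cells$x0[fc] + wex + 1e-12 |
    fx >= m2$cells$x1[fc] - wex - 1e-12
  xnormal <- unique(f$mrow[f$axis == 1L & at_ends])
  expect_setequal(which(sel3), xnormal)
  expect_gt(length(xnormal), 0)
})

test_that("mirror symmetry: y and z reflections preserve class counts", {
  m <- tiny_mesh(2)
  tab <- table(m$cls)
  ijk <- emir:::.node_ijk(m, seq_along(m$cls))
  # reflect z: node (ix, iy, nz + 1 - iz)
  ref <- function(axis) {
    n <- c(m$nx, m$ny, m$nz)[axis]
    idx <- ijk
    idx[, axis] <- n + 1L - idx[, axis]
    id <- idx[, 1] + m$nx * (idx[, 2] - 1L) +
      m$nx * m$ny * (idx[, 3] - 1L)
    m$cls[id]
  }
  expect_identical(table(ref(3)), tab)
  expect_identical(table(ref(2)), tab)
  # the z-grid is symmetric, so reflection maps classes onto classes
  expect_identical(ref(3), m$cls)
})
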