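# Conductance-field construction and whole-cell conservation.

test_that("p = 0 gives the uniform field and p = 1 empties the remainder", {
  m <- tiny_mesh(2)
  model <- reduced_test_model()
  g0 <- assign_gna(m, channel_distribution(0), model)
  expect_true(all(g0 == model$gbar_na))
  g1 <- assign_gna(m, channel_distribution(1, "horizontal_ends"), model)
  sel <- junction_region(m, "horizontal_ends")
  expect_true(all(g1[!sel] == 0))
  A_c <- attr(g1, "A_c"); A_j <- attr(g1, "A_j")
  expect_equal(g1[sel],
               (A_c[m$memb$cell[sel]] / A_j[m$memb$cell[sel]]) *
                 model$gbar_na)
})

test_that("total conductance is conserved for all p and both regions", {
  m <- tiny_mesh(2)
  model <- reduced_test_model()
  quad <- membrane_areas(m)
  target <- quad$A_c * model$gbar_na
  for (region in c("horizontal_ends", "vertical_ends")) {
    for (p in seq(0, 1, by = 0.1)) {
      g <- assign_gna(m, channel_distribution(p, region), model)
      # independent node-by-node summation per cell
      tot <- vapply(1:2, function(k) {
        s <- 0
        for (i in which(m$memb$cell == k)) s <- s + g[i] * quad$A[i]
        s
      }, numeric(1))
      expect_lt(max(abs(tot - target) / target), 1e-12)
    }
  }
})

test_that("extreme-node conductances are monotone in p and linear in gbar", {
  m <- tiny_mesh(2)
  model <- reduced_test_model()
  ps <- seq(0, 1, by = 0.25)
  gmax <- gmin <- numeric(length(ps))
  for (i in seq_along(ps)) {
    g <- assign_gna(m, channel_distribution(ps[i], "horizontal_ends"),
                    model)
    gmax[i] <- max(g); gmin[i] <- min(g)
  }
  expect_true(all(diff(gmax) >= 0))
  expect_true(all(diff(gmin) <= 0))
  g1 <- assign_gna(m, channel_distribution(0.5, "horizontal_ends",
                                           gbar = 10))
  g2 <- assign_gna(m, channel_distribution(0.5, "horizontal_ends",
                                           gbar = 20))
  expect_equal(g2, 2 * g1, ignore_attr = TRUE)
})

test_that("cell-length rescaling keeps the channel count constant", {
  model <- reduced_test_model()
  m0 <- tiny_mesh(1)
  A0 <- membrane_areas(m0)$A_c[1]
  # identity: same area leaves the field unchanged
  d_id <- rescale_for_cell_length(channel_distribution(0), A0)
  expect_equal(assign_gna(m0, d_id, model),
               assign_gna(m0, channel_distribution(0), model),
               ignore_attr = TRUE)
  # longer cell, uniform: density scales by A0/A_c, totals match
  geo_long <- cell_geometry(size_O = c(32, 6, 6), size_WE = c(2, 2, 2),
                            size_SN = c(4, 2, 4))
  mL <- tiny_mesh(1, geo = geo_long)
  quadL <- membrane_areas(mL)
  gU <- assign_gna(mL, rescale_for_cell_length(channel_distribution(0), A0),
                   model)
  expect_lt(abs(sum(gU * quadL$A) - A0 * model$gbar_na) /
              (A0 * model$gbar_na), 1e-12)
  expect_true(all(gU < model$gbar_na))  # density dilutes on a longer cell
  # NU p = 1: junctional density depends on A_c* and A_j only, so with the
  # same A_j it matches the default-cell value
  gN0 <- assign_gna(m0, rescale_for_cell_length(
    channel_distribution(1, "horizontal_ends"), A0), model)
  gNL <- assign_gna(mL, rescale_for_cell_length(
    channel_distribution(1, "horizontal_ends"), A0), model)
  expect_equal(max(gNL), max(gN0), tolerance = 1e-12)
})

test_that("an empty junctional region with p > 0 is rejected", {
  geo <- cell_geometry(size_O = c(12, 6, 6), size_WE = 0, size_SN = 0)
  m <- build_strand(geo, strand_layout(1, padding = c(4, 4, 3)),
                    grid_spec(1, 1, 1))
  expect_error(
    assign_gna(m, channel_distribution(0.5, "horizontal_ends"),
               reduced_test_model()),
    "Omega_W")
})
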