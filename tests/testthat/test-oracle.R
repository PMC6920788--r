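test_that("oracle gives exactly zero for zero boundary data", {
  p <- ref_params
  g <- protein_geometry(1.6, 2 * p$h_s, 0, 0)
  expect_equal(oracle_energy(p, g, domain_configuration(1.6, 1.6, g), 0.05),
               0, tolerance = 1e-12)
})

test_that("oracle refuses a grid that cannot resolve the decay length", {
  g <- open_geom(0.3, 0)
  expect_error(discretize(ref_params, g, domain_configuration(1.6, 1.6, g),
                          grid_step = 0.2),
               "grid too coarse")
})

test_that("oracle energy converges with the square of the grid step", {
  p <- ref_params
  g <- protein_geometry(1.6, 2 * p$h_r, 0.3, -0.1)
  conf <- domain_configuration(1.6, 1.6, g)
  Ws <- vapply(c(0.1, 0.05, 0.025), function(gs) oracle_energy(p, g, conf, gs), 1)
  d <- diff(Ws)
  expect_gt(abs(d[1] / d[2]), 2.8)   # second order: ratio ~ 4
  expect_lt(abs(d[1] / d[2]), 5.5)
})

test_that("oracle and Galerkin solver agree on the reference configuration", {
  p <- ref_params
  conf <- domain_configuration(ref_asym$Rd, ref_asym$Ru, ref_asym$geom)
  Wo <- oracle_energy(p, ref_asym$geom, conf, 0.025)
  Ws <- energy_of_configuration(p, ref_asym$geom, ref_asym$Rd, ref_asym$Ru)
  expect_lt(abs(Wo - Ws) / max(Ws, 1), 0.01)
})

test_that("direct minimization is deterministic and returns the profile", {
  p <- ref_params
  g <- open_geom(0.3, -0.1)
  f <- discretize(p, g, domain_configuration(1.6, 1.6, g), 0.05)
  m1 <- minimize_direct(f)
  m2 <- minimize_direct(f)
  expect_identical(m1$W, m2$W)
  expect_equal(m1$profile$n_a[1], 0.3, tolerance = 1e-9)
  expect_equal(m1$profile$n_b[1], -0.1, tolerance = 1e-9)
})

test_that("planar straight-wall limit behaves and anchors the cylindrical solver", {
  p <- ref_params
  expect_equal(planar_limit_energy(0, p), 0, tolerance = 1e-12)
  w1 <- planar_limit_energy(0.3, p)
  expect_equal(planar_limit_energy(0.6, p) / w1, 4, tolerance = 1e-6)
  expect_error(planar_limit_energy(0.9, p), "0.7")
  # large-radius cylindrical wall, no mismatch: energy per unit length
  g <- protein_geometry(100, 2 * p$h_s, 0.3, 0.3)
  Wc <- energy_of_configuration(p, g, 100, 100)
  expect_lt(abs(Wc / (2 * pi * 100) - w1) / w1, 0.02)
})
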