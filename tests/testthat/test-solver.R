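test_that("undeformed reference state has exactly zero energy", {
  # no domain, TMD length matched to the disordered bilayer, flat directors
  p <- ref_params
  g <- protein_geometry(1.6, 2 * p$h_s, 0, 0)
  expect_equal(energy_of_configuration(p, g, 1.6, 1.6), 0, tolerance = 1e-12)
  pr <- solve_profile(p, g, domain_configuration(1.6, 1.6, g))
  expect_lt(max(abs(pr$fields$n_a)), 1e-10)
  expect_lt(max(abs(pr$fields$M)), 1e-10)
})

test_that("any nonzero admissible deformation costs positive energy", {
  p <- ref_params
  W <- energy_of_configuration(p, open_geom(0.3, 0.1), 1.6, 1.6)
  expect_gt(W, 0)
})

test_that("energy is quadratic in boundary directors without mismatch", {
  p <- ref_params
  gl <- function(l) protein_geometry(1.6, 2 * p$h_s, 0.3 * l, -0.2 * l)
  W1 <- energy_of_configuration(p, gl(1), 1.6, 1.6)
  W2 <- energy_of_configuration(p, gl(2), 1.6, 1.6)
  Wh <- energy_of_configuration(p, gl(0.5), 1.6, 1.6)
  expect_equal(W2 / W1, 4, tolerance = 0.005)
  expect_equal(Wh / W1, 0.25, tolerance = 0.005)
})

test_that("energy is invariant under relabelling the two leaflets", {
  p <- ref_params
  W1 <- energy_of_configuration(p, protein_geometry(1.6, 3.6, 0.5, -0.2), 5.6, 8.6)
  W2 <- energy_of_configuration(p, protein_geometry(1.6, 3.6, -0.2, 0.5), 8.6, 5.6)
  expect_equal(W1, W2, tolerance = 1e-9)
})

test_that("mirror-symmetric input gives a mirror-symmetric profile", {
  p <- ref_params
  g <- protein_geometry(1.6, 2 * p$h_r, 0.4, 0.4)
  pr <- solve_profile(p, g, domain_configuration(6, 6, g))
  expect_lt(max(abs(pr$fields$M)), 1e-8)
  expect_lt(max(abs(pr$fields$n_a - pr$fields$n_b)), 1e-8)
  expect_lt(max(abs(pr$fields$H_a + pr$fields$H_b)), 1e-7)
})

test_that("deformations decay in the far field and at truncation", {
  pr <- solve_profile(ref_params, ref_asym$geom,
                      domain_configuration(ref_asym$Rd, ref_asym$Ru, ref_asym$geom))
  f <- pr$fields
  peak <- max(abs(f$n_a), abs(f$n_b))
  # the tilt modes decay on sqrt(B/K) = 1 nm: ten decay lengths past the
  # last boundary the tilt is below 1e-3 of its peak.  (The directors
  # themselves also ride the much slower bending-tension mode of decay
  # length sqrt(B/sigma) ~ 32 nm, so only the truncation-residual bound
  # applies to them.)
  # (a small tension-mode floor ~1e-3 of the peak remains under the slow
  # mode, so the bound is a few times 1e-3)
  peak_t <- max(abs(f$t_a), abs(f$t_b))
  far10 <- f[f$r >= ref_asym$Ru + 10, ]
  expect_lt(max(abs(far10$t_a), abs(far10$t_b)), 5e-3 * peak_t)
  last <- f[nrow(f), ]
  expect_lt(max(abs(last$n_a), abs(last$n_b), abs(last$M)), 1e-6 * peak)
  expect_lt(abs(last$H_a - ref_params$h_s), 1e-6)
  expect_lt(abs(last$H_b + ref_params$h_s), 1e-6)
})

test_that("directors and neutral surfaces are continuous across interfaces", {
  pr <- solve_profile(ref_params, ref_asym$geom,
                      domain_configuration(ref_asym$Rd, ref_asym$Ru, ref_asym$geom))
  f <- pr$fields
  for (rs in c(ref_asym$Rd, ref_asym$Ru)) {
    at <- f[abs(f$r - rs) < 1e-9, ]
    expect_equal(nrow(at), 2L)  # duplicated interface node
    expect_lt(abs(diff(at$n_a)), 1e-8)
    expect_lt(abs(diff(at$n_b)), 1e-8)
    expect_lt(abs(diff(at$H_a)), 1e-7)
    expect_lt(abs(diff(at$H_b)), 1e-7)
  }
})

test_that("energy breakdown components sum to the total and are positive", {
  pr <- solve_profile(ref_params, ref_asym$geom,
                      domain_configuration(ref_asym$Rd, ref_asym$Ru, ref_asym$geom))
  br <- elastic_energy(pr)
  expect_equal(sum(br$components$energy), br$W_total, tolerance = 1e-10)
  expect_true(all(br$components$energy >= 0))
  expect_setequal(unique(br$components$mode), c("bending", "tilt", "tension"))
})

test_that("energy converges under mesh refinement and truncation doubling", {
  p <- ref_params
  W <- energy_of_configuration(p, ref_asym$geom, ref_asym$Rd, ref_asym$Ru)
  Wf <- energy_of_configuration(p, ref_asym$geom, ref_asym$Rd, ref_asym$Ru,
                                solver_control(h_min = 0.05))
  Wt <- energy_of_configuration(p, ref_asym$geom, ref_asym$Rd, ref_asym$Ru,
                                solver_control(far = 160))
  expect_lt(abs(Wf - W) / W, 5e-4)
  expect_lt(abs(Wt - W) / W, 5e-4)
})

test_that("energy matrix reproduces direct solves for arbitrary directors", {
  p <- ref_params
  g0 <- protein_geometry(1.6, 3.6, 0, 0)
  S <- energy_matrix(p, g0, domain_configuration(5.6, 8.6, g0))
  for (nn in list(c(0.5, -0.2), c(-0.3, 0.6), c(0, 0))) {
    y <- c(1, nn[1], nn[2])
    Wq <- as.numeric(y %*% S %*% y) / 2
    Wd <- energy_of_configuration(p, protein_geometry(1.6, 3.6, nn[1], nn[2]),
                                  5.6, 8.6)
    expect_equal(Wq, Wd, tolerance = 1e-9)
  }
})
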