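test_that("chemical potential vanishes for a flat energy curve", {
  cur <- energy_curve(seq(1, 100, 1), rep(5, 100), "area")
  mu <- chemical_potential(cur, 0.5, params = ref_params)
  expect_lt(max(abs(mu)), 1e-10)
})

test_that("chemical potential of a perimeter-like curve matches the closed form", {
  s <- seq(10, 200, 2)
  cc <- 0.01
  cur <- energy_curve(s, cc * sqrt(s), "area")
  mu <- chemical_potential(cur, 0.5, params = ref_params)
  expect_equal(mu, 0.5 * cc / (2 * sqrt(s)), tolerance = 1e-2)
  expect_lt(abs(mu[length(mu)]), 0.1 * ref_params$kT * ref_params$Delta)
})

test_that("a non-decaying tail raises a range-too-small error", {
  s <- seq(1, 30, 1)
  cur <- energy_curve(s, sqrt(s), "area")  # mu ~ 0.045 at s = 30
  expect_error(chemical_potential(cur, 0.5, params = ref_params),
               "range-too-small")
})

test_that("free energy satisfies the exact integral identity", {
  p <- ref_params
  s <- seq(0, 300, 10)
  W <- 30 - 20 * s / (s + 40) + 0.03 * sqrt(s)   # arbitrary smooth curve
  cur <- energy_curve(s, W, "area")
  E <- free_energy(cur, p)
  expect_equal(E - (W - W[1]) - p$kT * p$Delta * (s - s[1]) / p$a_qm,
               rep(0, length(s)), tolerance = 1e-14)
  # zero subsaturation: E is the elastic excess alone
  p0 <- make_params(Delta = 0)
  expect_equal(free_energy(cur, p0), W - W[1], tolerance = 1e-14)
  # large-s slope of E approaches kT*Delta/a_qm as mu -> 0
  tc <- thermo_curves(energy_curve(seq(1e4, 2e4, 100), rep(7, 101), "area"), p)
  slope <- diff(tc$E) / diff(tc$s)
  expect_equal(mean(slope), p$kT * p$Delta / p$a_qm, tolerance = 1e-8)
})

test_that("equilibria of a synthetic double-well curve are classified correctly", {
  p <- ref_params
  s <- seq(0, 12, 0.25)
  # E'(s) = (s-3)(s-5)(s-8): minima at 3 (metastable) and 8 (stable, deeper),
  # nucleation barrier at 5
  Et <- s^4 / 4 - 16 * s^3 / 3 + 39.5 * s^2 - 120 * s
  W <- Et - p$kT * p$Delta * s / p$a_qm + 50
  tc <- thermo_curves(energy_curve(s, W, "area"), p)
  eq <- find_equilibria(tc)
  expect_true(attr(eq, "stable"))
  expect_equal(nrow(eq), 3L)
  expect_equal(eq$s_eq[eq$classification == "stable"], 8, tolerance = 0.02)
  expect_equal(eq$s_eq[eq$classification == "metastable"], 3, tolerance = 0.02)
  expect_equal(eq$s_eq[eq$classification == "unstable"], 5, tolerance = 0.02)
  # at every equilibrium the chemical potential balances the subsaturation
  for (i in seq_len(nrow(eq))) {
    expect_lt(abs(eq$mu_eq[i] + p$kT * p$Delta), 5e-3)
  }
})

test_that("monotonically increasing free energy reports no equilibria", {
  p <- ref_params
  s <- seq(0, 50, 1)
  tc <- thermo_curves(energy_curve(s, 2 * s + 3, "area"), p)
  eq <- find_equilibria(tc)
  expect_false(attr(eq, "stable"))
  expect_equal(sum(eq$classification %in% c("stable", "metastable")), 0L)
})

test_that("a curve ending on a downslope demands a larger range", {
  p <- ref_params
  s <- seq(0, 10, 0.5)
  tc <- thermo_curves(energy_curve(s, -s^2, "area"), p)
  expect_error(find_equilibria(tc), "range-too-small")
})

test_that("optimal partition handles the degenerate and symmetric cases", {
  p <- ref_params
  g <- open_geom()
  p0 <- optimal_partition(p, g, 0)
  expect_equal(c(p0$Rd, p0$Ru), c(1.6, 1.6))
  expect_equal(p0$class, "none")
  # mirror-symmetric directors: the optimum is either the equal split or one
  # of a mirror-degenerate pair of asymmetric partitions with equal energy
  # (the functional is leaflet-swap symmetric, so symmetry may break
  # spontaneously, but never towards one leaflet preferentially)
  gs <- protein_geometry(1.6, 2 * p$h_r, 0.6, 0.6)
  s_eq <- 2 * pi * ((1.6 + 4)^2 - 1.6^2)
  ps <- optimal_partition(p, gs, s_eq, dL = 0.5)
  W_swap <- energy_of_configuration(p, gs, ps$Ru, ps$Rd)
  expect_equal(ps$W, W_swap, tolerance = 1e-8)
})

test_that("raising the subsaturation never enlarges the stable film", {
  p <- ref_params
  Rp <- 5
  g0 <- protein_geometry(Rp, 2 * p$h_r, 0, 0)
  Ls <- c(0, seq(2, 10, 0.5))
  W <- vapply(Ls, function(L) energy_of_configuration(p, g0, Rp + L, Rp + L), 1)
  s <- 2 * pi * ((Rp + Ls)^2 - Rp^2)
  sizes <- vapply(c(0.005, 0.01, 0.02), function(D) {
    pD <- make_params(Delta = D)
    eq <- find_equilibria(thermo_curves(energy_curve(s, W, "area"), pD))
    st <- eq[eq$classification == "stable", ]
    if (nrow(st)) st$s_eq else 0
  }, 1)
  expect_true(all(diff(sizes) <= 1e-9))
})
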