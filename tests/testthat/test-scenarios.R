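# Scenario-level behaviour on coarse grids (the full-resolution phase
# portraits are exercised by the acceptance suite).

test_that("monolayer portrait classifies cells and satisfies the mu balance", {
  p <- ref_params
  pt <- monolayer_wetting_portrait(p, 1.6, grid_step = 0.2)
  expect_setequal(unique(pt$class), c("none", "inner-domain"))
  expect_equal(nrow(pt), 64L)  # 8 x 8 director grid at step 0.2
  st <- pt[pt$class == "inner-domain", ]
  expect_gt(nrow(st), 0)
  # every stable cell satisfies the equilibrium condition mu = -kT Delta
  expect_lt(max(abs(st$mu_res)), 5e-3)
  # widths of stable inner domains are in the few-nanometre range
  expect_true(all(st$L_d > 2 & st$L_d < 8))
})

test_that("saturating the inner leaflet can only enlarge the stable set", {
  p <- ref_params
  pt1 <- monolayer_wetting_portrait(p, 1.6, grid_step = 0.2)
  p0 <- make_params(Delta = 0)
  pt0 <- monolayer_wetting_portrait(p0, 1.6, grid_step = 0.2)
  s1 <- pt1$class == "inner-domain"
  s0 <- pt0$class == "inner-domain"
  expect_true(all(s0[s1]))   # Delta = 0 stable set contains the Delta = 0.01 set
  expect_gte(sum(s0), sum(s1))
})

test_that("width measurement summarizes stable configurations and flags spread", {
  fake <- data.frame(stable = c(TRUE, TRUE, TRUE, FALSE),
                     L_d = c(4, 4.2, 3.8, NA), L_u = c(7, 6.5, 7.5, NA))
  m <- measure_stable_widths(fake)
  expect_equal(m$n, 3L)
  expect_equal(unname(m$L_d["mean"]), 4, tolerance = 1e-9)
  expect_false(m$wide_spread)
  fake$L_u <- c(2, 7, 12, NA)
  expect_true(measure_stable_widths(fake)$wide_spread)
  expect_error(measure_stable_widths(data.frame(stable = FALSE, L_d = NA, L_u = NA)),
               "empty sample")
})

test_that("no stable film grows around a narrow TMD in the symmetric sweep", {
  fs <- symmetric_film_scan(ref_params, c(2, 5), L_max = 10)
  expect_equal(fs$width[fs$Rp == 2], 0)        # width below 1 nm (none at all)
  expect_gt(fs$width[fs$Rp == 5], 2)           # a stable film exists by 5 nm
  expect_true(all(diff(fs$width) >= -0.3))
})

test_that("portrait results are reproducible across repeated runs", {
  p <- ref_params
  a <- monolayer_wetting_portrait(p, 0.9, grid_step = 0.2)
  b <- monolayer_wetting_portrait(p, 0.9, grid_step = 0.2)
  expect_identical(a$class, b$class)
  expect_identical(a$L_d, b$L_d)
})
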