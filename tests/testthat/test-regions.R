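test_that("region decomposition tiles the membrane with correct thicknesses", {
  p <- ref_params
  g <- open_geom()

  # no ordered annulus: one region, both leaflets disordered
  r0 <- build_regions(p, g, domain_configuration(1.6, 1.6, g))
  expect_equal(nrow(r0), 1L)
  expect_equal(r0$h0_upper, p$h_s)
  expect_equal(r0$h0_lower, p$h_s)
  expect_equal(r0$r_in, 1.6)
  expect_true(is.infinite(r0$r_out))

  # staggered annuli: bilayer-ordered, upper-only, disordered
  r3 <- build_regions(p, g, domain_configuration(5.6, 8.6, g))
  expect_equal(nrow(r3), 3L)
  expect_equal(r3$r_in, c(1.6, 5.6, 8.6))
  expect_equal(r3$h0_upper, c(p$h_r, p$h_r, p$h_s))
  expect_equal(r3$h0_lower, c(p$h_r, p$h_s, p$h_s))

  # swapped: middle region ordered in the lower leaflet only
  r3b <- build_regions(p, g, domain_configuration(8.6, 5.6, g))
  expect_equal(r3b$h0_upper, c(p$h_r, p$h_s, p$h_s))
  expect_equal(r3b$h0_lower, c(p$h_r, p$h_r, p$h_s))

  # coincident radii collapse the middle region
  r2 <- build_regions(p, g, domain_configuration(5.6, 5.6 + 1e-12, g))
  expect_equal(nrow(r2), 2L)
})
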