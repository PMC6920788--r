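test_that("reference parameter set matches the model lipid values", {
  p <- make_params()
  expect_equal(p$B, 10)
  expect_equal(p$K, 10)       # 40 mN/m in kBT0/nm^2
  expect_equal(p$sigma, 0.01)
  expect_equal(p$h_r, 1.8)
  expect_equal(p$h_s, 1.3)
  expect_equal(p$Delta, 0.01) # 1 percent subsaturation
  expect_equal(p$kT, 1)
  expect_equal(p$a_qm, 0.5)
})

test_that("parameter overrides and validation behave", {
  expect_equal(make_params(Delta = 0)$Delta, 0)
  expect_equal(make_params(list(B = 12, sigma = 0.02))$B, 12)
  expect_error(make_params(list(bogus = 1)), "unknown parameter")
  expect_error(make_params(h_r = 1.0), "h_r")        # thinner than h_s
  expect_error(make_params(Delta = -0.01), "Delta")
  expect_error(make_params(K = 0), "K")
  # equality h_r = h_s is the degenerate no-mismatch membrane, allowed
  expect_silent(make_params(h_r = 1.3))
})

test_that("protein geometry validates the small-deformation range", {
  g <- protein_geometry(1.6, 3.6, 0.5, -0.2)
  expect_equal(g$Rp, 1.6)
  expect_error(protein_geometry(-1, 3.6), "Rp")
  expect_error(protein_geometry(1.6, 3.6, n1 = 0.9), "n1")
  expect_error(protein_geometry(1.6, 3.6, n2 = -0.8), "n2")
})

test_that("EGFR conformation presets set the radii and TMD length", {
  g <- egfr_geometry("closed", -0.3, 0.0)
  expect_equal(g$Rp, 0.9)
  expect_equal(g$Hp, 3.6)  # 2 * h_r: zero mismatch with the ordered phase
  expect_equal(g$n1, -0.3)
  g2 <- egfr_geometry("open", 0.5, -0.2)
  expect_equal(g2$Rp, 1.6)
  expect_equal(g2$Hp, 3.6)
  expect_error(egfr_geometry("halfway"), "conformation")
  expect_error(egfr_geometry("open", n1 = 0.9), "n1")
})

test_that("domain configuration derives widths and rejects radii inside the wall", {
  g <- open_geom()
  conf <- domain_configuration(5.6, 8.6, g)
  expect_equal(conf$L_d, 4)
  expect_equal(conf$L_u, 7)
  expect_error(domain_configuration(1.0, 8.6, g), "Rd")
})

test_that("configuration round-trips through YAML", {
  cfg <- read_config(system.file("extdata/default_config.yaml", package = "memwet"))
  tmp <- tempfile(fileext = ".yaml")
  write_config(cfg, tmp)
  cfg2 <- read_config(tmp)
  expect_equal(cfg2$params[], cfg$params[])
  expect_equal(cfg2$geometry[], cfg$geometry[])
  expect_equal(cfg2$scan, cfg$scan)
  # overrides reach nested fields and are validated
  cfg3 <- read_config(tmp, overrides = "params.Delta=0.02")
  expect_equal(cfg3$params$Delta, 0.02)
  expect_error(read_config(tmp, overrides = "params.Delta=-1"), "Delta")
  expect_error(read_config(tmp, overrides = "geometry.n1=0.9"), "n1")
})
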