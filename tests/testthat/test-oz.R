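test_that("low-density limit recovers the ideal insertion work", {
  sv <- solvent_model(rho = 1e-6)
  sol <- solve_oz(sv, solute_diameter = 5)
  ref <- 1e-6 * (4 * pi / 3) * ((5 + 2.8) / 2)^3
  expect_lt(abs(sol$beta_mu_ex - ref) / ref, 0.01)
})

test_that("PY chemical potential stays close to Carnahan-Starling", {
  sv <- solvent_model()
  sol <- solve_oz(sv, solute_diameter = sv$d, closure = "PY",
                  charging_nodes = 12L)
  cs <- carnahan_starling_mu(sv$eta)
  expect_lt(abs(sol$beta_mu_ex - cs) / cs, 0.10)
})

test_that("HNC chemical-potential routes are mutually consistent", {
  ## the Morita-Hiroike functional and exact hard-particle charging are
  ## independent routes to the same closure's mu; their agreement checks
  ## the solver, independently of how accurate the closure itself is
  sv <- solvent_model()
  grid <- radial_grid(2048L, 0.04)
  sol <- solve_oz(sv, solute_diameter = sv$d, grid = grid)
  bulk <- hydromorph:::oz_bulk_pair(sv, "HNC", grid)
  mu_charge <- local({
    g2 <- radial_grid(4096L, 0.02)
    fine <- hydromorph:::.mu_charging(sv, sv$d, "HNC", g2, 0.3, 1e-8, 20000L,
                                      bulk$fine, nodes = 12L)
    coarse <- hydromorph:::.mu_charging(sv, sv$d, "HNC", grid, 0.3, 1e-8,
                                        20000L, bulk$coarse, nodes = 12L)
    2 * fine - coarse
  })
  expect_lt(abs(sol$beta_mu_ex - mu_charge) / sol$beta_mu_ex, 0.03)
})

test_that("solver is deterministic and validates inputs", {
  sv <- solvent_model()
  g <- radial_grid(2048L, 0.04)
  a <- solve_oz(sv, 2.0, grid = g)
  b <- solve_oz(sv, 2.0, grid = g)
  expect_identical(a$beta_mu_ex, b$beta_mu_ex)
  expect_error(solve_oz(sv, -1, grid = g), ">= 0")
  expect_error(solve_oz(sv, 2, grid = radial_grid(256L, 0.02)),
               "20 solvent diameters")
  expect_error(solvent_model(rho = 0.2), "packing fraction")
  expect_error(radial_grid(1000L), "power of two")
})

test_that("sphere entropy is negative and strictly decreasing in radius", {
  sv <- solvent_model()
  g <- radial_grid(2048L, 0.04)
  bulk <- hydromorph:::oz_bulk_pair(sv, "HNC", g)
  s <- vapply(c(0, 1, 3), function(R)
    sphere_entropy(sv, R, grid = g, bulk = bulk), 0)
  expect_true(all(s < 0))
  expect_true(abs(s[2]) > abs(s[1]))
  expect_true(abs(s[3]) > abs(s[2]))
})

test_that("calibration reproduces its points and predicts held-out spheres", {
  co <- hm_coeffs()
  expect_lt(co$c_V, 0)
  expect_true(all(abs(co$residuals) <= 2 * co$fit_rms + 1e-12))
  pred <- predict_sphere_entropy(co, 4.25)
  act <- sphere_entropy(co$solvent, 4.25)
  expect_lt(abs(pred - act), 3 * co$fit_rms)
  ## the volume term dominates for solutes beyond ~3 solvent diameters
  m <- sphere_measures(3 * co$solvent$d + co$solvent$d / 2)
  expect_gt(abs(co$c_V * m["V"]),
            abs(co$c_A * m["A"]) + abs(co$c_C * m["C"]) + abs(co$c_X * m["X"]))
})

test_that("calibration validates its inputs and is reproducible", {
  sv <- solvent_model()
  expect_error(calibrate(sv, radii = c(1, 2, 3)), "at least 8")
  expect_error(calibrate(sv, radii = seq(1, 8, length.out = 10)),
               "span at least")
  co1 <- hm_coeffs()
  co2 <- calibrate(solvent_model())
  expect_identical(co1$c_V, co2$c_V)
  expect_identical(co1$id, co2$id)
})

test_that("coefficients survive a JSON round trip", {
  co <- hm_coeffs()
  f <- tempfile(fileext = ".json")
  write_coefficients(co, f)
  co2 <- read_coefficients(f)
  expect_equal(co2$c_V, co$c_V, tolerance = 1e-12)
  expect_identical(co2$id, co$id)
  expect_equal(co2$solvent$d, co$solvent$d)
  notco <- tempfile(fileext = ".json")
  jsonlite::write_json(list(something = 1), notco, auto_unbox = TRUE)
  expect_error(read_coefficients(notco), "not a coefficients")
})
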