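test_that("exact backend reproduces closed forms for spheres and pairs", {
  for (fx in analytic_fixtures()) {
    m <- measures_exact(fx$spheres)
    expect_lt(max(abs(m - fx$measures) / pmax(abs(fx$measures), 1e-12)), 1e-9,
              label = sprintf("fixture %s relative error", fx$name))
  }
  ## a grid of radii and separations with lens closed forms
  for (r in c(0.8, 1.4, 2.8)) for (f in c(0.3, 0.8, 1.3)) {
    d <- f * r
    ss <- sphere_set(rbind(c(0, 0, 0), c(d, 0, 0)), c(r, r), "pairgrid")
    vref <- 2 * sphere_measures(r)["V"] - lens_volume(r, r, d)
    expect_lt(abs(measures_exact(ss)["V"] - vref) / vref, 1e-9)
  }
})

test_that("exact volume agrees with an independent hit-or-miss oracle on a triple overlap", {
  tri <- sphere_set(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                    rep(1, 3), "triangle")
  m <- measures_exact(tri)
  vo <- mc_volume_oracle(tri, n = 2e6, seed = 42)
  expect_lt(abs(m["V"] - vo["value"]), 4 * vo["se"])
  expect_equal(unname(m["X"]), 4 * pi, tolerance = 1e-12)
})

test_that("measures are additive over far-separated components", {
  a <- random_cluster(8, seed = 5)
  b <- transform_spheres(random_cluster(7, seed = 6), shift = c(60, 0, 0))
  both <- combine_spheres(a, b)
  m <- measures_exact(both)
  ref <- measures_exact(a) + measures_exact(b)
  expect_lt(max(abs(m - ref) / pmax(abs(ref), 1)), 1e-12)
})

test_that("rigid motion leaves all four measures unchanged", {
  ss <- random_cluster(20, seed = 9)
  m1 <- measures_exact(ss)
  m2 <- measures_exact(transform_spheres(ss, angle = 71.3, shift = c(-4, 9, 2)))
  expect_lt(max(abs(m1 - m2) / abs(m1)), 1e-9)
})

test_that("adding a sphere never decreases the union volume", {
  ss <- random_cluster(12, seed = 11)
  v0 <- measures_exact(ss)["V"]
  for (extra in list(c(0, 0, 0), c(2, 1, 0), c(50, 0, 0))) {
    grown <- combine_spheres(ss, sphere_set(matrix(extra, 1, 3), 1.2, "extra"))
    expect_gte(measures_exact(grown)["V"], v0 - 1e-9)
  }
})

test_that("Euler term counts components and handles rings", {
  two <- sphere_set(rbind(c(0, 0, 0), c(10, 0, 0)), c(2.8, 2.8), "two")
  expect_equal(unname(measures_exact(two)["X"]), 8 * pi, tolerance = 1e-12)
  ring <- sphere_set(rbind(c(1.2, 0, 0), c(0, 1.2, 0), c(-1.2, 0, 0),
                           c(0, -1.2, 0)), rep(1, 4), "ring")
  expect_equal(unname(measures_exact(ring)["X"]), 0, tolerance = 1e-9)
})

test_that("steiner MC backend matches closed form for a single sphere", {
  ss <- sphere_set(matrix(0, 1, 3), 2.8, "s")
  est <- measures_steiner_mc(ss, epsilons = c(0, 0.2, 0.4, 0.6),
                             n_samples = 1e6, seed = 11)
  ref <- sphere_measures(2.8)
  expect_true(all(abs(est$value - ref) <= 3 * est$standard_error))
})

test_that("steiner MC backend is deterministic under a fixed seed", {
  ss <- lattice_cluster(15, 3.6, seed = 4)
  a <- measures_steiner_mc(ss, n_samples = 1e5, seed = 7)
  b <- measures_steiner_mc(ss, n_samples = 1e5, seed = 7)
  expect_identical(a, b)
  c2 <- measures_steiner_mc(ss, n_samples = 1e5, seed = 8)
  expect_false(identical(a$value, c2$value))
})

test_that("measures() dispatches by size and validates the method", {
  small <- random_cluster(5, seed = 2)
  est <- measures(small, probe = 1.4, method = "auto")
  expect_identical(est$method, "exact")
  expect_true(all(est$standard_error == 0))
  est2 <- measures(small, probe = 1.4, method = "auto", exact_limit = 3L,
                   n_samples = 1e5, seed = 1)
  expect_identical(est2$method, "steiner_mc")
  expect_error(measures(small, method = "exact", exact_limit = 3L),
               "exceeds the exact-backend limit")
})

test_that("dilate grows radii only and rejects negative probes", {
  ss <- sphere_set(rbind(c(0, 0, 0), c(3, 0, 0)), c(1.4, 1.7), "d")
  d <- dilate(ss, 1.4)
  expect_equal(d$radii, c(2.8, 3.1))
  expect_identical(d$centers, ss$centers)
  expect_identical(dilate(ss, 0)$radii, ss$radii)
  expect_error(dilate(ss, -0.1), "non-negative")
})

test_that("degenerate tangency is rejected with the pair named", {
  ss <- sphere_set(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1), "tangent")
  expect_error(measures_exact(ss), "near-tangent")
})
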