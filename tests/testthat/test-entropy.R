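test_that("structure entropy matches the sphere solver at calibration scale", {
  co <- hm_coeffs()
  res <- s1_structure(sphere_set(matrix(0, 1, 3), 2.0, "sphere2"), co)
  expect_lt(abs(res$s1 - sphere_entropy(co$solvent, 2.0)), 2 * co$fit_rms)
  expect_equal(res$s1, sum(res$terms), tolerance = 1e-12)
  expect_lt(res$s1, 0)
})

test_that("entropy is additive over far-separated copies", {
  co <- hm_coeffs()
  a <- random_cluster(10, seed = 21, label = "copyA")
  b <- transform_spheres(a, shift = c(80, 0, 0))
  b$label <- "copyB"
  s_one <- s1_structure(a, co)$s1
  s_two <- s1_structure(combine_spheres(a, b, label = "both"), co)$s1
  expect_equal(s_two, 2 * s_one, tolerance = 1e-9)
})

test_that("exact and stochastic backends give compatible entropies", {
  co <- hm_coeffs()
  ss <- lattice_cluster(30, 3.6, seed = 31)
  ex <- s1_structure(ss, co, method = "exact")
  mc <- s1_structure(ss, co, method = "steiner_mc", n_samples = 1e6, seed = 5)
  expect_lt(abs(ex$s1 - mc$s1), 3 * mc$standard_error)
})

test_that("probe-solvent mismatch is rejected", {
  co <- hm_coeffs()
  ss <- sphere_set(matrix(0, 1, 3), 2, "s")
  expect_error(s1_structure(ss, co, probe = 1.0), "does not match")
})

test_that("relative table picks the most closely packed reference", {
  mk <- function(label, s1) structure(list(label = label, s1 = s1,
                                           coefficients_id = "test"),
                                      class = "entropy_result")
  tab <- relative_table(list(mk("x", -100), mk("y", -150), mk("z", -130)))
  expect_identical(attr(tab, "reference_label"), "x")
  expect_equal(tab$relative_s1, c(0, -50, -30))
  expect_true(all(tab$relative_s1[!tab$is_reference] < 0))
  expect_error(relative_table(list(mk("x", -1))), "length")
  expect_error(relative_table(list(mk("x", -1), mk("x", -2))), "duplicate")
  ## tie at the reference is flagged and broken by label order
  tab2 <- relative_table(list(mk("b", -100.4), mk("a", -100.0)), tie_tol = 1)
  expect_identical(attr(tab2, "reference_label"), "a")
  expect_true(tab2$tie_with_reference[tab2$label == "b"])
})

test_that("entropy-to-free-energy conversion has the right scale and inverts", {
  expect_equal(entropy_to_free_energy(0)$delta_g_kbt, 0)
  ## a -20 k_B T free-energy drop at 298 K is -12 kcal/mol to the nearest
  ## kcal/mol
  conv <- entropy_to_free_energy(20, 298)
  expect_equal(conv$delta_g_kbt, -20)
  expect_equal(round(conv$delta_g_kcal_mol), -12)
  ## a protein-folding scale water-entropy gain of ~670 k_B
  conv2 <- entropy_to_free_energy(670, 298)
  expect_equal(conv2$delta_g_kbt, -670)
  expect_lt(conv2$delta_g_kcal_mol, 0)
  ## unit round trip
  kbt <- conv$delta_g_kcal_mol / (conv$kb_kcal_per_mol_K * 298)
  expect_equal(kbt, conv$delta_g_kbt, tolerance = 1e-12)
})

test_that("the packing comparator honors magnitude and tolerance", {
  expect_identical(pe_compare(-100, -200), 1L)
  expect_identical(pe_compare(-200, -100), -1L)
  expect_identical(pe_compare(-100.0, -100.5), 0L)
  expect_identical(pe_compare(-102, -100.0, tol = 1), -1L)
})
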