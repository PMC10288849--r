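test_that("packing-efficiency variants satisfy their defining identity", {
  co <- hm_coeffs()
  sub <- random_cluster(12, seed = 41, label = "sub")
  lig <- transform_spheres(random_cluster(4, seed = 42, sd = 1.0), shift = c(3.5, 0, 0))
  lig$label <- "lig"
  e1a <- packing_efficiency(sub, variant = "eq1a", coefficients = co)
  expect_equal(e1a$eta, s1_structure(sub, co)$s1, tolerance = 1e-12)
  e1b <- packing_efficiency(sub, lig, "eq1b", co)
  e2a <- packing_efficiency(sub, lig, "eq2a", co)
  e2b <- packing_efficiency(sub, lig, "eq2b", co)
  expect_equal((e1a$eta - e1b$eta) - (e2a$eta - e2b$eta), 0, tolerance = 1e-9)
  expect_error(packing_efficiency(sub, variant = "eq1b", coefficients = co),
               "requires a ligand")
})

test_that("a ligand beyond interaction range leaves eta unchanged", {
  co <- hm_coeffs()
  sub <- random_cluster(10, seed = 43, label = "sub")
  far <- transform_spheres(random_cluster(4, seed = 44, sd = 1.0),
                           shift = c(100, 0, 0))
  far$label <- "far"
  e1a <- packing_efficiency(sub, variant = "eq1a", coefficients = co)
  e1b <- packing_efficiency(sub, far, "eq1b", co)
  expect_equal(e1a$eta, e1b$eta, tolerance = 1e-9)
})

test_that("interface gain vanishes at range, is symmetric, grows on approach", {
  co <- hm_coeffs()
  a <- random_cluster(10, seed = 45, label = "I")
  bbase <- random_cluster(10, seed = 46, label = "J")
  gain_at <- function(dx) {
    b <- transform_spheres(bbase, shift = c(dx, 0, 0)); b$label <- "J"
    pair <- combine_spheres(a, b, label = "pair")
    interface_gain(pair, a, b, co)$delta_s
  }
  expect_equal(gain_at(120), 0, tolerance = 1e-9)
  ## symmetry in I and J
  b <- transform_spheres(bbase, shift = c(9, 0, 0)); b$label <- "J"
  pair <- combine_spheres(a, b, label = "pair")
  g_ij <- interface_gain(pair, a, b, co)$delta_s
  g_ji <- interface_gain(pair, b, a, co)$delta_s
  expect_equal(g_ij, g_ji, tolerance = 1e-12)
  ## once the clusters interpenetrate, the gain grows as separation
  ## shrinks (marginal first contact sits outside this regime: there the
  ## topology term of the linear form can dip slightly negative)
  scan <- vapply(c(5, 4, 3, 2), gain_at, 0)
  expect_true(all(diff(scan) > 0))
  expect_gt(scan[4], 0)
  ## split mismatch is caught
  expect_error(interface_gain(pair, a, a, co), "rigid split")
})

test_that("association gain reduces to interface gain without a ligand and rewards bridges", {
  co <- hm_coeffs()
  toy <- generate_toy_complex(toy_complex_config(
    seed = 47, tightness = c(A_DP = 0.75, A_TP = 0.75, A_E = 0.75,
                             B_DP = 0.75, B_TP = 0.75, B_E = 0.75),
    ligands = list(A_DP = "large_bridge", A_TP = "small_bridge")))
  pair_of <- function(a, b, lig = NULL) {
    parts <- list(toy$sets[[a]], toy$sets[[b]])
    if (!is.null(lig)) parts <- append(parts, list(toy$sets[[lig]]), 1)
    whole <- do.call(combine_spheres, c(parts, list(label = "bound")))
    association_gain(toy$sets[[a]], if (!is.null(lig)) toy$sets[[lig]],
                     toy$sets[[b]], whole, co)
  }
  ## no ligand: identical to the interface gain on the same pair
  ag <- pair_of("A_E", "B_E")
  ig <- interface_gain(combine_spheres(toy$sets$A_E, toy$sets$B_E),
                       toy$sets$A_E, toy$sets$B_E, co)
  expect_equal(ag$delta_s1, ig$delta_s, tolerance = 1e-9)
  ## bridge size orders the gains: large > small > none
  g_large <- pair_of("A_DP", "B_DP", "A_DP.ligand")$delta_s1
  g_small <- pair_of("A_TP", "B_TP", "A_TP.ligand")$delta_s1
  g_none <- pair_of("A_E", "B_E")$delta_s1
  expect_gt(g_large, g_small)
  expect_gt(g_small, g_none)
})

test_that("rank_packing orders by |eta|, flags ties, and checks expected orders", {
  r <- rank_packing(c(a = -300, b = -100, c = -200))
  expect_identical(r$ranking, c("b", "c", "a"))
  r2 <- rank_packing(c(a = -100.0, b = -100.5), tol = 1)
  expect_identical(r2$ranking, c("a", "b"))
  expect_true(r2$ties[1])
  ## expected-order comparison is strict only outside the tolerance
  r3 <- rank_packing(c(a = -100.0, b = -100.5), expected = c("b", "a"), tol = 1)
  expect_true(r3$matches_expected)
  r4 <- rank_packing(c(a = -100, b = -150), expected = c("b", "a"), tol = 1)
  expect_false(r4$matches_expected)
  expect_match(r4$flipped, "b > a")
  ## invariant under a common shift of all eta values
  r5 <- rank_packing(c(a = -400, b = -200, c = -300))
  expect_identical(r5$ranking, r$ranking)
  ## provenance guard
  mk <- function(l, e, id) structure(list(subject_label = l, eta = e,
                                          bound_compound = "none",
                                          variant = "eq1a",
                                          coefficients_id = id),
                                     class = "packing_efficiency")
  expect_error(rank_packing(list(mk("a", -1, "x"), mk("b", -2, "y"))),
               "mix different calibration")
})

test_that("catalytic distance is plain geometry with named errors", {
  sub <- data.frame(chain_id = "A", residue_name = c("GLU", "GLU", "ALA"),
                    residue_number = c(261, 261, 12), insertion_code = "",
                    atom_name = c("CA", "CD", "CA"), element = "C",
                    x = c(1, 0, 5), y = 0, z = c(0, 0, 2), alt_loc = "",
                    occupancy = 1, stringsAsFactors = FALSE)
  lig <- data.frame(chain_id = "I", residue_name = "ATP", residue_number = 1,
                    insertion_code = "", atom_name = c("PG", "O1G"),
                    element = c("P", "O"), x = 0, y = 0, z = c(3, 4),
                    alt_loc = "", occupancy = 1, stringsAsFactors = FALSE)
  cd <- catalytic_distance(sub, lig)
  expect_equal(cd$L, 3)
  expect_error(catalytic_distance(sub, lig, glutamate_number = 99),
               "no GLU residue 99")
  expect_error(catalytic_distance(sub[-2, ], lig), "lacks carboxyl carbon")
  expect_error(catalytic_distance(sub, lig[-1, ]), "gamma-phosphate")
})

test_that("the assembly report is internally consistent with and without a shaft", {
  co <- hm_coeffs()
  toy <- generate_toy_complex(toy_complex_config(seed = 48, shaft = TRUE,
    ligands = list(A_DP = "large_bridge", A_TP = "large_bridge")))
  f <- tempfile(fileext = ".pdb")
  write_toy_pdb(toy, f)
  atoms <- parse_structure(f)
  spec <- toy$spec
  rep <- packing_structure_report(atoms, spec, co)
  expect_true(rep$has_shaft)
  expect_length(rep$ab_gains, 6L)
  expect_length(rep$shaft_gains, 6L)
  expect_equal(rep$shaft_gain_sum,
               sum(vapply(rep$shaft_gains, function(g) g$delta_s, 0)),
               tolerance = 1e-12)
  expect_true(rep$compensation$applied)
  ## without the shaft chain the shaft fields are empty
  atoms2 <- atoms[atoms$chain_id != "G", , drop = FALSE]
  rm2 <- spec$role_map[spec$role_map != "DF"]
  spec2 <- assembly_spec(stats::setNames(as.character(rm2), names(rm2)),
                         site_ligands = spec$site_ligands,
                         ligand_map = stats::setNames(
                           as.character(spec$ligand_map),
                           names(spec$ligand_map)))
  rep2 <- packing_structure_report(atoms2, spec2, co)
  expect_false(rep2$has_shaft)
  expect_length(rep2$shaft_gains, 0L)
  expect_true(is.na(rep2$shaft_gain_sum))
  ## artifacts can be written
  outdir <- tempfile()
  paths <- write_packing_report(rep, outdir)
  expect_true(all(file.exists(file.path(outdir, c("subunits.tsv",
                                                  "report.json")))))
})
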