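test_that("a minimal PDB round-trips with correct coordinates", {
  p <- write_mini_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 1.5, 2.25, -3.125),
    pdb_line(2, "N", "ALA", "A", 1, 0.0, 0.0, 4.0, elem = "N")))
  at <- parse_structure(p)
  expect_equal(nrow(at), 2L)
  expect_equal(at$x, c(1.5, 0))
  expect_equal(at$z, c(-3.125, 4))
  expect_identical(at$element, c("C", "N"))
})

test_that("alt-locs collapse to the highest-occupancy conformer", {
  p <- write_mini_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.6, alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = 0.4, alt = "B"),
    pdb_line(3, "CB", "ALA", "A", 1, 3.0, 0, 0)))
  at <- parse_structure(p)
  expect_equal(nrow(at), 2L)
  expect_equal(at$x[at$atom_name == "CA"], 1.0)
  ## a higher-occupancy B conformer beats A
  p3 <- write_mini_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.3, alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 4.0, 0, 0, occ = 0.7, alt = "B")))
  expect_equal(parse_structure(p3)$x, 4.0)
  ## occupancy ties break alphabetically by alt-loc id
  p2 <- write_mini_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 9.0, 0, 0, occ = 0.5, alt = "B"),
    pdb_line(2, "CA", "ALA", "A", 1, 7.0, 0, 0, occ = 0.5, alt = "A")))
  expect_equal(parse_structure(p2)$x, 7.0)
})

test_that("waters are excluded by default and empties are rejected", {
  p <- write_mini_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "O", "HOH", "W", 2, 5, 5, 5, elem = "O")))
  at <- parse_structure(p)
  expect_equal(nrow(at), 1L)
  expect_equal(nrow(parse_structure(p, keep_waters = TRUE)), 2L)
  p_water_only <- write_mini_pdb(pdb_line(1, "O", "HOH", "W", 1, 0, 0, 0,
                                          elem = "O"))
  expect_error(parse_structure(p_water_only), "no non-water atoms")
  expect_error(parse_structure(tempfile()), "not found")
})

test_that("radius assignment looks up elements and refuses unknowns", {
  tab <- c(C = 1.7, N = 1.55, O = 1.52)
  at <- data.frame(chain_id = "A", residue_name = "ALA", residue_number = 1,
                   insertion_code = "", atom_name = c("CA", "N", "O"),
                   element = c("C", "N", "O"), x = 1:3, y = 0, z = 0,
                   alt_loc = "", occupancy = 1, stringsAsFactors = FALSE)
  ss <- assign_radii(at, tab)
  expect_equal(ss$radii, c(1.7, 1.55, 1.52))
  at$element[2] <- "XX"
  expect_error(assign_radii(at, tab), "no radius .* N \\(XX\\)")
  ## single carbon from the shipped table
  ss1 <- assign_radii(at[1, ], default_radius_table())
  expect_equal(ss1$radii, 1.7)
})

test_that("carving is a rigid partition of the assembly", {
  toy <- generate_toy_complex(toy_complex_config(seed = 51,
    ligands = list(A_DP = "small_bridge")))
  f <- tempfile(fileext = ".pdb")
  write_toy_pdb(toy, f)
  atoms <- parse_structure(f)
  spec <- toy$spec
  one <- carve_assembly(atoms, spec, "A_DP")
  expect_equal(nsphere(one), nsphere(toy$sets$A_DP))
  ## pair equals the concatenation of its separately carved parts, bitwise
  pair <- carve_assembly(atoms, spec, c("A_DP", "B_DP"))
  parts <- combine_spheres(carve_assembly(atoms, spec, "A_DP"),
                           carve_assembly(atoms, spec, "B_DP"))
  expect_identical(pair$centers, parts$centers)
  ## subcomplex 1 is the union of its three member subunits
  sc1 <- carve_assembly(atoms, spec, subcomplex_roles(1))
  expect_equal(nsphere(sc1),
               sum(vapply(subcomplex_roles(1),
                          function(r) nsphere(toy$sets[[r]]), 0L)))
  expect_error(carve_assembly(atoms, spec, character()), "empty selection")
  expect_error(carve_assembly(atoms, spec, "DF"), "absent from the assembly")
})

test_that("the assembly spec validates roles and accepts F1 naming", {
  expect_error(assembly_spec(c(A = "A_DP", B = "A_TP")), "three distinct A")
  expect_error(assembly_spec(c(A = "A_DP", B = "A_TP", C = "A_E",
                               D = "B_DP", E = "B_TP", F = "B_E",
                               G = "DF", H = "DF")), "at most one")
  f1 <- assembly_spec(c(A = "beta_DP", B = "beta_TP", C = "beta_E",
                        D = "alpha_DP", E = "alpha_TP", F = "alpha_E",
                        G = "gamma"), motor_family = "F1")
  expect_identical(unname(f1$role_map[c("A", "D", "G")]),
                   c("A_DP", "B_DP", "DF"))
  expect_error(assembly_spec(c(A = "A_DP", B = "A_TP", C = "A_E",
                               D = "B_DP", E = "B_TP", F = "B_E"),
                             site_ligands = list(DF = "ATP")),
               "existing role")
})

test_that("AMP-PNP to ATP substitution re-types only the bridging nitrogen", {
  lig <- data.frame(chain_id = "I", residue_name = c("ANP", "ANP", "MG"),
                    residue_number = c(1, 1, 2), insertion_code = "",
                    atom_name = c("PG", "N3B", "MG"),
                    element = c("P", "N", "MG"),
                    x = c(0, 1, 5), y = 0, z = 0, alt_loc = "",
                    occupancy = 1, stringsAsFactors = FALSE)
  out <- substitute_amppnp_with_atp(lig)
  expect_equal(nrow(out), 3L)
  expect_identical(out$atom_name[2], "O3B")
  expect_identical(out$element[2], "O")
  expect_identical(out$residue_name[1:2], c("ATP", "ATP"))
  ## Mg untouched, coordinates untouched
  expect_identical(out$element[3], "MG")
  expect_identical(out[, c("x", "y", "z")], lig[, c("x", "y", "z")])
  ## refuse a second substitution
  expect_error(substitute_amppnp_with_atp(out), "not AMP-PNP")
})

test_that("overlap relaxation removes overlaps within the step cap", {
  ## two spheres overlapping by 0.05
  ss <- sphere_set(rbind(c(0, 0, 0), c(1.95, 0, 0)), c(1, 1), "ov")
  rel <- relax_overlaps(ss, max_step = 0.5, tol = 0.01)
  d <- sqrt(sum((rel$centers[1, ] - rel$centers[2, ])^2))
  expect_gt(d, 2 - 0.01)
  ## overlap-free input comes back bit-identical
  free <- sphere_set(rbind(c(0, 0, 0), c(5, 0, 0)), c(1, 1), "free")
  expect_identical(relax_overlaps(free), free)
  ## jittered cluster: converged, displacements capped
  ss2 <- random_cluster(10, seed = 52, sd = 1.6, rlo = 0.9, rhi = 1.1)
  rel2 <- relax_overlaps(ss2, max_step = 1.0, tol = 0.05)
  dm <- as.matrix(dist(rel2$centers))
  ov <- outer(rel2$radii, rel2$radii, "+") - dm
  diag(ov) <- 0
  expect_lt(max(ov), 0.05)
  disp <- sqrt(rowSums((rel2$centers - ss2$centers)^2))
  expect_lte(max(disp), 1.0 + 1e-9)
})
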