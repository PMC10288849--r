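#' Configuration of a synthetic ring assembly
#'
#' Toy complexes emulate the statistical structure the packing analysis
#' assumes, at a scale where the exact geometry backend applies: six
#' sphere-cluster subunits alternating A-like and B-like roles on a ring,
#' per-subunit packing tightness (tighter cluster = smaller union volume =
#' smaller |S1|, the closed-vs-open distinction), an optional asymmetric
#' central-shaft cluster whose protruding lobe approaches one subunit, and
#' optional bridge clusters standing in for nucleotides at A-B
#' interfaces.  Everything is deterministic given the seed.
#'
#' Clusters are jittered cubic lattices rather than random gas, so
#' tightness maps smoothly onto union volume.  The tightness-to-spacing
#' map is confined to the regime where the excluded-volume union stays
#' solidly connected: once clusters loosen toward fragmentation, the
#' topology term of the morphometric form breaks the packing-entropy
#' correspondence, so that regime is deliberately out of range.
#'
#' @param spheres_per_subunit spheres per A-type cluster (B-type clusters
#'   carry 80 percent of that); default 30.
#' @param sphere_radius sphere radius in Angstrom (default 1.7, a carbon
#'   van der Waals radius, so emitted pseudo-atoms can be carbons).
#' @param tightness named 6-vector in (0, 1] for roles A_DP, A_TP, A_E,
#'   B_DP, B_TP, B_E; 1 is maximally compact.
#' @param ring_radius ring radius in Angstrom (default 12).
#' @param shaft logical: include the central-shaft cluster.
#' @param shaft_orientation azimuthal rotation of the shaft lobe in
#'   degrees away from its favored subunit (default 0 = facing it).
#' @param shaft_bias named vector of radial offsets (Angstrom) pulling
#'   subunits toward the axis; default pulls B_E inward by 2.5, making
#'   B_E-DF the favored shaft interface.
#' @param ligands named list/vector: A-site role -> "none",
#'   "small_bridge" or "large_bridge".
#' @param bridge_spheres sphere counts c(small = , large = ).
#' @param seed integer seed.
#' @return A `toy_complex_config`.
#' @export
toy_complex_config <- function(spheres_per_subunit = 30L, sphere_radius = 1.7,
                               tightness = c(A_DP = 0.9, A_TP = 0.95,
                                             A_E = 0.45, B_DP = 0.75,
                                             B_TP = 0.8, B_E = 0.6),
                               ring_radius = 12, shaft = FALSE,
                               shaft_orientation = 0,
                               shaft_bias = c(B_E = 2.5),
                               ligands = list(), bridge_spheres = c(small = 5L,
                                                                    large = 12L),
                               seed = 1L) {
  roles <- c("A_DP", "A_TP", "A_E", "B_DP", "B_TP", "B_E")
  if (is.null(names(tightness))) names(tightness) <- roles
  stopifnot(setequal(names(tightness), roles),
            all(tightness > 0), all(tightness <= 1),
            spheres_per_subunit >= 4L, sphere_radius > 0, ring_radius > 0)
  ligands <- as.list(ligands)
  if (length(ligands)) {
    stopifnot(all(names(ligands) %in% c("A_DP", "A_TP", "A_E")))
    stopifnot(all(unlist(ligands) %in% c("none", "small_bridge",
                                         "large_bridge")))
    ligands <- ligands[unlist(ligands) != "none"]
  }
  structure(list(spheres_per_subunit = as.integer(spheres_per_subunit),
                 sphere_radius = sphere_radius,
                 tightness = tightness[roles], ring_radius = ring_radius,
                 shaft = isTRUE(shaft), shaft_orientation = shaft_orientation,
                 shaft_bias = shaft_bias, ligands = ligands,
                 bridge_spheres = bridge_spheres, seed = as.integer(seed)),
            class = "toy_complex_config")
}

## ring azimuth of each role, degrees (alternating A/B, consistent with
## the positional subcomplex triples)
.ring_azimuth <- c(A_E = 0, B_E = 60, A_DP = 120, B_DP = 180, A_TP = 240,
                   B_TP = 300)

## jittered-lattice cluster of n spheres around the origin; spacing shrinks
## with tightness
.toy_cluster <- function(n, radius, tightness, jitter_sd) {
  spacing <- 2 * radius * (1.02 + 0.25 * (1 - tightness))
  m <- ceiling(n^(1 / 3)) + 2L
  g <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m), z = seq_len(m)))
  g <- sweep(g, 2L, colMeans(g)) * spacing
  ord <- order(rowSums(g^2))
  pts <- g[ord[seq_len(n)], , drop = FALSE]
  pts + matrix(stats::rnorm(n * 3L, sd = jitter_sd * spacing), ncol = 3L)
}

#' Generate a synthetic ring assembly
#'
#' Expands a [toy_complex_config] into per-role [sphere_set]s plus a
#' matching [assembly_spec], fully deterministic given the seed.  Higher
#' tightness gives a more compact cluster, hence smaller |S1| through the
#' entropy stack; bridge ligands sit between their A subunit and the
#' adjacent B subunit (A_DP pairs with B_DP, A_TP with B_TP, A_E with
#' B_E); the shaft lobe points at the subunit named in `shaft_bias`,
#' rotated by `shaft_orientation`.
#'
#' @param config a [toy_complex_config].
#' @return List with `sets` (named [sphere_set]s: six roles, optional
#'   `DF`, optional `<role>.ligand`), `spec` (an [assembly_spec]),
#'   `config`.
#' @export
generate_toy_complex <- function(config) {
  stopifnot(inherits(config, "toy_complex_config"))
  with_seed(config$seed, {
    r <- config$sphere_radius
    nA <- config$spheres_per_subunit
    nB <- max(4L, as.integer(round(0.8 * nA)))
    sets <- list()
    centers <- list()
    for (role in names(.ring_azimuth)) {
      n <- if (startsWith(role, "A")) nA else nB
      cl <- .toy_cluster(n, r, config$tightness[role], jitter_sd = 0.05)
      bias <- if (role %in% names(config$shaft_bias))
        config$shaft_bias[[role]] else 0
      az <- .ring_azimuth[[role]] * pi / 180
      ctr <- (config$ring_radius - bias) * c(cos(az), sin(az), 0)
      centers[[role]] <- ctr
      sets[[role]] <- sphere_set(sweep(cl, 2L, ctr, "+"), r, label = role)
    }
    ## sanity: clusters must not be forced to coincide
    cc <- do.call(rbind, centers)
    dmin <- min(stats::dist(cc))
    if (dmin < 2 * r)
      stop("geometrically impossible configuration: subunit centers coincide")
    ## bridge ligands at the A-B interface the site's nucleotide occupies
    partner <- c(A_DP = "B_DP", A_TP = "B_TP", A_E = "B_E")
    for (site in names(config$ligands)) {
      nb <- config$bridge_spheres[[sub("_bridge", "", config$ligands[[site]])]]
      mid <- (centers[[site]] + centers[[partner[[site]]]]) / 2
      mid <- mid * 0.96  # nudge toward the axis, clear of both clusters
      cl <- .toy_cluster(nb, r, 1, jitter_sd = 0.04)
      sets[[paste0(site, ".ligand")]] <-
        sphere_set(sweep(cl, 2L, mid, "+"), r,
                   label = paste0(site, ".ligand"))
    }
    ## central shaft: a vertical two-column core plus a lobe pointing at
    ## the favored subunit
    if (config$shaft) {
      nS <- max(8L, as.integer(round(1.1 * nA)))
      core <- .toy_cluster(nS, r, 0.95, jitter_sd = 0.04)
      core <- core %*% diag(c(0.45, 0.45, 1.6))  # elongate along z
      nL <- max(4L, as.integer(round(0.5 * nA)))
      lobe <- .toy_cluster(nL, r, 0.95, jitter_sd = 0.04)
      target <- names(config$shaft_bias)[1L]
      az <- (.ring_azimuth[[target]] + config$shaft_orientation) * pi / 180
      lobe_ctr <- (config$ring_radius / 2.6) * c(cos(az), sin(az), 0)
      shaft <- rbind(core, sweep(lobe, 2L, lobe_ctr, "+"))
      sets[["DF"]] <- sphere_set(shaft, r, label = "DF")
    }
    role_map <- stats::setNames(names(.ring_azimuth),
                                c("A", "B", "C", "D", "E", "F"))
    ligand_map <- NULL
    site_ligands <- list()
    if (length(config$ligands)) {
      lchains <- c(A_DP = "I", A_TP = "J", A_E = "K")
      ligand_map <- stats::setNames(names(config$ligands),
                                    lchains[names(config$ligands)])
      site_ligands <- stats::setNames(
        lapply(names(config$ligands), function(s) list(type = "ATP")),
        names(config$ligands))
    }
    if (config$shaft) role_map <- c(role_map, G = "DF")
    spec <- assembly_spec(role_map, site_ligands = site_ligands,
                          ligand_map = ligand_map)
    list(sets = sets, spec = spec, config = config)
  })
}

#' Write a toy assembly as a PDB file
#'
#' Emits the synthetic assembly through the same public file interface
#' real structures use: pseudo-carbon atoms (residue TOY, ligand residue
#' ATP), one chain per subunit matching the generated [assembly_spec].
#'
#' @param toy result of [generate_toy_complex()].
#' @param path output PDB path.
#' @return Invisibly, the chain -> role maps used (`role_map`,
#'   `ligand_map`).
#' @export
write_toy_pdb <- function(toy, path) {
  spec <- toy$spec
  chain_of <- c(stats::setNames(names(spec$role_map), spec$role_map),
                if (!is.null(spec$ligand_map))
                  stats::setNames(names(spec$ligand_map),
                                  paste0(spec$ligand_map, ".ligand")))
  xyz <- NULL; chains <- character(); res <- character()
  for (nm in names(toy$sets)) {
    ctr <- toy$sets[[nm]]$centers
    xyz <- rbind(xyz, ctr)
    chains <- c(chains, rep(chain_of[[nm]], nrow(ctr)))
    res <- c(res, rep(if (grepl("\\.ligand$", nm)) "ATP" else "TOY",
                      nrow(ctr)))
  }
  n <- nrow(xyz)
  pdb <- bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = rep("ATOM", n),
    resno = seq_len(n),
    resid = res,
    chain = chains,
    elety = rep("C1", n),
    eleno = seq_len(n),
    o = rep(1, n), b = rep(0, n),
    elesy = rep("C", n))
  invisible(list(role_map = spec$role_map, ligand_map = spec$ligand_map))
}

#' Analytic geometry fixtures
#'
#' Small sphere configurations with closed-form morphometric measures,
#' used to pin the exact backend to independent arithmetic: single
#' spheres, a disjoint pair, the unit-sphere overlapping pair (lens), and
#' a collinear triple with pairwise-only overlaps (inclusion-exclusion of
#' lens closed forms).
#'
#' @return List of fixtures, each with `name`, `spheres` (a
#'   [sphere_set]), `measures` (named V, A, C, X).
#' @export
analytic_fixtures <- function() {
  lens_closed <- function(r1, r2, d) {
    costh1 <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
    costh2 <- (d^2 + r2^2 - r1^2) / (2 * d * r2)
    gam <- acos((r1^2 + r2^2 - d^2) / (2 * r1 * r2))
    rc <- r1 * sqrt(1 - costh1^2)
    capA1 <- 2 * pi * r1^2 * (1 - costh1)
    capA2 <- 2 * pi * r2^2 * (1 - costh2)
    c(V = lens_volume(r1, r2, d), A = capA1 + capA2,
      C = capA1 / r1 + capA2 / r2 + pi * rc * gam, X = 4 * pi)
  }
  pair_union <- function(r1, r2, d) {
    s <- sphere_measures(r1) + sphere_measures(r2)
    s - lens_closed(r1, r2, d)
  }
  f <- list()
  for (R in c(1, 1.7, 2.8))
    f[[sprintf("sphere_%.1f", R)]] <- list(
      name = sprintf("sphere_%.1f", R),
      spheres = sphere_set(matrix(0, 1L, 3L), R, sprintf("sphere_%.1f", R)),
      measures = sphere_measures(R))
  f$pair_disjoint <- list(
    name = "pair_disjoint",
    spheres = sphere_set(rbind(c(0, 0, 0), c(10, 0, 0)), c(2.8, 2.8),
                         "pair_disjoint"),
    measures = 2 * sphere_measures(2.8))
  f$pair_lens_r1_d1 <- list(
    name = "pair_lens_r1_d1",
    spheres = sphere_set(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 1),
                         "pair_lens_r1_d1"),
    measures = pair_union(1, 1, 1))
  trip <- sphere_set(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)), rep(1, 3L),
                     "triple_collinear")
  f$triple_collinear <- list(
    name = "triple_collinear",
    spheres = trip,
    measures = 3 * sphere_measures(1) - 2 * lens_closed(1, 1, 1.5))
  f
}
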