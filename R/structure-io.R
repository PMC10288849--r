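#' Parse an atomic structure file
#'
#' Reads a PDB or mmCIF file (format chosen by extension, overridable) into
#' a plain data frame of atom records.  Alternate locations are collapsed
#' to the highest-occupancy conformer (ties broken alphabetically by
#' alt-loc id) and waters are excluded by default — crystallographic waters
#' are part of the solvent the hydration-entropy model represents, not of
#' the solute.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif` file.
#' @param format "auto", "pdb" or "cif".
#' @param keep_waters keep HOH/WAT/DOD residues (default FALSE).
#' @return A data frame of atom records with columns `chain_id`,
#'   `residue_name`, `residue_number`, `insertion_code`, `atom_name`,
#'   `element`, `x`, `y`, `z`, `alt_loc`, `occupancy`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "cif"),
                            keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("structure file '%s' not found", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE),
    error = function(e) stop(sprintf("failed to parse '%s' as %s: %s",
                                     path, format, conditionMessage(e))))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop(sprintf("'%s' contains no atoms", path))
  ele <- at$elesy
  if (is.null(ele) || all(is.na(ele)) || all(!nzchar(trimws(ele))))
    ele <- suppressWarnings(bio3d::atom2ele(pdb))
  rec <- data.frame(
    chain_id = as.character(at$chain),
    residue_name = trimws(as.character(at$resid)),
    residue_number = as.integer(at$resno),
    insertion_code = ifelse(is.na(at$insert) | !nzchar(trimws(at$insert)),
                            "", trimws(at$insert)),
    atom_name = trimws(as.character(at$elety)),
    element = toupper(trimws(as.character(ele))),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    alt_loc = ifelse(is.na(at$alt) | !nzchar(trimws(at$alt)), "",
                     trimws(at$alt)),
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    stringsAsFactors = FALSE)
  if (!all(is.finite(rec$x) & is.finite(rec$y) & is.finite(rec$z)))
    stop(sprintf("non-finite coordinates in '%s'", path))
  if (!keep_waters)
    rec <- rec[!rec$residue_name %in% c("HOH", "WAT", "DOD", "H2O"), ,
               drop = FALSE]
  if (nrow(rec) == 0L) stop(sprintf("'%s' holds no non-water atoms", path))
  collapse_altlocs(rec)
}

## keep, per atom site, the conformer with highest occupancy (alphabetical
## alt-loc id on ties)
collapse_altlocs <- function(rec) {
  has_alt <- nzchar(rec$alt_loc)
  if (!any(has_alt)) return(rec)
  key <- paste(rec$chain_id, rec$residue_number, rec$insertion_code,
               rec$residue_name, rec$atom_name, sep = "\r")
  ord <- order(key, -rec$occupancy, rec$alt_loc)
  rec <- rec[ord, , drop = FALSE]
  rec <- rec[!duplicated(key[ord]), , drop = FALSE]
  rec[order(as.integer(rownames(rec))), , drop = FALSE]
}

#' Load the package's van der Waals radius table
#'
#' A versioned heavy-atom radius set shipped with the package
#' (`inst/extdata/vdw_radii.tsv`); edit a copy and pass its path to use a
#' different set.
#'
#' @param path optional path to a custom two-column (element, radius) TSV.
#' @return Named numeric vector, Angstrom per element symbol.
#' @export
default_radius_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "vdw_radii.tsv", package = "hydromorph",
                        mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$radius), toupper(tab$element))
}

#' Assign van der Waals radii to atom records
#'
#' One sphere per atom, radius looked up by element symbol.  Unknown
#' elements are a hard error naming the offending atoms: a silent default
#' radius would corrupt every downstream entropy silently.
#'
#' @param atoms atom-record data frame from [parse_structure()] or
#'   [carve_assembly()].
#' @param radius_table named numeric vector, element -> radius (Angstrom).
#' @param label label for the resulting set.
#' @return A [sphere_set] carrying the atom records as provenance.
#' @export
assign_radii <- function(atoms, radius_table = default_radius_table(),
                         label = "structure") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  ele <- toupper(atoms$element)
  miss <- !(ele %in% names(radius_table))
  if (any(miss)) {
    bad <- unique(paste0(atoms$atom_name[miss], " (", ele[miss], ")"))
    stop(sprintf("no radius for %d atom(s): %s", sum(miss),
                 paste(utils::head(bad, 8L), collapse = ", ")))
  }
  sphere_set(cbind(atoms$x, atoms$y, atoms$z), radius_table[ele],
             label = label, atoms = atoms)
}

ROLE_SET <- c("A_DP", "A_TP", "A_E", "B_DP", "B_TP", "B_E", "DF")

## F1 naming -> internal V1-style roles (catalytic beta ~ A, alpha ~ B,
## gamma ~ central shaft)
.normalize_role <- function(role) {
  r <- gsub("^beta_", "A_", role)
  r <- gsub("^alpha_", "B_", r)
  r[r == "gamma"] <- "DF"
  r
}

#' Define the role architecture of a ring assembly
#'
#' Maps chains to positional subunit roles (three catalytic A-type, three
#' non-catalytic B-type, optionally one central shaft), records which site
#' holds which ligand, and fixes the motor family naming (V1: A/B/DF; F1:
#' beta/alpha/gamma, normalized internally to the V1 names).
#'
#' The chain-to-role correspondence is deliberately user-supplied
#' configuration, not hard-coded: deposition chain naming varies between
#' structures and between naming conventions of different groups.
#'
#' @param role_map named character vector: chain id -> role in
#'   `A_DP, A_TP, A_E, B_DP, B_TP, B_E, DF` (or `beta_DP, ..., alpha_DP,
#'   ..., gamma`).
#' @param site_ligands named list: A-site role -> list(type = "ATP"/"ADP"/
#'   "Pi"/"none", mg = TRUE/FALSE).
#' @param ligand_map optional named character vector: chain id -> site role
#'   for ligands deposited as separate chains.
#' @param motor_family "V1" or "F1".
#' @return An `assembly_spec` object.
#' @export
assembly_spec <- function(role_map, site_ligands = list(), ligand_map = NULL,
                          motor_family = c("V1", "F1")) {
  motor_family <- match.arg(motor_family)
  stopifnot(is.character(role_map), !is.null(names(role_map)))
  roles <- .normalize_role(unname(role_map))
  bad <- setdiff(roles, ROLE_SET)
  if (length(bad))
    stop(sprintf("unknown role(s): %s", paste(unique(bad), collapse = ", ")))
  a_roles <- intersect(roles, c("A_DP", "A_TP", "A_E"))
  b_roles <- intersect(roles, c("B_DP", "B_TP", "B_E"))
  if (length(a_roles) != 3L || anyDuplicated(roles[roles != "DF"]))
    stop("role map must name exactly three distinct A-type roles")
  if (length(b_roles) != 3L)
    stop("role map must name exactly three distinct B-type roles")
  if (sum(roles == "DF") > 1L)
    stop("at most one central-shaft (DF) role is allowed")
  norm_map <- stats::setNames(roles, names(role_map))
  if (length(site_ligands)) {
    if (is.null(names(site_ligands)) ||
        !all(.normalize_role(names(site_ligands)) %in% roles))
      stop("every ligand site must reference an existing role")
    names(site_ligands) <- .normalize_role(names(site_ligands))
    site_ligands <- lapply(site_ligands, function(l) {
      if (is.character(l)) l <- list(type = l)
      l$type <- match.arg(l$type, c("ATP", "ADP", "Pi", "none"))
      l$mg <- isTRUE(l$mg)
      l
    })
    site_ligands <- site_ligands[
      vapply(site_ligands, function(l) l$type != "none", TRUE)]
  }
  if (!is.null(ligand_map)) {
    stopifnot(is.character(ligand_map), !is.null(names(ligand_map)))
    ligand_map <- stats::setNames(.normalize_role(unname(ligand_map)),
                                  names(ligand_map))
    if (!all(ligand_map %in% roles))
      stop("ligand_map references roles absent from the role map")
  }
  structure(list(role_map = norm_map, site_ligands = site_ligands,
                 ligand_map = ligand_map, motor_family = motor_family),
            class = "assembly_spec")
}

#' @export
print.assembly_spec <- function(x, ...) {
  cat(sprintf("<assembly_spec> %s: %s\n", x$motor_family,
              paste(sprintf("%s=%s", names(x$role_map), x$role_map),
                    collapse = " ")))
  if (length(x$site_ligands))
    cat("  ligands:", paste(sprintf("%s:%s%s", names(x$site_ligands),
                                    vapply(x$site_ligands, `[[`, "", "type"),
                                    ifelse(vapply(x$site_ligands, `[[`, TRUE,
                                                  "mg"), "+Mg", "")),
                            collapse = " "), "\n")
  invisible(x)
}

#' Positional subcomplex definitions
#'
#' The three subcomplexes are named by position in the ring, not by
#' occupancy: 1 = (A_E, B_E, B_TP), 2 = (A_TP, B_TP, B_DP),
#' 3 = (A_DP, B_DP, B_E).  The F1 naming maps onto the same triples with
#' beta -> A and alpha -> B.
#'
#' @param index subcomplex index 1, 2 or 3.
#' @return Character vector of the three member roles.
#' @export
subcomplex_roles <- function(index) {
  defs <- list(`1` = c("A_E", "B_E", "B_TP"),
               `2` = c("A_TP", "B_TP", "B_DP"),
               `3` = c("A_DP", "B_DP", "B_E"))
  stopifnot(index %in% 1:3)
  defs[[as.character(index)]]
}

#' The six A-B ring interfaces
#'
#' @return Two-column matrix of adjacent (A-role, B-role) pairs around the
#'   ring.
#' @export
ab_interfaces <- function() {
  cbind(A = c("A_E", "A_E", "A_TP", "A_TP", "A_DP", "A_DP"),
        B = c("B_E", "B_TP", "B_TP", "B_DP", "B_DP", "B_E"))
}

LIGAND_RESNAMES <- c("ATP", "ADP", "ANP", "AMP", "PI", "PO4", "MG")

## atoms of a role's protein chains (ligand residues excluded)
.role_atoms <- function(atoms, spec, role) {
  chains <- names(spec$role_map)[spec$role_map == role]
  sub <- atoms[atoms$chain_id %in% chains &
               !(toupper(atoms$residue_name) %in% LIGAND_RESNAMES), ,
               drop = FALSE]
  sub
}

## ligand atoms assigned to a site role: ligand residues inside the role's
## chains plus any chains mapped to the site via ligand_map
.site_ligand_atoms <- function(atoms, spec, role) {
  chains <- names(spec$role_map)[spec$role_map == role]
  keep <- atoms$chain_id %in% chains &
    toupper(atoms$residue_name) %in% LIGAND_RESNAMES
  if (!is.null(spec$ligand_map)) {
    lchains <- names(spec$ligand_map)[spec$ligand_map == role]
    keep <- keep | atoms$chain_id %in% lchains
  }
  atoms[keep, , drop = FALSE]
}

#' Carve an assembly into subunits, ligands, pairs, or subcomplexes
#'
#' Rigid selection: the returned spheres are exactly the atoms of the
#' selected roles and ligand sites with coordinates unchanged, so any
#' disjoint selection partitions the assembly bit-identically.
#'
#' @param atoms atom-record data frame of the whole assembly.
#' @param spec an [assembly_spec].
#' @param roles character vector of subunit roles to include (may be
#'   empty if `ligand_sites` is not).
#' @param ligand_sites character vector of site roles whose ligands to
#'   include.
#' @param radius_table element radii for the resulting [sphere_set].
#' @param label label; defaults to the selection.
#' @return A [sphere_set] with atom provenance.
#' @export
carve_assembly <- function(atoms, spec, roles = character(),
                           ligand_sites = character(),
                           radius_table = default_radius_table(),
                           label = NULL) {
  stopifnot(is.data.frame(atoms), inherits(spec, "assembly_spec"))
  roles <- .normalize_role(roles)
  ligand_sites <- .normalize_role(ligand_sites)
  if (length(roles) == 0L && length(ligand_sites) == 0L)
    stop("empty selection")
  bad <- setdiff(c(roles, ligand_sites), spec$role_map)
  if (length(bad))
    stop(sprintf("selection names role(s) absent from the assembly: %s",
                 paste(bad, collapse = ", ")))
  parts <- list()
  for (r in roles) {
    sub <- .role_atoms(atoms, spec, r)
    if (nrow(sub) == 0L)
      stop(sprintf("role %s selects zero atoms", r))
    parts[[length(parts) + 1L]] <- sub
  }
  for (r in ligand_sites) {
    sub <- .site_ligand_atoms(atoms, spec, r)
    if (nrow(sub) == 0L)
      stop(sprintf("ligand site %s selects zero atoms", r))
    parts[[length(parts) + 1L]] <- sub
  }
  sel <- do.call(rbind, parts)
  if (is.null(label))
    label <- paste(c(roles, if (length(ligand_sites))
      paste0(ligand_sites, ".ligand")), collapse = "+")
  assign_radii(sel, radius_table, label = label)
}

#' Replace AMP-PNP by ATP
#'
#' Crystal structures use the non-hydrolyzable analogue AMP-PNP; for the
#' entropy analysis it is treated as ATP by re-typing the bridging
#' nitrogen between the beta- and gamma-phosphates (N3B) as the bridging
#' oxygen (O3B).  Coordinates and atom count are untouched; any bound Mg
#' is untouched.  Refuses input that already lacks the bridging nitrogen.
#'
#' @param atoms ligand atom records (AMP-PNP residue `ANP`, optionally
#'   with Mg).
#' @param bridging_atom atom name of the bridging nitrogen (default
#'   "N3B").
#' @return Atom records with the bridging atom re-typed and the residue
#'   renamed ATP.
#' @export
substitute_amppnp_with_atp <- function(atoms, bridging_atom = "N3B") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  hit <- which(atoms$atom_name == bridging_atom &
               toupper(atoms$element) == "N")
  if (length(hit) == 0L)
    stop(sprintf(paste0("no bridging nitrogen '%s' found: input is not ",
                        "AMP-PNP (already ATP?)"), bridging_atom))
  atoms$atom_name[hit] <- sub("^N", "O", bridging_atom)
  atoms$element[hit] <- "O"
  atoms$residue_name[atoms$residue_name == "ANP"] <- "ATP"
  atoms
}

#' Remove slight hard-sphere overlaps by steepest descent
#'
#' Optional preprocessing mirroring the energy-minimization step used on
#' crystal structures before packing analysis: small steepest-descent
#' displacements on a soft quadratic overlap penalty until every pairwise
#' overlap beyond `tol` is gone.  Off by default in the pipeline — the
#' union-of-balls geometry is well defined for overlapping spheres, so
#' this is cosmetic preprocessing, not a requirement.
#'
#' @param spheres a [sphere_set].
#' @param max_step maximum total displacement per sphere in Angstrom.
#' @param tol residual overlap tolerance in Angstrom.
#' @param max_iter iteration cap.
#' @param step_size descent step in Angstrom per unit overlap.
#' @return A [sphere_set] with overlaps reduced below `tol`; input
#'   returned bit-identical if it was already overlap-free.
#' @export
relax_overlaps <- function(spheres, max_step = 0.5, tol = 0.01,
                           max_iter = 2000L, step_size = 0.2) {
  stopifnot(inherits(spheres, "sphere_set"))
  ctr0 <- spheres$centers
  rad <- spheres$radii
  n <- nrow(ctr0)
  ctr <- ctr0
  worst <- 0
  for (it in seq_len(max_iter)) {
    dm <- as.matrix(stats::dist(ctr))
    ov <- outer(rad, rad, "+") - dm
    diag(ov) <- 0
    worst <- max(ov)
    if (worst < tol) {
      if (it == 1L) return(spheres)  # untouched input
      out <- sphere_set(ctr, rad, label = spheres$label,
                        atoms = spheres$atoms)
      return(out)
    }
    grad <- matrix(0, n, 3L)
    idx <- which(ov > tol & upper.tri(ov), arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1L]; j <- idx[k, 2L]
      dir <- ctr[i, ] - ctr[j, ]
      dd <- sqrt(sum(dir^2))
      dir <- if (dd > 1e-12) dir / dd else c(1, 0, 0)
      push <- ov[i, j] * step_size
      grad[i, ] <- grad[i, ] + dir * push
      grad[j, ] <- grad[j, ] - dir * push
    }
    cand <- ctr + grad
    ## cap each sphere's cumulative displacement from its original site
    disp <- cand - ctr0
    dnorm <- sqrt(rowSums(disp^2))
    over <- dnorm > max_step
    if (any(over))
      disp[over, ] <- disp[over, ] * (max_step / dnorm[over])
    ctr <- ctr0 + disp
  }
  stop(sprintf("overlap relaxation did not converge; worst residual overlap %.4f A",
               worst))
}
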