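#' Packing efficiency of a subunit or subcomplex
#'
#' The measure of packing efficiency (PE) is the hydration entropy of the
#' structure; smaller |eta| means closer atomic packing.  Four variants
#' cover the bare and ligand-bound comparisons:
#' \describe{
#'   \item{eq1a}{eta = S1(subunit), nothing bound.}
#'   \item{eq1b}{eta_Y = S1(subunit with Y bound) - S1(Y).}
#'   \item{eq2a}{eta' = S1(subunit) + S1(Y): the ligand-compensated bare
#'     form used when comparing empty against occupied sites.}
#'   \item{eq2b}{eta'_Y = S1(subunit with Y bound).}
#' }
#' The identity eta - eta_Y = eta' - eta'_Y holds exactly, so either
#' route gives the same differences; both are kept because each matches a
#' different tabulation.
#'
#' @param subunit bare subunit [sphere_set].
#' @param ligand ligand [sphere_set] (rigidly carved), or NULL for eq1a.
#' @param variant one of "eq1a", "eq1b", "eq2a", "eq2b".
#' @param coefficients an `ma_coefficients` object.
#' @param probe probe radius; defaults to the calibration's d/2.
#' @param ... passed to [s1_structure()].
#' @return A `packing_efficiency`: list with `subject_label`,
#'   `bound_compound`, `eta`, `variant`, `coefficients_id`.
#' @export
packing_efficiency <- function(subunit, ligand = NULL,
                               variant = c("eq1a", "eq1b", "eq2a", "eq2b"),
                               coefficients, probe = NULL, ...) {
  variant <- match.arg(variant)
  stopifnot(inherits(subunit, "sphere_set"))
  if (variant != "eq1a" && is.null(ligand))
    stop(sprintf("variant %s requires a ligand", variant))
  if (!is.null(ligand)) stopifnot(inherits(ligand, "sphere_set"))
  s1 <- function(ss) s1_structure(ss, coefficients, probe = probe, ...)$s1
  eta <- switch(variant,
    eq1a = s1(subunit),
    eq1b = s1(combine_spheres(subunit, ligand)) - s1(ligand),
    eq2a = s1(subunit) + s1(ligand),
    eq2b = s1(combine_spheres(subunit, ligand)))
  structure(list(subject_label = subunit$label,
                 bound_compound = if (is.null(ligand)) "none" else ligand$label,
                 eta = eta, variant = variant,
                 coefficients_id = coefficients$id),
            class = "packing_efficiency")
}

#' @export
print.packing_efficiency <- function(x, ...) {
  cat(sprintf("<packing_efficiency> %s (%s, Y=%s): eta = %.2f k_B\n",
              x$subject_label, x$variant, x$bound_compound, x$eta))
  invisible(x)
}

## rigid-split verification: parts must reproduce the whole sphere multiset
.check_partition <- function(whole, parts) {
  key <- function(ss) sort(paste(signif(ss$centers[, 1L], 10),
                                 signif(ss$centers[, 2L], 10),
                                 signif(ss$centers[, 3L], 10),
                                 signif(ss$radii, 10)))
  if (!identical(key(whole), key(do.call(combine_spheres, parts))))
    stop("parts are not a rigid split of the whole (sphere multisets differ)")
}

#' Water-entropy gain upon contact of two subunits
#'
#' Delta S_IJ = S1(pair) - [S1(I) + S1(J)], where the pair is taken from
#' the complex and the parts are obtained by simply separating it (the
#' split is verified).  A larger gain means the interface is more closely
#' packed; parts beyond interaction range give exactly zero.
#'
#' @param pair the subunit pair as one [sphere_set].
#' @param part_i,part_j the two rigid parts.
#' @param coefficients an `ma_coefficients` object.
#' @param probe probe radius; defaults to the calibration's d/2.
#' @param ... passed to [s1_structure()].
#' @return An `interface_gain`: list with `pair_label`, `delta_s`
#'   (k_B), per-part entropies.
#' @export
interface_gain <- function(pair, part_i, part_j, coefficients, probe = NULL,
                           ...) {
  stopifnot(inherits(pair, "sphere_set"), inherits(part_i, "sphere_set"),
            inherits(part_j, "sphere_set"))
  .check_partition(pair, list(part_i, part_j))
  s1 <- function(ss) s1_structure(ss, coefficients, probe = probe, ...)$s1
  sp <- s1(pair); si <- s1(part_i); sj <- s1(part_j)
  structure(list(pair_label = paste0(part_i$label, "-", part_j$label),
                 delta_s = sp - (si + sj),
                 s1_pair = sp, s1_i = si, s1_j = sj,
                 coefficients_id = coefficients$id),
            class = "interface_gain")
}

#' @export
print.interface_gain <- function(x, ...) {
  cat(sprintf("<interface_gain> %s: Delta S_IJ/kB = %.2f\n",
              x$pair_label, x$delta_s))
  invisible(x)
}

#' Water-entropy gain upon association of two subunits and a ligand
#'
#' Delta S1 for A + Y + B -> A.Y-B: S1 of the bound complex minus the sum
#' of S1 of the rigidly separated parts.  With no ligand this reduces
#' exactly to the interface gain of the pair.  A larger gain means higher
#' water-mediated affinity.
#'
#' @param a_subunit,b_subunit the two subunits as [sphere_set]s.
#' @param ligand ligand [sphere_set] or NULL.
#' @param bound_complex the associated complex (must be the exact rigid
#'   union of the parts).
#' @param coefficients an `ma_coefficients` object.
#' @param probe probe radius; defaults to the calibration's d/2.
#' @param ... passed to [s1_structure()].
#' @return An `association_gain`: list with `participants`, `delta_s1`.
#' @export
association_gain <- function(a_subunit, ligand = NULL, b_subunit,
                             bound_complex, coefficients, probe = NULL, ...) {
  stopifnot(inherits(a_subunit, "sphere_set"),
            inherits(b_subunit, "sphere_set"),
            inherits(bound_complex, "sphere_set"))
  parts <- if (is.null(ligand)) list(a_subunit, b_subunit)
           else list(a_subunit, ligand, b_subunit)
  .check_partition(bound_complex, parts)
  s1 <- function(ss) s1_structure(ss, coefficients, probe = probe, ...)$s1
  parts_s1 <- vapply(parts, s1, 0)
  bound_s1 <- s1(bound_complex)
  structure(list(participants = vapply(parts, function(p) p$label, ""),
                 delta_s1 = bound_s1 - sum(parts_s1),
                 s1_bound = bound_s1,
                 s1_parts = parts_s1,
                 coefficients_id = coefficients$id),
            class = "association_gain")
}

#' @export
print.association_gain <- function(x, ...) {
  cat(sprintf("<association_gain> %s: Delta S1/kB = %.2f\n",
              paste(x$participants, collapse = "+"), x$delta_s1))
  invisible(x)
}

#' Named packing-efficiency orderings
#'
#' The checkable PE orderings reported for the five assembly states,
#' encoded as data (label sequences in decreasing PE) so that a failed
#' comparison can report exactly which inequality flipped.  Subcomplex
#' orders use labels `subcomplex_1..3`; subunit orders use role labels.
#'
#' @return Named list of character vectors, each in decreasing PE.
#' @export
named_orders <- function() {
  list(
    ## two ATP + shaft: subcomplex 2 > 3 > 1; A_TP > A_DP > A_E
    order9 = c("subcomplex_2", "subcomplex_3", "subcomplex_1"),
    order10 = c("A_TP", "A_DP", "A_E"),
    ## apo, no shaft: 1 > 2 > 3; A_E > A_TP > A_DP
    order11 = c("subcomplex_1", "subcomplex_2", "subcomplex_3"),
    order12 = c("A_E", "A_TP", "A_DP"),
    ## two ATP, no shaft: 3 > 2 > 1; A_DP > A_TP > A_E
    order13 = c("subcomplex_3", "subcomplex_2", "subcomplex_1"),
    order14 = c("A_DP", "A_TP", "A_E"),
    ## apo + shaft: 2 > 3 > 1; A_TP > A_DP > A_E
    order15 = c("subcomplex_2", "subcomplex_3", "subcomplex_1"),
    order16 = c("A_TP", "A_DP", "A_E"))
}

#' Rank structures by packing efficiency
#'
#' Descending PE = ascending |eta|, with ties inside the tolerance flagged
#' and broken deterministically by label order.  An expected ordering (a
#' label vector or the name of a [named_orders()] entry) is compared
#' strictly only outside the tolerance: a flip within `tol` does not
#' count as a mismatch.
#'
#' @param records list of `packing_efficiency` objects (or a named numeric
#'   vector of eta values).
#' @param expected optional expected ordering: character vector of labels
#'   in decreasing PE, or a [named_orders()] name such as "order9".
#' @param tol tie tolerance in k_B (default 1).
#' @param coefficients_id provenance id when `records` is a bare vector.
#' @return An `ordering_report`: list with `ranking` (labels, decreasing
#'   PE), `eta`, `ties` (logical, tied with the next rank), `expected`,
#'   `matches_expected`, `flipped` (which expected comparison failed).
#' @export
rank_packing <- function(records, expected = NULL, tol = 1,
                         coefficients_id = NULL) {
  if (is.numeric(records)) {
    stopifnot(!is.null(names(records)))
    eta <- records
    ids <- coefficients_id %||% "unspecified"
  } else {
    stopifnot(is.list(records),
              all(vapply(records, inherits, TRUE, "packing_efficiency")))
    eta <- stats::setNames(vapply(records, function(r) r$eta, 0),
                           vapply(records, function(r) r$subject_label, ""))
    ids <- unique(vapply(records, function(r) r$coefficients_id, ""))
    if (length(ids) > 1L)
      stop("records mix different calibration coefficients")
  }
  if (anyDuplicated(names(eta))) stop("duplicate labels in ranking input")
  ord <- order(abs(eta), names(eta))
  ranked <- eta[ord]
  ties <- c(diff(abs(ranked)) <= tol, FALSE)
  flipped <- character()
  matches <- NA
  if (!is.null(expected)) {
    if (length(expected) == 1L && expected %in% names(named_orders()))
      expected <- named_orders()[[expected]]
    if (!all(expected %in% names(eta)))
      stop("expected ordering names labels absent from the records")
    for (i in seq_len(length(expected) - 1L)) {
      a <- expected[i]; b <- expected[i + 1L]
      ## a should have higher PE (smaller |eta|) than b, beyond tolerance
      if (abs(eta[a]) > abs(eta[b]) + tol)
        flipped <- c(flipped, sprintf("%s > %s", a, b))
    }
    matches <- length(flipped) == 0L
  }
  structure(list(ranking = names(ranked), eta = ranked, ties = ties,
                 tolerance = tol, expected = expected,
                 matches_expected = matches, flipped = flipped,
                 coefficients_id = ids),
            class = "ordering_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ordering_report <- function(x, ...) {
  lab <- x$ranking
  lab[x$ties] <- paste0(lab[x$ties], "~")
  cat("<ordering_report> PE:", paste(lab, collapse = " > "), "\n")
  if (!is.na(x$matches_expected)) {
    if (x$matches_expected) cat("  matches expected ordering\n")
    else cat("  flipped:", paste(x$flipped, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Catalytic distance between the gamma-phosphate and the essential
#' glutamate
#'
#' The distance L between the phosphorus of the bound nucleotide's
#' gamma-phosphate and the carboxyl carbon of the catalytic glutamate
#' side chain (CD in standard amino-acid nomenclature).  Shorter L means
#' the site is closer to hydrolysis-ready.  Pure geometry: no entropy
#' coefficients involved.
#'
#' @param a_subunit_atoms atom records of the catalytic subunit.
#' @param ligand_atoms atom records of the bound nucleotide.
#' @param glutamate_number residue number of the catalytic glutamate
#'   (261 in the V-type A subunit).
#' @param p_atom gamma-phosphate phosphorus atom name (default "PG").
#' @param carboxyl_atom glutamate carboxyl carbon atom name (default
#'   "CD").
#' @return A `catalytic_distance`: list with `L` (Angstrom), atom
#'   provenance.
#' @export
catalytic_distance <- function(a_subunit_atoms, ligand_atoms,
                               glutamate_number = 261, p_atom = "PG",
                               carboxyl_atom = "CD") {
  stopifnot(is.data.frame(a_subunit_atoms), is.data.frame(ligand_atoms))
  glu <- a_subunit_atoms[a_subunit_atoms$residue_name == "GLU" &
                         a_subunit_atoms$residue_number == glutamate_number, ,
                         drop = FALSE]
  if (nrow(glu) == 0L)
    stop(sprintf("no GLU residue %d in the subunit", glutamate_number))
  cd <- glu[glu$atom_name == carboxyl_atom, , drop = FALSE]
  if (nrow(cd) == 0L)
    stop(sprintf("GLU %d lacks carboxyl carbon atom '%s'", glutamate_number,
                 carboxyl_atom))
  pg <- ligand_atoms[ligand_atoms$atom_name == p_atom, , drop = FALSE]
  if (nrow(pg) == 0L)
    stop(sprintf("ligand lacks gamma-phosphate phosphorus '%s'", p_atom))
  L <- sqrt((cd$x[1L] - pg$x[1L])^2 + (cd$y[1L] - pg$y[1L])^2 +
            (cd$z[1L] - pg$z[1L])^2)
  structure(list(L = L, glutamate_number = glutamate_number,
                 p_atom = p_atom, carboxyl_atom = carboxyl_atom),
            class = "catalytic_distance")
}

#' @export
print.catalytic_distance <- function(x, ...) {
  cat(sprintf("<catalytic_distance> L = %.2f A (P %s to GLU%d %s)\n",
              x$L, x$p_atom, x$glutamate_number, x$carboxyl_atom))
  invisible(x)
}

#' Full packing-structure report of a ring assembly
#'
#' The integrated analysis of one assembly: per-A-subunit relative
#' hydration entropies (with the ligand compensation applied to empty
#' sites whenever the assembly carries ligands, so subunits with
#' different atom counts compare impartially), the six A-B interface
#' gains, the six shaft interface gains and their sum (when a central
#' shaft is present), the positional-subcomplex relative-entropy table,
#' and PE orderings optionally checked against named expected orders.
#'
#' @param atoms atom records of the whole assembly.
#' @param spec an [assembly_spec].
#' @param coefficients an `ma_coefficients` object.
#' @param probe probe radius; defaults to the calibration's d/2.
#' @param radius_table element radius table.
#' @param expected_subcomplex_order,expected_subunit_order optional
#'   expected orderings for [rank_packing()].
#' @param tie_tol tie tolerance in k_B.
#' @param ... passed to [s1_structure()].
#' @return A `packing_structure_report` with fields `subunit_table`,
#'   `subcomplex_table`, `ab_gains`, `shaft_gains`, `shaft_gain_sum`,
#'   `subunit_ordering`, `subcomplex_ordering`, `has_shaft`,
#'   `compensation`.
#' @export
packing_structure_report <- function(atoms, spec, coefficients, probe = NULL,
                                     radius_table = default_radius_table(),
                                     expected_subcomplex_order = NULL,
                                     expected_subunit_order = NULL,
                                     tie_tol = 1, ...) {
  stopifnot(is.data.frame(atoms), inherits(spec, "assembly_spec"),
            inherits(coefficients, "ma_coefficients"))
  s1 <- function(ss) s1_structure(ss, coefficients, probe = probe, ...)
  carve <- function(roles = character(), lig = character(), label = NULL)
    carve_assembly(atoms, spec, roles, lig, radius_table, label)
  has_shaft <- "DF" %in% spec$role_map
  lig_sites <- names(spec$site_ligands)
  occupied <- function(role) role %in% lig_sites
  ## ligand-alone S1 used to compensate empty-site selections (Mg rides
  ## with the nucleotide)
  s1_lig <- NULL
  if (length(lig_sites)) {
    lig_ref <- carve(lig = lig_sites[1L],
                     label = paste0(lig_sites[1L], ".ligand"))
    s1_lig <- s1(lig_ref)$s1
  }
  ## per-A-subunit comparison (eta'_Y for occupied sites, eta' for empty)
  a_roles <- c("A_DP", "A_TP", "A_E")
  sub_res <- lapply(a_roles, function(r) {
    if (occupied(r)) {
      res <- s1(carve(r, lig = r, label = r))
    } else {
      res <- s1(carve(r, label = r))
      if (!is.null(s1_lig)) res$s1 <- res$s1 + s1_lig
    }
    res
  })
  subunit_table <- relative_table(sub_res, tie_tol = tie_tol)
  ## positional subcomplexes (compensated the same way: a subcomplex
  ## containing an empty A site gets the ligand-alone S1 added)
  sc_res <- lapply(1:3, function(i) {
    roles <- subcomplex_roles(i)
    lig <- roles[vapply(roles, occupied, TRUE)]
    res <- s1(carve(roles, lig = lig, label = paste0("subcomplex_", i)))
    if (!is.null(s1_lig) && !any(vapply(roles, occupied, TRUE)))
      res$s1 <- res$s1 + s1_lig
    res
  })
  subcomplex_table <- relative_table(sc_res, tie_tol = tie_tol)
  ## six A-B interface gains (the bound nucleotide travels with its A
  ## subunit: I = A.Y, J = B)
  ifc <- ab_interfaces()
  ab_gains <- lapply(seq_len(nrow(ifc)), function(k) {
    a <- ifc[k, 1L]; b <- ifc[k, 2L]
    lig <- if (occupied(a)) a else character()
    gi <- interface_gain(
      carve(c(a, b), lig = lig, label = paste0(a, ".", b, ".pair")),
      carve(a, lig = lig, label = if (length(lig)) paste0(a, ".bound") else a),
      carve(b, label = b),
      coefficients, probe = probe, ...)
    gi$pair_label <- paste0(a, "-", b)
    gi
  })
  names(ab_gains) <- vapply(ab_gains, function(g) g$pair_label, "")
  ## shaft interfaces
  shaft_gains <- list(); shaft_sum <- NA_real_
  if (has_shaft) {
    all_roles <- c(a_roles, c("B_DP", "B_TP", "B_E"))
    shaft_gains <- lapply(all_roles, function(r) {
      lig <- if (occupied(r)) r else character()
      gi <- interface_gain(
        carve(c(r, "DF"), lig = lig, label = paste0(r, ".DF.pair")),
        carve(r, lig = lig, label = if (length(lig)) paste0(r, ".bound") else r),
        carve("DF", label = "DF"),
        coefficients, probe = probe, ...)
      gi$pair_label <- paste0(r, "-DF")
      gi
    })
    names(shaft_gains) <- vapply(shaft_gains, function(g) g$pair_label, "")
    shaft_sum <- sum(vapply(shaft_gains, function(g) g$delta_s, 0))
  }
  subunit_eta <- stats::setNames(vapply(sub_res, function(r) r$s1, 0), a_roles)
  sc_eta <- stats::setNames(vapply(sc_res, function(r) r$s1, 0),
                            paste0("subcomplex_", 1:3))
  structure(list(
    subunit_table = subunit_table,
    subcomplex_table = subcomplex_table,
    ab_gains = ab_gains,
    shaft_gains = shaft_gains,
    shaft_gain_sum = shaft_sum,
    has_shaft = has_shaft,
    compensation = if (!is.null(s1_lig))
      list(applied = TRUE, ligand_s1 = s1_lig, site = lig_sites[1L])
      else list(applied = FALSE),
    subunit_ordering = rank_packing(subunit_eta, expected_subunit_order,
                                    tol = tie_tol,
                                    coefficients_id = coefficients$id),
    subcomplex_ordering = rank_packing(sc_eta, expected_subcomplex_order,
                                       tol = tie_tol,
                                       coefficients_id = coefficients$id),
    coefficients_id = coefficients$id),
    class = "packing_structure_report")
}

#' @export
print.packing_structure_report <- function(x, ...) {
  cat("<packing_structure_report>\n")
  cat("A-subunit relative S1/kB (reference = most closely packed):\n")
  print(x$subunit_table[, c("label", "relative_s1", "is_reference")],
        row.names = FALSE)
  cat("Subcomplex relative S1/kB:\n")
  print(x$subcomplex_table[, c("label", "relative_s1", "is_reference")],
        row.names = FALSE)
  cat("A-B interface gains (Delta S_IJ/kB):\n")
  for (g in x$ab_gains) cat(sprintf("  %-12s %8.2f\n", g$pair_label, g$delta_s))
  if (x$has_shaft) {
    cat("Shaft interface gains:\n")
    for (g in x$shaft_gains)
      cat(sprintf("  %-12s %8.2f\n", g$pair_label, g$delta_s))
    cat(sprintf("  sum of the six shaft gains: %.2f\n", x$shaft_gain_sum))
  }
  invisible(x)
}
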