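#' Hydration entropy of a structure via the morphometric linear form
#'
#' Evaluates S1/k_B = c_V V + c_A A + c_C C + c_X X on the probe-dilated
#' union of the structure's spheres.  S1 is the water-entropy loss upon
#' creating, at a fixed position, a cavity that geometrically matches the
#' solute; it is negative, and a smaller |S1| means the structure is more
#' closely packed (higher packing efficiency).
#'
#' The probe radius must equal half the solvent diameter the coefficients
#' were calibrated with; a mismatch would evaluate the linear form on a
#' surface the calibration knows nothing about, so it is an error.
#'
#' @param spheres a [sphere_set] (van der Waals radii, undilated).
#' @param coefficients an `ma_coefficients` object from [calibrate()].
#' @param probe probe radius in Angstrom; defaults to the calibration's
#'   d/2.
#' @param method measure backend passed to [measures()].
#' @param ... further arguments for [measures()].
#' @return An `entropy_result`: list with `label`, `s1` (S1/k_B),
#'   `terms` (the four addends), `measures` (a `measure_estimate`),
#'   `standard_error`, `coefficients_id`.
#' @export
s1_structure <- function(spheres, coefficients, probe = NULL,
                         method = "auto", ...) {
  stopifnot(inherits(spheres, "sphere_set"),
            inherits(coefficients, "ma_coefficients"))
  if (is.null(probe)) probe <- coefficients$probe
  if (abs(probe - coefficients$solvent$d / 2) > 1e-9)
    stop(sprintf(paste0("probe radius %.4g does not match the calibration ",
                        "solvent radius %.4g (d/2)"), probe,
                 coefficients$solvent$d / 2))
  est <- measures(spheres, probe = probe, method = method, ...)
  cv <- c(coefficients$c_V, coefficients$c_A, coefficients$c_C,
          coefficients$c_X)
  terms <- cv * est$value
  names(terms) <- c("c_V.V", "c_A.A", "c_C.C", "c_X.X")
  se <- sqrt(sum((cv * est$standard_error)^2))
  structure(list(label = spheres$label, s1 = sum(terms), terms = terms,
                 measures = est, standard_error = se,
                 coefficients_id = coefficients$id),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> '%s': S1/kB = %.2f", x$label, x$s1))
  if (x$standard_error > 0) cat(sprintf(" +- %.2f", x$standard_error))
  cat(sprintf("  [%s]\n", x$coefficients_id))
  invisible(x)
}

#' Relative hydration-entropy table
#'
#' Tabulates S1/k_B of each structure relative to the one with the
#' smallest |S1| (the most closely packed), the layout used for
#' subcomplex comparisons: the reference row is 0 and every other row is
#' negative.  Smaller |S1| means closer packing, so more negative relative
#' values mean lower packing efficiency.
#'
#' @param results a list of `entropy_result` objects (>= 2, distinct
#'   labels, same calibration).
#' @param tie_tol values of |S1| within this tolerance (k_B) of the
#'   reference are flagged as ties (default 1).
#' @return A `relative_entropy_table`: data frame with columns `label`,
#'   `s1`, `relative_s1`, `is_reference`, `tie_with_reference`.
#' @export
relative_table <- function(results, tie_tol = 1) {
  stopifnot(is.list(results), length(results) >= 2L,
            all(vapply(results, inherits, TRUE, "entropy_result")))
  labels <- vapply(results, function(r) r$label, "")
  if (anyDuplicated(labels))
    stop("duplicate labels in relative_table input")
  ids <- unique(vapply(results, function(r) r$coefficients_id, ""))
  if (length(ids) > 1L)
    stop("entropy results mix different calibration coefficients")
  s1 <- vapply(results, function(r) r$s1, 0)
  ## reference: smallest |S1|; ties broken by label order, flagged
  ord <- order(abs(s1), labels)
  ref <- ord[1L]
  out <- data.frame(label = labels, s1 = s1,
                    relative_s1 = s1 - s1[ref],
                    is_reference = seq_along(s1) == ref,
                    tie_with_reference =
                      abs(abs(s1) - abs(s1[ref])) <= tie_tol &
                      seq_along(s1) != ref,
                    stringsAsFactors = FALSE)
  attr(out, "reference_label") <- labels[ref]
  attr(out, "coefficients_id") <- ids
  attr(out, "note") <- "smaller |S1| implies closer packing (higher PE)"
  class(out) <- c("relative_entropy_table", "data.frame")
  out
}

#' Convert a water-entropy change to a system free-energy change
#'
#' In the water-entropy picture the free-energy change of the system is
#' carried by the hydration-entropy change: Delta G ~ -T Delta S_water.
#' Reported both in units of k_B T and in kcal/mol (k_B = 0.0019872041
#' kcal mol^-1 K^-1), e.g. -20 k_B T at 298 K is about -12 kcal/mol —
#' the scale of one ATP hydrolysis in bulk solution.
#'
#' @param delta_s_over_kb entropy change Delta S / k_B (dimensionless).
#' @param temperature absolute temperature in K (default 298).
#' @return List with `delta_g_kbt` (Delta G in units of k_B T) and
#'   `delta_g_kcal_mol`.
#' @examples
#' entropy_to_free_energy(20, 298)$delta_g_kcal_mol  # ~ -11.8
#' @export
entropy_to_free_energy <- function(delta_s_over_kb, temperature = 298) {
  if (!all(is.finite(delta_s_over_kb)) || !is.finite(temperature))
    stop("inputs must be finite")
  kb_kcal <- 0.0019872041  # kcal / (mol K)
  dg_kbt <- -delta_s_over_kb
  list(delta_g_kbt = dg_kbt,
       delta_g_kcal_mol = dg_kbt * kb_kcal * temperature,
       temperature = temperature,
       kb_kcal_per_mol_K = kb_kcal)
}

#' Compare packing efficiencies
#'
#' The single comparator used by all ranking code: a smaller |S1| (or
#' |eta|) means closer packing and higher packing efficiency.  Values
#' whose magnitudes differ by no more than `tol` count as tied.
#'
#' @param s1_a,s1_b S1/k_B (or eta) values.
#' @param tol equality tolerance in k_B (default 1).
#' @return +1 if `s1_a` has higher PE, -1 if lower, 0 if tied.
#' @export
pe_compare <- function(s1_a, s1_b, tol = 1) {
  d <- abs(s1_b) - abs(s1_a)
  if (abs(d) <= tol) 0L else if (d > 0) 1L else -1L
}
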