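#' Save calibrated coefficients as a versioned JSON artifact
#'
#' Coefficient files are the unit of provenance: every downstream entropy
#' value records the id embedded here, so results can always be traced to
#' one calibration (solvent, closure, radii, fit diagnostics).
#'
#' @param coefficients an `ma_coefficients` object.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_coefficients <- function(coefficients, path) {
  stopifnot(inherits(coefficients, "ma_coefficients"))
  x <- list(id = coefficients$id,
            coefficients = list(c_V = coefficients$c_V,
                                c_A = coefficients$c_A,
                                c_C = coefficients$c_C,
                                c_X = coefficients$c_X),
            fit_rms = coefficients$fit_rms,
            calibration_radii = coefficients$calibration_radii,
            residuals = coefficients$residuals,
            s1 = coefficients$s1,
            closure = coefficients$closure,
            probe = coefficients$probe,
            solvent = list(d = coefficients$solvent$d,
                           rho = coefficients$solvent$rho,
                           temperature = coefficients$solvent$temperature),
            package_version = as.character(utils::packageVersion("hydromorph")))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load coefficients saved by [write_coefficients()]
#'
#' @param path JSON path.
#' @return An `ma_coefficients` object.
#' @export
read_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("id", "coefficients", "closure", "probe", "solvent")
  if (!all(need %in% names(x)))
    stop(sprintf("'%s' is not a coefficients file (missing: %s)", path,
                 paste(setdiff(need, names(x)), collapse = ", ")))
  sv <- solvent_model(x$solvent$d, x$solvent$rho, x$solvent$temperature)
  structure(list(c_V = x$coefficients$c_V, c_A = x$coefficients$c_A,
                 c_C = x$coefficients$c_C, c_X = x$coefficients$c_X,
                 fit_rms = x$fit_rms, calibration_radii = x$calibration_radii,
                 residuals = x$residuals, s1 = x$s1,
                 solvent = sv, closure = x$closure, probe = x$probe,
                 id = x$id),
            class = "ma_coefficients")
}

#' Read a structured run configuration
#'
#' YAML configuration shared by the command-line interface and scripted
#' runs: structure path, chain-to-role map, ligand assignments, radius
#' table, coefficients file, probe, backend options, seed, output
#' directory.  A resolved copy of the configuration is written next to
#' every run's artifacts so any artifact can be regenerated from it.
#'
#' @param path YAML file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop(sprintf("config '%s' is not a key-value mapping", path))
  structure(cfg, class = c("run_config", "list"))
}

## assembly_spec from the config's mapping blocks
config_assembly_spec <- function(cfg) {
  if (is.null(cfg$role_map)) stop("config field 'role_map' is required")
  assembly_spec(unlist(cfg$role_map),
                site_ligands = cfg$site_ligands %||% list(),
                ligand_map = if (!is.null(cfg$ligand_map))
                  unlist(cfg$ligand_map),
                motor_family = cfg$motor_family %||% "V1")
}

#' Write a data frame as a provenance-stamped TSV
#'
#' @param df data frame.
#' @param path output path.
#' @param provenance named character vector written as `# key: value`
#'   header lines.
#' @return Invisibly, `path`.
#' @export
write_tsv_artifact <- function(df, path, provenance = c()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## gains list -> data frame
.gains_df <- function(gains) {
  if (!length(gains)) return(data.frame(pair = character(),
                                        delta_s_kB = numeric()))
  data.frame(pair = vapply(gains, function(g) g$pair_label, ""),
             delta_s_kB = vapply(gains, function(g) g$delta_s, 0),
             row.names = NULL)
}

#' Write the full packing-structure report as TSV + JSON artifacts
#'
#' Emits `subunits.tsv`, `subcomplexes.tsv`, `interfaces.tsv` (the
#' human-diffable mirrors of the per-subunit, subcomplex and interface
#' tabulations) and `report.json` (the machine surface), all stamped with
#' the coefficients id.
#'
#' @param report a `packing_structure_report`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default empty).
#' @return Invisibly, the paths written.
#' @export
write_packing_report <- function(report, dir, prefix = "") {
  stopifnot(inherits(report, "packing_structure_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(coefficients_id = report$coefficients_id)
  p <- function(name) file.path(dir, paste0(prefix, name))
  paths <- c(
    write_tsv_artifact(as.data.frame(report$subunit_table), p("subunits.tsv"),
                       prov),
    write_tsv_artifact(as.data.frame(report$subcomplex_table),
                       p("subcomplexes.tsv"), prov),
    write_tsv_artifact(rbind(.gains_df(report$ab_gains),
                             .gains_df(report$shaft_gains)),
                       p("interfaces.tsv"), prov))
  j <- list(coefficients_id = report$coefficients_id,
            has_shaft = report$has_shaft,
            compensation = report$compensation,
            subunits = as.data.frame(report$subunit_table),
            subcomplexes = as.data.frame(report$subcomplex_table),
            ab_gains = .gains_df(report$ab_gains),
            shaft_gains = .gains_df(report$shaft_gains),
            shaft_gain_sum = report$shaft_gain_sum,
            subunit_ranking = report$subunit_ordering$ranking,
            subcomplex_ranking = report$subcomplex_ordering$ranking)
  jsonlite::write_json(j, p("report.json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(paths, p("report.json")))
}
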