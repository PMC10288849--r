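#' Labeled sphere collections
#'
#' A `sphere_set` is the geometric unit of the whole analysis: a labelled
#' collection of spheres (centers in Angstrom, one positive radius per
#' sphere) standing for a subunit, a ligand, a subunit pair, or a whole
#' complex.  Atom-level metadata (chain, residue, atom name) survives as an
#' attached data frame when the set was carved from a parsed structure, so
#' downstream geometry never needs to re-read files.
#'
#' @param centers numeric matrix with three columns (x, y, z in Angstrom),
#'   one row per sphere.
#' @param radii numeric vector of sphere radii in Angstrom, all > 0.
#' @param label single character label, unique within an analysis run.
#' @param atoms optional data frame of atom records carried as provenance.
#' @return An object of class `sphere_set`.
#' @examples
#' ss <- sphere_set(matrix(0, 1, 3), 1.4, label = "probe")
#' nsphere(ss)
#' @export
sphere_set <- function(centers, radii, label = "spheres", atoms = NULL) {
  if (is.data.frame(centers)) centers <- as.matrix(centers)
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3L, byrow = TRUE)
  centers <- unname(as.matrix(centers))
  storage.mode(centers) <- "double"
  if (ncol(centers) != 3L)
    stop("'centers' must have three columns (x, y, z)")
  radii <- as.numeric(radii)
  if (length(radii) == 1L) radii <- rep(radii, nrow(centers))
  if (length(radii) != nrow(centers))
    stop("length of 'radii' must match the number of centers")
  if (nrow(centers) == 0L)
    stop("a sphere_set must contain at least one sphere")
  if (!all(is.finite(centers)) || !all(is.finite(radii)))
    stop("sphere centers and radii must be finite")
  if (any(radii <= 0))
    stop("all sphere radii must be > 0")
  structure(
    list(centers = centers, radii = radii, label = as.character(label)[1L],
         atoms = atoms),
    class = "sphere_set")
}

#' @export
print.sphere_set <- function(x, ...) {
  cat(sprintf("<sphere_set> '%s': %d spheres, radii [%.3g, %.3g] A\n",
              x$label, nrow(x$centers), min(x$radii), max(x$radii)))
  invisible(x)
}

#' Number of spheres in a set
#' @param x a `sphere_set`.
#' @return Integer count.
#' @export
nsphere <- function(x) {
  stopifnot(inherits(x, "sphere_set"))
  nrow(x$centers)
}

#' Combine sphere sets rigidly
#'
#' Concatenates the spheres of several sets without touching any coordinate
#' (the rigid-split convention: a pair is always the exact union of its
#' parts).
#'
#' @param ... `sphere_set` objects.
#' @param label label for the combined set.
#' @return A `sphere_set` holding all spheres of the inputs, in order.
#' @export
combine_spheres <- function(..., label = NULL) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "sphere_set"))
    parts <- parts[[1L]]
  stopifnot(length(parts) >= 1L, all(vapply(parts, inherits, TRUE, "sphere_set")))
  if (is.null(label))
    label <- paste(vapply(parts, function(p) p$label, ""), collapse = "+")
  atoms <- lapply(parts, function(p) p$atoms)
  atoms <- if (all(!vapply(atoms, is.null, TRUE))) do.call(rbind, atoms) else NULL
  sphere_set(do.call(rbind, lapply(parts, function(p) p$centers)),
             unlist(lapply(parts, function(p) p$radii)),
             label = label, atoms = atoms)
}

#' Rigidly transform a sphere set
#'
#' Rotation about the z axis followed by a translation; used by the toy
#' generator (shaft orientation scans) and by the invariance tests.
#'
#' @param x a `sphere_set`.
#' @param angle rotation angle about the z axis, degrees.
#' @param shift numeric length-3 translation in Angstrom.
#' @return The transformed `sphere_set`.
#' @export
transform_spheres <- function(x, angle = 0, shift = c(0, 0, 0)) {
  stopifnot(inherits(x, "sphere_set"))
  th <- angle * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3L, 3L, byrow = TRUE)
  ctr <- x$centers %*% t(rot)
  ctr <- sweep(ctr, 2L, as.numeric(shift), "+")
  sphere_set(ctr, x$radii, label = x$label, atoms = x$atoms)
}

#' Dilate every sphere by the probe radius
#'
#' Growing each radius by the solvent probe radius turns the van der Waals
#' body into the excluded volume: the region water-molecule centers cannot
#' enter.  Centers are untouched.
#'
#' @param spheres a `sphere_set`.
#' @param probe_radius probe radius in Angstrom, >= 0.
#' @return The dilated `sphere_set`.
#' @examples
#' dilate(sphere_set(matrix(0, 1, 3), 1.4), 1.4)$radii  # 2.8
#' @export
dilate <- function(spheres, probe_radius) {
  stopifnot(inherits(spheres, "sphere_set"))
  if (!is.finite(probe_radius) || probe_radius < 0)
    stop("'probe_radius' must be a finite non-negative number")
  sphere_set(spheres$centers, spheres$radii + probe_radius,
             label = spheres$label, atoms = spheres$atoms)
}
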