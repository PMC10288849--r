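## shared expensive fixtures, computed once per test run

.hm_cache <- new.env(parent = emptyenv())

## default-solvent HNC calibration (the one every entropy test uses)
hm_coeffs <- function() {
  if (is.null(.hm_cache$coeffs))
    .hm_cache$coeffs <- calibrate(solvent_model())
  .hm_cache$coeffs
}

## moderate-overlap lattice cluster: the regime in which both measure
## backends estimate the same quantities (see the methods vignette)
lattice_cluster <- function(k, spacing, seed, rlo = 1.4, rhi = 1.8) {
  with_seed(seed, {
    g <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3)) * spacing
    g <- g[sample(nrow(g), k), , drop = FALSE] +
      matrix(stats::rnorm(k * 3, sd = 0.05 * spacing), ncol = 3)
    sphere_set(g, stats::runif(k, rlo, rhi), label = sprintf("cluster%d", seed))
  })
}

## independent hit-or-miss volume oracle (no shared code with the backends)
mc_volume_oracle <- function(ss, n = 2e6, seed = 1) {
  ctr <- ss$centers; rad <- ss$radii
  lo <- apply(ctr - rad, 2, min); hi <- apply(ctr + rad, 2, max)
  with_seed(seed, {
    pts <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]),
                 stats::runif(n, lo[3], hi[3]))
    inside <- rep(FALSE, n)
    for (i in seq_len(nrow(ctr)))
      inside <- inside | (rowSums(sweep(pts, 2, ctr[i, ], "-")^2) < rad[i]^2)
    v <- prod(hi - lo) * mean(inside)
    se <- prod(hi - lo) * stats::sd(inside) / sqrt(n)
    c(value = v, se = se)
  })
}

## small random cluster for property tests
random_cluster <- function(k, seed, sd = 2.2, rlo = 0.8, rhi = 2.0,
                           label = sprintf("rnd%d", seed)) {
  with_seed(seed, {
    sphere_set(matrix(stats::rnorm(k * 3, sd = sd), ncol = 3),
               stats::runif(k, rlo, rhi), label = label)
  })
}

## minimal synthetic PDB text fixtures built in code
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     occ = 1, alt = "", elem = NULL) {
  if (is.null(elem)) elem <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
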