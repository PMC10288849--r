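Package: hydromorph
Title: Hydration-Entropy Packing Analysis of Rotary ATPase Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Morphometric hydration-entropy analysis of protein assemblies,
    built for the packing structure of rotary ATPase rings (V-type A3B3DF and
    F-type alpha3beta3gamma complexes).  Computes the four morphometric
    measures of a union of atom spheres dilated by the solvent probe (exact
    boundary-arrangement backend and a Steiner-series Monte-Carlo backend),
    calibrates the linear hydration-entropy coefficients against an
    isotropic hard-sphere Ornstein-Zernike solver (HNC and PY closures),
    and derives the packing statistics used to analyse such motors: packing
    efficiencies of subunits and positional subcomplexes, water-entropy
    gains of subunit interfaces and of ligand-mediated association, shaft
    orientation scans, catalytic-site distances, and seeded synthetic ring
    assemblies that make the whole pipeline testable without structure
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
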