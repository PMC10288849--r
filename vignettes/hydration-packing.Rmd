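---
title: "Water-entropy packing analysis: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-entropy packing analysis: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A solute held at a fixed position in water excludes water-molecule centers
from a region of space — the excluded volume (EV), the union of the atom
spheres dilated by the solvent radius.  Creating that cavity costs the
solvent translational (configurational) entropy.  We call the loss `S1`
(`S1 < 0`, in units of `k_B`); its magnitude grows with the size of the EV,
so for a fixed set of atoms, *tighter packing means a smaller `|S1|`*.
That single comparator — smaller `|S1|` implies higher packing efficiency
(PE) — drives the whole analysis of multi-subunit ring motors: which
catalytic subunit is most closely packed, which interfaces are tight,
how a bound nucleotide or the central shaft changes the picture.

The hydration entropy is evaluated with the morphometric approach (MA).
By Hadwiger's characterization, any additive, motion-invariant, continuous
functional of a body in 3-space is a linear combination of its four
Minkowski functionals, so

```
S1 / k_B  =  c_V V + c_A A + c_C C + c_X X
```

where `V`, `A`, `C`, `X` are the volume, boundary area, integrated mean
curvature and integrated Gaussian curvature of the probe-dilated union of
balls, and the four coefficients depend only on the solvent.  Conventions
(`sphere_measures()`): a ball of radius `R` gives `(4πR³/3, 4πR², 4πR,
4π)`; `X` is `2π` times the Euler characteristic of the boundary.  The
coefficients are calibrated on spherical solutes, for which the reference
entropy can be computed from first principles, and then applied to
arbitrarily shaped solutes.

Derived statistics (all in `k_B`):

* Packing efficiency of a subunit or subcomplex: `eta = S1` (nothing
  bound), `eta_Y = S1(with Y) − S1(Y)` (ligand `Y` bound), and the
  compensated forms `eta' = S1 + S1(Y)`, `eta'_Y = S1(with Y)` used when
  an empty site must be compared impartially against occupied sites.  The
  identity `eta − eta_Y = eta' − eta'_Y` holds exactly and is
  property-tested.
* Interface gain `ΔS_IJ = S1(pair) − [S1(I) + S1(J)]`, the water-entropy
  gain when two rigidly carved subunits are in contact.  We use the
  bracketed reading — pair minus the *sum* of the parts — which is the
  only one for which the gain is zero at infinite separation and positive
  for a packed interface.
* Association gain `ΔS1 = S1(A·Y-B) − [S1(A) + S1(Y) + S1(B)]`, the
  ligand-mediated generalization.
* The catalytic distance `L`: the distance between the γ-phosphate
  phosphorus of a bound nucleotide and the carboxyl carbon (`CD`) of the
  catalytic glutamate (residue 261 in the V-type A subunit) — pure
  geometry, used as a proxy for hydrolysis readiness.

## Geometry backends

`measures_exact()` computes `(V, A, C, X)` analytically from the
arrangement of sphere-sphere intersection circles.  Per sphere, every
neighbor defines a spherical cap; uncovered arcs of the cap circles are
the boundary edges.  Exposed areas come from Gauss-Bonnet (the Euler
characteristic of each exposed region is assembled combinatorially from
the cap-overlap graph and the boundary-cycle count), volumes from the
divergence theorem with arc-wise closed-form vector areas, the mean
curvature from the smooth patches plus `−γ/2` per unit length of each
reentrant edge (`γ` = angle between the outward sphere normals), and `X`
from the global face-edge-vertex assembly.  These are the *additively
extended* (convex-ring) measures — the ones Hadwiger's theorem is about.
The backend is exact to round-off in generic position; exact duplicates
and swallowed spheres are eliminated first, and near-tangent
configurations (within `tol = 1e-8` Å) are rejected as degenerate rather
than silently resolved.  It was validated against closed forms (spheres,
lens pairs, collinear triples via inclusion-exclusion), against
independent hit-or-miss and surface-sampling oracles, and against a
nerve-theorem Euler-characteristic oracle on dense random clusters.

`measures_steiner_mc()` is the stochastic backend for unions too large
for the arrangement: the volumes of the ε-parallel bodies (all radii
grown by ε) are estimated from one seeded uniform sample in a bounding
box and `(V, A, C, X)` are recovered by least squares from the
Steiner-type cubic `V(ε) ≈ V + Aε + Cε² + (X/3)ε³`.  Two facts shape the
estimator design:

* the parallel-body volume of a non-convex union is not exactly a cubic,
  so the fit carries guard terms of one and two orders beyond the cubic
  (quartic from six offsets, quintic from seven; default grid: ten
  offsets in `[0, 0.8]` Å), and the reported standard errors add the
  successive-order coefficient shifts to the binomial sampling
  covariance — an explicit truncation-uncertainty estimate;
* for *deeply* interpenetrating spheres the curvature coefficients of the
  dilation series differ systematically from the additive measures (a
  reentrant-wedge effect: the dilation edge density behaves like
  `−tan(γ/2)` versus the additive `−γ/2`), so `C` from this backend is
  only trustworthy for moderately overlapping unions.  `V` and `A` are
  free of the effect.  Cross-validation against the exact backend is part
  of the test suite on moderate-overlap clusters (lattice spacings
  3.0-4.2 Å at radii 1.4-1.8 Å), where all four components agree within
  the reported errors.

The default probe radius is 1.4 Å — half the solvent hard-sphere
diameter — and `s1_structure()` refuses a probe that does not match its
coefficients' solvent, because the linear form is only meaningful on the
surface it was calibrated for.

## Solvent model and calibration

The reference entropies come from the solute-solvent Ornstein-Zernike
equation for one hard-sphere solute at infinite dilution in a hard-sphere
solvent (`solvent_model()`: diameter 2.8 Å, number density 0.0333 Å⁻³,
T = 298 K; packing fraction 0.383).  These defaults are this package's
documented water-mimicking choice.  Hard-sphere solvation is athermal, so
`S1/k_B = −βμ_ex` exactly.  Two closures are available: HNC (default) with
the closed-form Morita-Hiroike chemical-potential functional, and PY,
whose `βμ_ex` is obtained by exact hard-particle charging
(`dβμ/dσ_c = 4πρσ_c² g(σ_c)`, integrated from the exact point-cavity
value `−ln(1−η)`).

Two numerical choices matter.  The cell of the radial grid straddling the
hard-core boundary is blended by its core volume fraction, which removes
a grid-phase sensitivity that otherwise injects ~1 `k_B` of noise into
`S1(R)` across solute radii; and the reported `βμ_ex` is Richardson
extrapolated over the grid and its half-spacing refinement, which cancels
the leading `O(dr)` discretization error (halving the user grid then
changes the result by well under 0.1%).

Accuracy against the Carnahan-Starling equation of state, which the test
suite computes: the PY charging route lands within a few percent, as
expected for hard spheres; HNC converges cleanly (its two independent
chemical-potential routes agree to ~2%) but overshoots CS by roughly 15-20%
at this density — a well-known property of the HNC closure for dense hard
spheres, not a solver defect.  Because the MA coefficients are *fitted to
the same solver that defines them*, closure error does not perturb the
internal consistency of the analysis; it only moves the absolute scale.

`calibrate()` fits the four coefficients to `S1(R)` on 16 equally spaced
radii in `[0.5, 12]` Å against the sphere measures at the EV radius
`R + d/2`.  The fit RMS (df-corrected) is ~0.02 `k_B`, every calibration
point is reproduced within twice that, held-out radii are predicted well
inside three times it, and `c_V < 0` as the physics requires (larger
excluded volume, more negative entropy).  Coefficients travel as a
versioned JSON artifact whose id is embedded in every downstream result.

**Absolute values are solvent-model dependent.**  A multipolar,
orientation-resolving water model would give different coefficients and
different absolute `S1` magnitudes.  Signs, orderings, differences, and
gains are the comparable surface of this analysis; no output of this
package should be read as an absolute hydration entropy of a real
protein.

## The empty-site compensation

In two-nucleotide states nothing is bound at the third catalytic site, so
the bare subunit has fewer atoms than its nucleotide-bound peers.  For
impartial PE comparison the ligand-alone `S1` is added to every selection
containing the empty site (the `eta'`/`eta'_Y` route); the identity above
guarantees the differences are the same as under the `eta`/`eta_Y` route.
`packing_structure_report()` applies this automatically whenever the
assembly carries ligands and records it in the report's provenance.

## Tie handling

The PE comparator treats `|S1|` values within 1 `k_B` as tied (the
linear-form fit RMS is ~0.02 `k_B`, so 1 `k_B` is a deliberately
conservative equality band); rankings flag ties and break them by label
order, and expected-order comparisons count a flip as a mismatch only
outside the tolerance.

## The synthetic generator

`generate_toy_complex()` builds the statistical structure the analysis
assumes, at a scale (20-60 spheres per subunit) where the exact backend
applies: six jittered-lattice sphere clusters alternating A-like and
B-like roles on a ring of radius 12 Å, per-subunit *tightness* in (0, 1]
mapping to lattice spacing `2r(1.02 + 0.25(1−t))`, optional bridge
clusters standing in for nucleotides at A-B interfaces (5 or 12 spheres
for the ADP-like and ATP-like cases), and an optional central shaft — an
elongated core plus a protruding lobe aimed at the subunit named in the
shaft bias (default: B_E, pulled 2.5 Å toward the axis so that B_E-DF is
the favored shaft interface by construction).

Two geometric regimes informed the defaults.  First, the tightness map is
confined to spacings at which each cluster's EV union stays solidly
connected: looser clusters fragment into marginally touching pieces, and
there the Euler term of the linear form (positive `c_X` times a component
count) breaks the tightness-to-`|S1|` correspondence the generator is
supposed to embody.  Second, the shaft bias must exceed the contact
advantage the larger A-type clusters would otherwise have over the
favored B-type subunit; 2.5 Å does, across seeds.  With these defaults the
generator satisfies its contracts on every seeded battery the tests run:
constructed tightness orderings are recovered through the full entropy
stack, association gains order as large bridge > small bridge > none, and
the constructed shaft orientation strictly maximizes the sum of the six
shaft-interface gains over a 60°-step rotation scan.

What the toys do *not* emulate: real secondary structure, sequence,
side-chain chemistry, the actual V-type geometry beyond ring-plus-shaft
topology, or crystallographic noise.  Passing toy tests therefore
demonstrates that the *pipeline* (geometry, calibration, statistics,
orderings) is correct and self-consistent — not that any particular real
complex will show a particular ordering.

## Degenerate inputs and policies

* Alternate locations: highest occupancy wins, ties break alphabetically
  by alt-loc id.  Waters are excluded by default (they belong to the
  solvent model, not the solute).
* Unknown elements in radius assignment are a hard error naming the
  atoms; there is no silent default radius.
* Exact duplicate spheres are dropped; spheres entirely inside another
  are eliminated (they cannot touch the boundary); near-tangencies beyond
  the 1e-8 Å tolerance are an error.
* `relax_overlaps()` (steepest descent on a soft overlap penalty,
  displacement-capped per atom) mirrors the crystallographic practice of
  removing slight atom overlaps, but it is *off by default*: the
  union-of-balls geometry is well defined for overlapping spheres.
* Carving never moves an atom; every pair/complex split is verified to be
  an exact multiset partition before gains are computed.
* All stochastic steps take explicit integer seeds and record them in
  their outputs; identical seeds give bit-identical results.

## Problem sizes

The shipped tests and the reproduction script run the exact backend on
unions up to a few hundred spheres, the stochastic backend at 10⁶ samples
per estimate, calibrations on 16 radii with a 4096-point radial grid
(cutoff 82 Å), and seeded toy batteries of 20 assemblies — sizes chosen so
the full suite replays in minutes on one core while every statistic keeps
comfortable margins.

## Known limitations

* The solvent is isotropic: no hydrogen-bond orientation, no
  electrostatics, no enthalpy.  Only the translational-entropy physics is
  represented; orientational contributions are absorbed into the
  calibration.
* Fixed structures: no conformational ensembles, no side-chain
  flexibility, no conformational-entropy terms.
* The stochastic backend's curvature coefficients inherit the
  dilation-series convention; use the exact backend when `C` matters and
  the union is deeply overlapping.
* The MA linear form itself misbehaves at topology changes (the `X` term
  jumps by `4π` when components merge), which is why near-fragmented
  structures are outside the generator's design range and should be
  interpreted cautiously in real inputs too.
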