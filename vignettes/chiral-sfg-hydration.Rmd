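---
title: "Chiral SFG spectra of hydration-shell water: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chiral SFG spectra of hydration-shell water: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralsfg)
```

## The problem

Chiral sum-frequency generation (SFG) spectroscopy detects the
second-order susceptibility element `chi2_zyx`, which vanishes unless
the interfacial arrangement of molecules is chiral.  Water molecules
are achiral, yet water templated by a chiral solute at an interface can
form a chiral superstructure and emit a chiral SFG signal in the O–H
stretch band.  This package computes that signal from molecular
configurations and dissects it by hydration shell and by the
hydrogen-bonding relationship between each water and the solute, which
is how one shows that the response is dominated by the first hydration
shell.

## The spectroscopic model

Each water O–H bond is treated as a local-mode chromophore through an
electric-field spectroscopic map.  For a bond O→H with unit vector
$\hat u$, the electric field of all charged sites of *other* molecules
within a cutoff of the H atom is projected on $\hat u$, giving a scalar
$E$ in atomic units.  Map polynomials then supply:

* the 0→1 frequency $\omega_{10}(E)$ (cm⁻¹),
* the position matrix element $x_{10}(\omega_{10})$ (Å),
* the transition-dipole derivative $\mu'(E)$,

so the bond's transition dipole is $\mu = \mu'(E)\,x_{10}\,\hat u$ and
its transition polarizability is the axially symmetric bond tensor
$\alpha = x_{10}\,[r\,I + (1-r)\,\hat u \hat u^{\mathsf T}]$ with
transverse/parallel ratio $r$.  The two O–H bonds of one molecule are
coupled through a 2×2 exciton Hamiltonian whose off-diagonal element
follows the map's intramolecular coupling model; *inter*molecular
coupling is deliberately neglected, which makes the spectrum of a union
of disjoint water subsets exactly the sum of the subset spectra — the
property that allows a clean shell decomposition.

The spectrum is computed in the inhomogeneous limit: each analyzed
configuration contributes static sticks $(\omega_m, A_{ij}\mu_k)$, with
$(i,j,k)$ the lab-frame indices of the requested tensor element
(`zyx` for chiral psp detection, `yyz` for achiral ssp), broadened by a
normalized line shape and averaged over frames.  The imaginary part is
the reported observable, matching phase-resolved detection; the real
part is its Kramers–Kronig partner and is retained in all outputs.

The map coefficients are configuration, not code: they ship in
`inst/extdata/map_oh_tip4p_2013.yaml`, transcribed from a published O–H
stretch map for 4-site water models (source and units documented in the
file), and any compatible file can be substituted.  The overall
amplitude of `chi2` is arbitrary — no absolute intensity calibration is
attempted — so all comparisons between spectra use ratios, areas, or
signs.

Fermi resonance with the bend overtone, intermolecular vibrational
coupling, and motional narrowing are outside the model.

## Symmetry properties the implementation must honor

Three exact properties anchor the test suite:

1. **Mirror antisymmetry.**  Reflecting every coordinate through a
   vertical plane (one containing the interface normal) negates
   `Im chi2_zyx` pointwise.  Reflection is implemented as a pure sign
   flip of one coordinate, which is exact in floating point, so the
   test asserts machine precision.
2. **Achiral null.**  Any arrangement with an explicit vertical mirror
   plane — an untilted planar ring of waters, or a structure merged
   with its own mirror image — yields `chi2_zyx = 0` to numerical
   precision relative to the single-stick scale.
3. **Additivity.**  `chi2(first) + chi2(second) + chi2(rest) =
   chi2(all)` exactly, because intermolecular coupling is absent.

## Hydration shells and the hydrogen-bond taxonomy

Shells are defined by Voronoi tessellation of all atomic centers
(hydrogens included, massless virtual sites excluded) under full
periodic boundary conditions.  A water is in the **first shell** if any
of its atoms' Voronoi cells shares a face with a solute atom's cell,
and in the **second shell** if it borders a first-shell water without
being in the first shell.  No pre-installed R package provides periodic
3-D tessellation, so the package implements the standard per-particle
cell-clipping algorithm (each cell starts as a bounding cube and is cut
by bisector half-spaces of candidate neighbors, nearest first, until no
candidate can reach the cell) in C++.  The engine is validated against
a frozen neighbor list computed with an independent tessellation
library on a random periodic point set, and against analytic cases
(cubic lattice: exactly 6 face neighbors).  Exactly degenerate
configurations (co-circular lattices) are handled by an area threshold
on faces; optional deterministic jitter (`1e-9` Å, logged) is available
for pathological inputs.

First-shell waters are split into **backbone** and **side-chain**
regions by which class of solute atom their cells touch; the regions
deliberately overlap so that together they cover the first shell.
Hydrogen bonds use geometric criteria: donor-heavy to acceptor-heavy
distance `< 3.5` Å and donor-heavy–H···acceptor angle at the hydrogen
`> 135°` (with a `>135°` threshold, the at-H vertex is the only
geometrically sensible convention, and 180° is linear).  The taxonomy
then distinguishes waters donating to backbone carbonyls (with a
"strong" subset at H···O `≤ 1.6` Å), waters accepting from amide N–H,
waters H-bonded to side-chain ammonium groups, and the
near-but-not-H-bonded complements.  The N–H class is amide-only;
side-chain ammonium donors are classified separately.

## Water-ordering diagnostics

* **Dipole grid**: each water's point-charge dipole (chemistry
  convention: along the H–O–H bisector, pointing toward the oxygen) is
  added to the 1 Å interfacial-plane cell containing its oxygen,
  restricted to a depth range below the water surface.  The surface is
  located per frame as the mean height of the top decile of water
  oxygens — a robust density proxy, configurable.  Both in-plane and
  full 3-vector ring sums are reported because either convention is
  defensible for annulus profiles.
* **Annulus profile**: the magnitude of the vector sum of cell dipoles
  in concentric 1 Å rings; near-zero magnitude indicates local mirror
  symmetry, nonzero magnitude broken symmetry.
* **Mirror-asymmetry score**: RMS difference between the dipole field
  and its mirror image across a chosen vertical plane, over cells
  occupied on both sides; it quantifies what is otherwise a visual
  judgment.
* **Retention time**: subset membership is sampled at 1 ps resolution;
  episodes are maximal runs of consecutive membership and the retention
  time is the mean episode length.  Episodes truncated by the
  trajectory edges are included in the mean and counted as censored —
  with short test trajectories the censored fraction is large, and the
  separate count makes that visible.
* **Dangling O–H fraction**: fraction of subset waters with at least
  one O–H bond pointing within `angle_max` of the vacuum normal whose
  H donates no hydrogen bond.  The angular threshold defaults to 60°;
  it is a tunable with no canonical value, and results should be
  reported with the threshold used.

## Synthetic systems

The generators exist so that every downstream stage is testable without
external trajectories:

* `build_chiral_water_helix()` places waters on one helix turn with
  bisectors tilted toward the local tangent.  Any nonzero tilt or pitch
  breaks all vertical mirror planes (chiral); zero tilt and zero pitch
  gives an explicitly mirror-symmetric ring (achiral control).
  Handedness −1 is constructed as the exact reflection of +1.
* `build_mirror_pair()` reflects a frame through a vertical plane.
* `build_template_system()` embeds an idealized planar strand mimic —
  repeat units exposing carbonyl, amide and ammonium-like point-charge
  sites, each repeat netting exactly +1 e, neutralized by chloride —
  at the upper interface of a water slab.  It is a synthetic stand-in
  that reproduces the *interaction classes* of a beta-strand surface,
  not any particular protein; the package's conclusions are exercised
  through symmetry and electrostatics, which do not depend on the
  peptide details.
* `build_slab_fixture()` builds a water slab with a vacuum gap:
  rejection-sampled positions (minimum O–O distance 2.4 Å, which
  prevents unphysical field singularities) and uniform orientations,
  bit-reproducible from the seed.

### Thermalization

With `thermalize = TRUE` the slab is relaxed and sampled at 298 K by a
rigid-body Metropolis Monte Carlo sampler written in C++: one sweep is
one attempted translation + rotation move per molecule, the pair
potential is the water model's O–O Lennard-Jones term plus Coulomb
interactions of all charged sites under a molecule-based 9 Å
minimum-image cutoff, and frames are drawn at fixed sweep intervals
after an equilibration period.  Monte Carlo samples the same NVT
ensemble a thermostatted MD run would, and keeping the sampler inside
the package avoids any dependence on an external simulation engine.
The sampler is deterministic for a given seed and independent of R's
RNG state.  Long-range (Ewald) electrostatics are not included; for
H-bond statistics and orientational ordering the truncation is a
second-order effect, but the sampler is not intended for properties
dominated by long-range fields (e.g. dielectric profiles).

At the default conditions (400 TIP4P-Ew waters in a 20×20×60 Å box,
slab ≈ 30 Å thick, 4000 equilibration sweeps, 60 frames at 50-sweep
spacing) the sampler reaches a potential energy near −11 kcal/mol per
water, and the mean number of hydrogen bonds per water under the
3.5 Å/135° criteria comes out near 3.6 for the pure-water slab.  A
protein-bearing slab has more interface per water and a
solute-perturbed population and therefore sits lower; the acceptance
checks use ≈3.4 as the reference for that regime.  The
test suite uses a smaller, thinner slab (250 waters, 19×19×55 Å,
2500 + 1200 sweeps) whose larger surface fraction brings the mean to
≈3.57; these problem sizes are the package's chosen test conditions
and are stated here so that results are reproducible.

What the generators do *not* emulate: real protein flexibility,
polarization, long-range electrostatics, and the slow collective
dynamics of a production MD trajectory.  Green tests on these fixtures
validate the *machinery* (geometry, symmetry, bookkeeping, statistics),
not force-field realism.

## Numerical choices

* Line shape: Lorentzian with 5 cm⁻¹ half-width by default; a Gaussian
  (with its Kramers–Kronig partner via the Dawson function) is
  available.  Broadening only smooths — it moves no peak signs or
  positions materially.
* Frequency grid: 2800–4000 cm⁻¹ at 1 cm⁻¹, covering the O–H band.
* Field summation cutoff: 7.831 Å (shipped map file), the customary
  value for such maps; configurable.
* Field singularities: a charged site within 0.1 Å of an H atom is an
  error naming the frame and atoms, not a silent large number.
* Exciton diagonalization: analytic 2×2 closed form; the trace
  (`w+ + w- = w1 + w2`) is conserved to rounding.
* Isotope handling: the ¹⁶O→¹⁸O toggle is a harmonic reduced-mass
  rescaling (≈12 cm⁻¹ redshift at 3500 cm⁻¹), a convenience for
  comparison with isotope-labeling experiments.
* Charges: read from the topology when present, otherwise from a named
  charge table (TIP4P-Ew, TIP3P, strand mimic) shipped as plain data
  files.

## Scope and limitations

* Trajectory formats: PDB/GRO topologies; DCD or multi-model PDB
  trajectories.  XTC is not supported (no installed reader; writing an
  XDR codec was judged out of proportion to its value here).
* The full protein-scale experiment — a ~100 ns slab trajectory of an
  amphiphilic beta-sheet peptide with ~1340 waters — is outside desk
  scale.  On such a trajectory the pipeline is expected to show the
  first shell carrying ~90% of the chiral band area, subset H-bond
  means near 3.2/3.1/2.3, a ~15% dangling-OH fraction among
  amide-N–H-bonded waters, and the characteristic +3400/−3600 cm⁻¹
  band pair; those numbers require cluster-scale input that this
  package consumes but does not generate.
* Orthorhombic boxes only for the Monte Carlo sampler; triclinic boxes
  are supported everywhere else via minimum-image search.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates, from
scratch: the thermalized-slab mean H-bond count, the isotope redshift,
and the mirror-antisymmetry and subset-additivity residuals, writing
them as JSON.  The test suite (`testthat`) asserts the same properties
at fixed seeds, plus the oracle equivalences (field sums, tessellation,
run-length retention, grid binning, annulus sums) against brute-force
reimplementations.
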