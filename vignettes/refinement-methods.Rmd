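---
title: "Restrained energy refinement of nucleic acid structures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restrained energy refinement of nucleic acid structures: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Computational models of RNA and DNA 3D structure — from template-based
modelling or coarse-grained folding simulations — usually carry local
defects: steric clashes, distorted bond angles, backbone conformers far
from anything observed in high-resolution crystal structures, and base
pairs that are "almost" paired but with degraded hydrogen-bond and
stacking geometry. `rnarefine` performs fine-grained local refinement of
such models: it minimizes an all-atom molecular-mechanics energy extended
with four restraint terms that push the model towards chemically
idealized local geometry without attempting any global refolding.

## The energy model

The total energy is a sum of standard AMBER-family terms and four add-on
terms, each with an analytic Cartesian gradient:

* **Bonds** `k (r - r0)^2` and **angles** `k (theta - theta0)^2`. The
  convention is `k * delta^2` with no 1/2 factor; force constants are in
  kcal/mol/A^2 and kcal/mol/rad^2. Two rest angles are deliberately tuned
  away from their textbook values to eliminate the most common "bad
  angle" outliers in refined models: OP1-P-OP2 is 119.62 degrees and the
  glycosidic N9-C1'-O4' (N1-C1'-O4' for pyrimidines, which shares the
  same type triple) is 109.00 degrees.
* **Torsions** `k (1 + cos(n phi - gamma))` with wildcard type matching,
  two-fold terms keeping rings and amino groups planar.
* **Lennard-Jones (12-6)** with Lorentz-Berthelot mixing and **Coulomb**
  electrostatics over all non-excluded pairs (1-2 and 1-3 excluded, 1-4
  scaled by 1/2 and 1/1.2 respectively). The system is non-periodic and
  no cutoff is applied by default (`cutoff` is a config knob). Solvent is
  either vacuum or a **generalized Born** model: effective Born radii by
  the pairwise descreening (Hawkins-Cramer-Truhlar) integral with
  per-type intrinsic radii and screening factors, dielectrics 1 (solute)
  and 78.5 (solvent), and the canonical smoothed pairwise energy. The
  gradient includes the full chain rule through the coordinate dependence
  of the Born radii.
* **Explicit hydrogen bonds** (add-on 1):
  `E = k1 exp(-(r - r_ideal)^2 / d) exp(cos(theta - theta0))`, Gaussian in
  the hydrogen-acceptor length and exponential in the cosine of the
  donor-hydrogen-acceptor angle, with `k1 = -1` kcal/mol so that ideal
  geometry is an energy minimum. The literal Gaussian form peaks at zero
  donor-acceptor separation, which is sterically impossible; we therefore
  evaluate it on the *deviation* from a per-donor/acceptor-element ideal
  length (1.84-1.90 A), which preserves the intended shape while
  matching experimental hydrogen-bond lengths. `d = 0.16 A^2` and
  `theta0 = 180` degrees are declared defaults, overridable in the
  parameter files.
* **Base-pair co-planarity** (add-on 2): for each Watson-Crick pair a
  plane is least-squares fitted to the heavy base atoms of both residues
  at every evaluation and `E = k2 sum r_i0^2` accumulates squared
  atom-plane distances. Because the fitted plane is itself the minimizer
  over plane parameters, the exact gradient is simply a force
  perpendicular to the plane, proportional to each atom's distance from
  it. `k2 = 10` kcal/mol/A^2 by default.
* **Backbone regularization** (add-on 3): each backbone fragment (the
  eight atoms P, OP1, OP2, O5', C5', C4', C3', O3' of a residue plus the
  next residue's P — one suite-like unit) is assigned, once at startup,
  the conformer-library entry with minimal superposed RMSD. At every
  evaluation the reference is rigid-body superposed onto the current
  fragment and `E = k3 sum (r_i - b_i)^2`, which equals
  `k3 * n_atoms * RMSD^2` and is invariant under rigid motion of the
  fragment. `k3 = 10` kcal/mol/A^2.
* **Custom springs** (add-on 4): positional `k4 |r - c|^2` to a fixed
  point, or distance `k4 (|r_a - r_b| - rest)^2` between two atoms, from
  a plain-text restraint file (`DIST`/`POSN` records).

With all four add-on terms disabled the model falls back to the plain
force field: those components are exactly zero.

## Base-pair handling

Canonical A-U, G-C (and deoxy analogue) pairs are detected geometrically
at startup: for every candidate pair of complementary residues the
explicit hydrogen-bond energy is summed over the Watson-Crick-edge
donor/hydrogen/acceptor triples and the pair is accepted when that sum is
below -2 kcal/mol. (The acceptance threshold is stated in terms of the
hydrogen-bond term: the co-planarity term is non-negative by construction
and can never be below a negative threshold.) Detected pairs receive both
hydrogen-bond restraints (three triples for G-C, two for A-U/A-T) and a
co-planarity group. When the user supplies secondary structure — a Vienna
dot-bracket string for a single chain, with independent bracket tiers so
pseudoknots can be expressed, or a chain-qualified contact list — the
user list is used verbatim and automatic detection is disabled. The whole
restraint set is frozen at startup; nothing is re-detected during
minimization.

## Parameters and templates

All parameters live in versioned plain-text files under
`inst/extdata/params/`: atom types (Lennard-Jones sigma/epsilon, GB radii
and screening factors), bonded parameters, add-on constants, and one
template file per residue with atoms (name, type, charge, idealized
coordinates), bonds, donor/acceptor annotations and Watson-Crick edge
atoms. Users can add modified residues by dropping in a new template
file; the packaged set covers the eight canonical ribo- and
deoxyribonucleotides plus 5-methyluridine (5MU) and 2'-deoxyuridine (DU)
as modified-residue demonstrations. Force constants are AMBER-family
values; rest lengths and angles are measured from the idealized template
geometry so that templates are near-zero-strain under the force field;
charges are AMBER-flavoured and rebalanced so every internal nucleotide
template sums to exactly -1 e. Template coordinates are idealized
residue geometry (derived from standard chemical-component ideal
coordinates, rebuilt into the C3'-endo/anti conformation used by A-form
helices).

The template idealized coordinates also drive deterministic hydrogen
completion: each missing hydrogen is mapped through the rigid
superposition of its parent atom's local heavy-atom cluster, which makes
`add_hydrogens()` exactly idempotent.

## Backbone conformer library

The packaged library is synthetic: the helical backbone window of an
ideal A-form duplex plus fifteen versioned perturbed variants (0.05-0.4 A
Gaussian noise, generated once with a fixed seed). This replaces a
PDB-mined library while preserving the construction recipe: the exported
`build_conformer_library()` extracts every complete backbone window from
user-supplied coordinate files, so users with access to high-resolution
structures can build a real library and pass it to `refine()`.

## Minimization

Two gradient minimizers are provided: steepest descent with
golden-section line search, and Polak-Ribiere conjugate gradients
(`beta = max(0, PR)`, direction reset on non-descent directions and every
`dim` steps). The line search brackets from a 1e-4 A trial step, growing
geometrically (factor 2) and capped at 1 A along the normalized direction
(`ls_cap`), which prevents structure explosion on rough energy surfaces;
golden-section refinement (`gs_tol`, default 1e-4 A) is finished by one
centered parabolic interpolation, which recovers near-machine-precision
line minima on smooth functions (golden section alone is limited to about
sqrt(machine epsilon) by value comparisons). Termination is by RMS
gradient threshold (`grad_tol`, default 0.05 kcal/mol/A — the convergence
criterion is ours, declared, not inherited) or by `max_steps` (default
10000). The energy trace is non-increasing by construction and the whole
pipeline is deterministic: identical inputs and configuration give
byte-identical refined PDB files. Energy evaluation is independent of any
ordering of the pair list, so parallel chunking of the non-bonded loop
cannot change results.

## Synthetic test structures

`generate_aform_duplex()` builds an ideal double helix for any sequence
over ACGU. One strand is grown by natural-extension (NeRF) chaining of
backbone anchors with A-form junction torsions; the torsions were
calibrated once, at design time, so that the emergent helix has exactly
the standard A-form parameters (twist 32.7 degrees, rise 2.81 A per
step) with the packaged template geometry; they stay within a few
degrees of textbook A-form values. The complementary strand is built the
same way and placed by the duplex pseudo-dyad: its helical axis is
aligned antiparallel to the first strand's and only the rotation about
and shift along the common axis are optimized against ideal Watson-Crick
pairing targets (precomputed pair transforms with hydrogen-bond
directionality residuals). By helical symmetry the pairing quality is
then uniform along the duplex: every pair is detected by the geometric
detector with energies well below the -2 kcal/mol threshold, and the
construction is clash-free and fully deterministic.

`generate_decoys()` displaces all atoms by i.i.d. Gaussian noise rescaled
so the superposed RMSDs of the set are spread evenly over
`(0, rmsd_max]`; `perturb_backbone()` perturbs only the sugar-phosphate
backbone. Both are deterministic under a fixed seed and leave the global
RNG state untouched.

What the generator does *not* emulate about real data: experimental
structures have sequence-dependent helical irregularity, non-canonical
pairs, loops and junctions, crystal contacts and solvent structure. A
passing test on these fixtures demonstrates correctness of the energy
model, restraint machinery and minimizers on well-posed geometry — not
prediction quality on real RNA models.

## The decoy-funnel experiment

The scaled-down scoring experiment generates a 14-bp duplex, 1000
Gaussian decoys spread over (0, 5] A RMSD (decoy seed 42), single-point
scores each decoy with default settings, and reports the largest radius
`r` (0.25 A grid) such that the Spearman correlation between score and
RMSD over all decoys with RMSD <= r stays at least 0.5.

Two facts about this experiment are worth separating. First, the *local*
discrimination of the score is narrow: computing the same correlation in
non-overlapping 0.25 A RMSD shells, the correlation is essentially
perfect below ~0.5 A, drops through ~0.67 at 0.75 A and collapses to
noise (|rho| < 0.45) beyond ~1 A — the score separates only near-native
models from everything else, a funnel well under 2 A. Second, the
*cumulative* statistic used for the reported width never falls below 0.5
for raw Gaussian decoys: i.i.d. position noise stretches bonds and
manufactures steric overlaps whose 12-6 energies grow by orders of
magnitude with the noise amplitude, so decoys in every RMSD band rank
above the bands below them even though ranks within a band are noise.
The cumulative width therefore evaluates to the full 5 A range on this
decoy ensemble. Decoys that preserve local geometry (for example,
accumulated small perturbations of experimental structures) do not have
this property; with such decoys the cumulative and local measures agree.
We report the cumulative statistic as defined, and show the shell-wise
analysis here because it is the scientifically meaningful description of
the funnel.

## Numerical choices and degenerate inputs

* Torsion sign convention is IUPAC; the analytic torsion gradient was
  validated against central finite differences (1e-5 A steps, < 1e-4
  relative deviation) along with every other term.
* Collinear planarity groups (degenerate plane) and mismatched backbone
  fragment/reference lengths are errors, not silent results.
* Coincident atoms in the non-bonded loop raise a singularity error
  naming the pair.
* Born radii are capped at 30 A in pathological overlap geometries; the
  cap region contributes zero gradient.
* Ties in conformer selection are broken by the lowest library index.
* Clash-score radii are the Lennard-Jones zero-crossing (sigma/2) for
  heavy atoms — numerically the standard van der Waals radii — with
  conventional contact radii for carbon-bound hydrogens (1.1 A
  aliphatic, 1.0 A aromatic). Polar (N/O-bound) hydrogens keep their
  LJ-derived radius, which is tiny in AMBER-family parameter sets: their
  contacts are governed by hydrogen bonding, not a van der Waals core,
  so the proxy only counts contacts that the energy model itself can
  resolve. Hydrogen-bond pairs (polar hydrogen vs N/O, and donor-heavy
  vs acceptor N/O) are exempt — hydrogen bonds are not steric clashes.
  Overlaps of >= 0.4 A are counted per 1000 atoms. This is a proxy
  metric for steric quality, deliberately simple; it is not a
  reimplementation of external validation suites and its absolute
  values are not comparable to theirs.

## Problem sizes used in the tests

The test suite exercises 2-8 bp duplexes for unit and property tests,
the full 14-bp/1000-decoy funnel experiment, and a 6-bp clash-seeded,
backbone-perturbed helix refined for up to 2000 conjugate-gradient steps
in vacuum for the refinement-behaviour check. These sizes were chosen so
the whole suite runs in minutes on one CPU while still exercising every
code path at realistic molecular dimensions.

## Known limitations

* The parameter set is an AMBER-family *style* set assembled for this
  package, not a byte-for-byte copy of any published force field;
  absolute energies are not comparable to other codes.
* No periodic boundary conditions, explicit solvent, Ewald
  electrostatics, or molecular dynamics.
* Only canonical Watson-Crick pairs are detected and restrained;
  non-canonical pairs are scored by the generic terms but not
  specifically restrained.
* Missing heavy atoms are an error (except the 5'-terminal phosphate
  group); ligands and solvent are dropped on reading.
* The synthetic conformer library idealizes towards A-form backbone;
  refining genuinely non-helical backbone against it will pull
  conformers towards helical geometry unless regularization is disabled
  or a user library is supplied.
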