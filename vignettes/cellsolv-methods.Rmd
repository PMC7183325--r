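---
title: "Methods: hydrogen bonding, lifetimes and dissolution statistics for cellulose-bundle trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen bonding, lifetimes and dissolution statistics for cellulose-bundle trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cellsolv post-processes all-atom trajectories of cellulose Iβ bundles in
tetrabutylphosphonium chloride (TBPCl)–water mixtures.  This vignette
documents the models and estimators, the parameters that matter, the
numerical choices, and what the synthetic-data layer does and does not
emulate.  Units throughout: Å, ps, kcal/mol, degrees, amu.

## Containers and conventions

A `topology` assigns every atom to exactly one strand glycan (cellulose)
or one solvent molecule (TBP, Cl⁻, water); glycans are numbered 1..g in
the same direction along every strand, and a strand of g glycans has
21·g + 3 atoms (21 per anhydroglucose residue plus the chain caps O1/HO1
and HO4).  Frames carry orthorhombic box edges; all distances use the
minimum-image convention.  Triclinic cells are not supported.  Readers and
writers cover PDB (topology and multi-model trajectories, via bio3d's
parser), XYZ, and the `ITEM: TIMESTEP`/`ITEM: ATOMS id type x y z` LAMMPS
text-dump dialect; DCD is deliberately out of scope.  LAMMPS step counters
convert to ps through an integration-step argument (`timestep_fs`,
default 2 fs, the conventional value).  PDB stores no bond records, so
bonds are reconstructed from the known chemistry of the recognised
residues; molecules that do not follow the builder's atom ordering get no
bonds and a warning.

## Hydrogen-bond model

A donor–hydrogen–acceptor triple is a bond when three geometric criteria
hold simultaneously:

* d(H⋯A) ≤ 2.45 Å,
* the angle at the donor between the D→H and D→A directions ≤ 30°,
* d(D⋯A) ≤ 3.5 Å.

The first two imply the third (the admissible maximum is
1.0 Å + 2.45 Å = 3.45 Å at a collinear geometry with a 1.0 Å D–H bond);
carrying the explicit D–A cutoff makes the criteria robust to longer D–H
bonds and is verified as a consistency property in the test suite.  The
angle convention (vertex at the donor) follows the A⋯H–D word order used
in the field; a `angle_vertex = "hydrogen"` switch measures
deviation-from-linearity at the hydrogen instead, since published work is
not always explicit about the convention.

Donor sets default to every oxygen carrying a covalently bonded hydrogen
(cellulose hydroxyls, chain caps, water); acceptors default to all
oxygens plus chloride.  C–H donors exist in the literature for
chloride–carbon contacts and are available behind `include_ch = TRUE`,
off by default for speed.  One hydrogen may bond several acceptors
simultaneously — chloride is known to hold multiple bonds at once — so no
exclusivity is imposed.  The neighbour search uses a cell list with cell
edge ≥ the distance cutoff; the test suite requires exact agreement with
an all-pairs brute-force oracle on randomised boxes, so the cell list is
purely an acceleration.

Classification partitions bonds into `intra_primary` (same strand and the
named pair O5⋯HO3–O3 or O6⋯HO2–O2 — the two bonds that stabilise each
glycosidic junction), `intra_other` (same strand, any other pair;
excluded from primary counts), `inter_strand`, the three solvent–strand
classes, and `solvent_solvent`.  Per-glycan averages over a time window
normalise `intra_primary` by g − 1 (the last glycan has no junction
partner; 11 for the 12-glycan bundle) and every other class by g.
Inter-strand bonds are credited to both participating strands, solvent
bonds to the cellulose strand; this matches per-strand bond counting in
visualisation tools, and is a convention, not physics.

Cross-section strand classes (corner, first layer, second layer,
above-corner, centre) are derived from the layout grid: boundary sites
missing an orthogonal neighbour form the outer shell, convex-hull
vertices of the site set are corners, and the eroded set splits into its
own boundary (second layer), corner-adjacent sites (above-corner,
adjacency including diagonals — on a rectangular grid nothing is
orthogonally adjacent to a corner through the interior) and centre.  When
the eroded set has no interior of its own the distinction collapses and
its sites are labelled centre (so a 3×3 cross-section yields 4 corner,
4 first-layer, 1 centre).  Small cross-sections can therefore leave some
classes empty; the 8×11 default for 88 strands populates all five.  The
layout and class map are plain data frames and can be overridden.

## Lifetimes

The existence autocorrelation of a bond class is estimated from binary
presence series (one per donor–hydrogen–acceptor triple).  In the default
continuous (survival) mode, C(t) is the probability that a bond present
at a time origin remains unbroken through t; every bonded sample point is
an origin, and multiple series pool numerators and denominators before
the ratio.  For alternating exponential (telegraph) kinetics this
estimator is unbiased at every lag, and pooling a class of bonds is what
gives it statistical power: its sampling error is governed by the
second-moment functional E[L²]/2E[L] of the sojourn lengths, roughly
2.2/√(number of sojourns) in relative terms, so single short series give
only coarse estimates.  Intermittent mode (re-formation allowed,
`⟨h(0)h(t)⟩/⟨h⟩`) is provided for comparison.

The lifetime is the trapezoidal integral of C(t) from zero to the first
point where C ≤ 10⁻³ (a numerical-zero tolerance, configurable, that
guards against floating-point tails); if C never reaches zero within the
window, the integral over the whole window is reported as a censored
lower bound and rendered with a `>` prefix.  Truncating a fixed C(t) to a
shorter window never lengthens the reported value — the monotonicity
property the tests check.  Note that the bound reported for a censored
series is the window integral, so comparing censored values across
different window lengths compares bounds, not lifetimes.

The multi-resolution cascade evaluates series sampled at 0.01, 0.1, 1 and
10 ps (windows 100, 1000, 10 000 ps and the full run) in order and
returns the first resolution whose autocorrelation decays to zero within
its window, recording which resolution was used; fast bonds are resolved
by the fine series, slow bonds fall through to the coarse ones, and bonds
that never decay are censored at the coarsest resolution.  Sample
averaging splits a run into 10 windows of 80 % of its length with evenly
spaced starts and reports mean and standard deviation, censored when any
window is.  Class averaging happens at the ACF level (ACFs are pooled
before integration), not by averaging per-bond lifetimes; the pooled
estimator is the one with a clean interpretation as a class survival
curve.

## Dissolution statistic

Glycan centres of mass are mass-weighted with coordinates unwrapped
within each glycan (atoms shifted to the image nearest the glycan's first
atom), so residues straddling the periodic boundary get a COM near the
boundary; strands are never unwrapped against each other.  For strand s
and glycan number j, NN(s, j) is the minimum over other strands s′ of the
minimum-image distance between COM(s, j) and COM(s′, j) — matching glycan
numbers only, which is what makes the statistic sensitive to a strand
peeling away rather than sliding along.  Ties take the lowest strand
index.  maxNN(j) = max over s profiles the furthest separation at each
position along the bundle.

The dissolution threshold is calibrated on a non-dissolving control
trajectory: maxNN(j) values are pooled over all glycan numbers and a list
of timepoints (all glycans, including strand ends), and the threshold is
the pool mean plus k standard deviations with k = 4 — far enough into
the tail that an undisturbed bundle essentially never crosses it.  On a
pool reconstructed from control statistics of mean 6.51 Å and σ 0.16 Å
this gives 7.15 Å; a reference value computed from unrounded statistics
can differ in the last digit (7.16 Å), which is a rounding artefact, not
a methodological difference.  A glycan is dissolved when NN(s, j)
strictly exceeds the threshold (a value exactly at the threshold is not
dissolved); the per-glycan decision uses NN rather than maxNN because the
dissolved mass must be attributable to specific glycans, while maxNN is
reported for separation profiles.  Dissolved counts convert to wt %
dissolved cellulose through the anhydroglucose residue mass
(162.14 amu) against the solvent masses of the composition, and an
ordinary least-squares fit of wt % against time gives the dissolution
rate in wt %/ns with a confidence interval.  Flags are recomputed per
frame and may go down as well as up — strands can partially re-form — so
monotonicity is only expected under monotone displacement schedules.

Composition arithmetic: mol % water = 100·n_water/(n_water + n_TBPCl),
and wt % dissolved = 100·m_dissolved/(m_dissolved + m_water + m_TBPCl).
The denominator is a sum of masses; a product of solvent masses would be
dimensionally wrong, so the sum is used even where source material prints
the expression ambiguously.  Species atom counts (53 per TBP = P + 16 C +
36 H, 1 per Cl, 3 per water, 21g + 3 per strand) reproduce the published
small- and large-bundle composition tables exactly, which the acceptance
tests assert row by row.

## Pairwise energies

Nonbonded energy between atom groups is the sum over unexcluded pairs
within a 20 Å minimum-image cutoff of 4ε[(σ/r)¹² − (σ/r)⁶] +
332.0636·q₁q₂/r, with Lorentz–Berthelot mixing.  Exclusions are bonded
paths of length ≤ 3 (1–2, 1–3, 1–4), built breadth-first from the bond
list.  The peeling-strand decomposition reports Cl, TBP and water terms
(each the full pair sum between that species' atoms and the strand — the
interpretation chosen for "proportionally attributed", since no
per-molecule partition is defined when a molecule spans the cutoff), the
rest-of-bundle term, and the strand's internal 1–5-or-further term.
Plain truncation is used at the cutoff: no switching, no Ewald/PPPM
long-range electrostatics and no long-range dispersion correction.  This
means absolute energies are not comparable to a mesh-Ewald re-run of a
real trajectory; the implementation is validated against internal
brute-force oracles (10⁻⁸ kcal/mol agreement), exact Newton-pair symmetry
(enforced by a canonical summation order), translation invariance and
linearity in charge, and force-field parameters come from a user file
(`name charge epsilon sigma` rows); `toy_ff_params()` ships
plausible-magnitude constants for the synthetic system only.

## Twist and presentation transforms

The glycosidic dihedral is measured, in order, over O5–C1–O4–C4 across
each junction (O5, C1, O4 of glycan j; C4 of glycan j + 1), IUPAC sign
convention, reported at the average glycan number j + 0.5.  Collinear
geometries raise an error rather than returning an arbitrary angle.  The
rolling average is a centred moving mean with truncated windows at the
series edges — chosen so traces start at t = 0 rather than half a window
in — followed by keeping every stride-th point (defaults 1000 and 100,
matching how long pairwise-energy and bond-count traces are usually
plotted).  It commutes with affine transformations of the series values,
which the tests exploit.

## The synthetic-data layer

The generators produce every input the estimators need, with controlled
ground truth:

* **Bundle builder.**  A schematic glycan template (21 atoms, standard
  naming) on a rigid lattice: glycan repeat 5.19 Å along the strand,
  strand spacing 5.0 Å both within and between sheets.  Hydroxyl
  hydrogens are aimed so the detector finds exactly two primary
  intra-strand bonds per junction and one O3⋯HO6–O6 inter-strand bond
  per glycan between sheet neighbours.  The isotropic 5.0 Å spacing is a
  deliberate simplification: with unequal spacings a strand losing its
  nearest neighbour "jumps" to the second spacing, which sits within
  thermal noise of a mean + 4σ threshold and confounds
  sensitivity/specificity testing of the dissolution statistic.  The
  template is **not** a crystal structure: a few bond lengths and
  non-bonded contacts are unphysical, ring puckering is absent, and
  lattice constants are chosen for estimator validation rather than
  crystallographic fidelity.
* **Solvent packing.**  Pseudo-TBP (tetrahedral P with four all-anti
  butyl arms; correct atom count and rough sterics only), chloride and
  rigid water are placed by rejection sampling (centres ≥ 3 Å apart, a
  bounded retry budget) and any molecule with an atom within 2 Å of
  cellulose is deleted — the insertion rule used when combining a
  pre-equilibrated solvent box with a solute.  This is geometric packing,
  not equilibration; densities are far below physical.
* **Peeling trajectories.**  Every atom receives isotropic Gaussian
  jitter of standard deviation σ per frame (uncorrelated in time and
  across atoms — adequate for exercising estimators, not a thermostat),
  and the planned strands translate along a displacement schedule, either
  rigidly or weighted linearly from 1 at the strand ends to 0 at the
  centre (ends peel first), plus an optional twist applied by rotating
  each junction's distal segment about the local C1→O4 axis, which
  changes exactly that junction's measured dihedral.  The applied
  per-glycan displacements are returned as ground truth.
* **Telegraph processes.**  Alternating exponential bound/unbound
  sojourns sampled on a regular grid, with the drawn sojourns returned —
  the ground truth for lifetime recovery.

Because the generators are kinematic and the solvent is sterically
placed rather than equilibrated, passing tests demonstrate that the
estimators recover planted truths under controlled conditions; they say
nothing about force-field accuracy, real solvent structure, or the
dynamics of actual dissolution, all of which require genuine MD input.

## Study conditions used in the validation suites

The acceptance suite runs at sizes chosen to exercise the reference
geometries while staying desk-sized: the full 18-strand × 12-glycan
bundle (4590 atoms) for bond-network and injection tests, with the
88 × 24 bundle (44 616 atoms) built for atom-count checks; 100 random
~20-molecule water boxes for each oracle-equivalence property; telegraph
ensembles of 20 series per resolution with per-series windows of at least
800·τ (≈ 16 000·τ total per resolution, where the estimator's ~2 %
sampling error makes the 10 % recovery band comfortable); and an
8–25-frame demo trajectory for end-to-end reproducibility.  Thermal noise
in injection tests is σ = 0.3 Å per atom per frame, the largest scale at
which the statistic is required to be error-free.

## Known limitations

* Orthorhombic boxes only; no velocities/forces; no DCD.
* Truncated electrostatics (no reciprocal-space solver) in the energy
  module; absolute energies are internally consistent, not
  literature-comparable.
* The builder's geometry is schematic (see above); analyses that depend
  on realistic ring conformations (e.g. puckering statistics) are out of
  scope.
* The bundle-level "percent twisting" summary sometimes quoted for
  cellulose bundles has no standard definition; only per-junction
  dihedrals are implemented.
* Lifetime estimates for bonds comparable to or slower than the analysis
  window are reported as censored bounds, and their values depend on the
  window; only the ">" flag is comparable across runs.
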