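# cellsolv

Trajectory analysis of cellulose Iβ microfibril dissolution in
ionic-liquid/water mixtures, written for computational chemists who
post-process all-atom simulations of cellulose bundles in
tetrabutylphosphonium chloride (TBPCl)–water solvents.

Dissolving cellulose is the bottleneck step in converting biomass to
biofuel.  In TBPCl–water, dissolution is a cooperative mechanism: chloride
anions break the hydrogen bonds holding a strand in the bundle, water delays
strand re-formation, and the bulky TBP⁺ cation wedges strands apart.
Quantifying that mechanism from a trajectory requires a specific analysis
stack, which this package implements end to end:

* **Hydrogen-bond detection and classification.**  A donor–H⋯acceptor
  triple (A⋯H–D notation) is a bond when d(H⋯A) ≤ 2.45 Å and the angle at
  the donor between D→H and D→A is ≤ 30°; these thresholds jointly imply
  d(D⋯A) ≤ 3.5 Å.  Bonds are classified as primary intra-strand
  (O5⋯HO3–O3 and O6⋯HO2–O2 across each glycosidic junction), inter-strand,
  or solvent–strand by species (Cl, TBP, water), and averaged per glycan by
  cross-section strand class (corner, first/second layer, centre).
* **Hydrogen-bond lifetimes.**  The lifetime τ of a bond class is the
  integral of its existence autocorrelation C(t) (continuous/survival mode
  by default) up to the point where C reaches zero, evaluated over a
  cascade of sampling resolutions (0.01, 0.1, 1, 10 ps with windows of
  100, 1000, 10 000 ps and the full run); a C(t) that never decays is
  reported censored, rendered `">31445"`-style.  Ten overlapping 80 %
  windows give a mean and spread.
* **Dissolution statistic.**  Per frame, the centre of mass (COM) of every
  glycan is computed; NN(s, j) is the minimum inter-strand distance between
  matching glycan numbers j, and maxNN(j) profiles strand separation.  The
  dissolution threshold is calibrated on a non-dissolving control as
  mean + 4σ of the pooled maxNN values; glycans beyond it count as
  dissolved, giving wt % dissolved cellulose over time and an OLS
  dissolution rate in wt %/ns.
* **Pairwise energy decomposition.**  Lennard-Jones + Coulomb sums
  (Lorentz–Berthelot mixing, 20 Å cutoffs, plain truncation) between a
  peeling strand and each solvent species, the rest of the bundle, and the
  strand's own 1–5-and-further interactions (1–2/1–3/1–4 pairs excluded).
* **Twist profiling.**  The O5–C1–O4–C4 glycosidic dihedral per junction,
  labelled at glycan number j + 0.5, plus the 1000-point rolling-average /
  every-100th-point presentation transform used for long traces.
* **Synthetic data with ground truth.**  An ideal Iβ-like bundle builder
  (18 × 12 and 88 × 24 geometries with the standard atom naming),
  pseudo-solvent packing with the 2 Å insertion-deletion rule, kinematic
  strand-peeling trajectories, and two-state bond telegraph processes —
  so every estimator can be validated against known answers.

## Worked example

```r
library(cellsolv)

## solvent composition bookkeeping for the densest mixture
mol_percent_water(2616, 1530)        # 63.06636 -> 63.1 mol % water
count_atoms(18, 12, 1530, 2616)
#> cellulose_atoms   solvent_atoms     total_atoms
#>            4590           90468           95058

## an ideal small bundle and its hydrogen-bond network
b <- build_ibeta_bundle(n_strands = 18, n_glycans = 12)
bonds <- classify_hbonds(detect_hbonds(b$frame, b$topology), b$topology)
table(bonds$class)[1:3]
#> intra_primary   intra_other  inter_strand
#>           396             0           180
sum(bonds$class == "intra_primary") / (18 * 11)
#> [1] 2          # exactly two primary intra-strand bonds per glycan

## dissolution threshold from control statistics (mean 6.51 A, sd 0.16 A)
raw <- rep(c(-1, 1), 50)
threshold_from_pool(6.51 + 0.16 * (raw - mean(raw)) / sd(raw), k = 4)
#> dissolution threshold: 7.15 A (mean 6.51 + 4 sd 0.160; pool max 6.67, n=100)

## lifetime of a synthetic bond with a known 5 ps mean bound time
tg <- lapply(1:20, function(r)
  generate_bond_telegraph(5, 5, duration = 4000, dt = 0.1, seed = r)$series)
res <- lifetime_from_acf(hbond_acf(do.call(rbind, tg), 0.1, "continuous"))
format_lifetime(res)
#> [1] "5.06"
```

The 396 primary bonds are 18 strands × 11 junctions × 2 bonds: the
"two per glycan is perfect" reference state of an undisturbed bundle.  The
7.15 Å threshold is the mean + 4σ separation beyond which a glycan counts
as dissolved.  The recovered 5.06 ps lifetime is within ~1 % of the
telegraph ground truth.

`make_demo(outdir)` builds a complete miniature study — bundle, solvent at
the 63.1 mol % composition ratio, a planted strand peel with thermal noise,
and a control — and `run_pipeline()` runs hydrogen-bond, dissolution and
twist stages over it, flagging the planted strand as dissolved.

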