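---
title: "Methods: SAXS characterization of flexible multi-domain proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAXS characterization of flexible multi-domain proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`flexsaxs` analyses one-dimensional small-angle X-ray scattering (SAXS)
curves `I(q)` from monodisperse solutions of flexible multi-domain
proteins — the motivating system is a full-length IgG antibody, whose two
Fab arms swing about hinges relative to the central Fc stem. At SAXS
resolution (tens of Angstrom) such a molecule is well described as three
quasi-rigid bodies connected by two hinges, and every structural model in
this package is a coarse bead model at that resolution: a set of point
scatterers with uniform scattering length. The package covers four layers:

1. **Reduction and invariants** — frame averaging with damage screening,
   buffer subtraction, concentration-series merging; Guinier fits,
   normalized Kratky curves, and the pair distance distribution `P(r)` by
   regularized indirect Fourier transform (IFT), with `Dmax` scanning.
2. **Shape reconstruction** — ab initio dummy-atom envelopes by simulated
   annealing, compared and pooled via the normalized spatial discrepancy
   (NSD), then averaged into a consensus envelope and voxelized.
3. **Envelope-restrained flexible fitting** — a density potential
   `V(r) = k (1 - rho(r)/rho_max)` drives a bead model into the envelope
   while an intra-domain elastic network preserves domain structure; the
   final model is the trajectory frame with the lowest reduced chi-square
   against the measured profile.
4. **Ensemble flexibility analysis** — a genetic algorithm selects the
   sub-ensemble of hinge conformers whose mean profile fits the data;
   flexibility is quantified by the entropy measure Rflex and the
   dispersion ratio Rsigma.

A synthetic-data module generates the whole study design — an
antibody-like surrogate with known coordinates, conformer pools with known
hinge distributions, noisy profiles, temperature and concentration
series — so every stage is testable against ground truth without any
external data.

# The synthetic surrogate and what it does (not) emulate

`build_antibody_surrogate()` constructs a Y-shaped molecule: three
ellipsoidal clouds of dummy scatterers (default 80 beads per domain,
semi-axes 30 x 18 x 14 Angstrom — the overall dimensions of Fab/Fc
fragments), joined by two 15 Angstrom hinges at the top of the stem with
the arms splayed 50 degrees from the vertical. Beads sit on a jittered
lattice, so a fixed seed reproduces coordinates bitwise. Conformers are
rigid (bend, twist) Euler rotations of each arm about its hinge pivot;
candidates with inter-domain bead contacts closer than one bead diameter
are rejected and resampled. The default hinge ranges (bend within 35
degrees, twist within 60 degrees) produce a conformer pool whose radius of
gyration brackets the template's — wide enough that ensemble selection is
a meaningful test, narrow enough that clash rejection stays rare.

The noise model is `sigma(q) = I(q) (floor + growth * q) / sqrt(counts)`
with defaults floor = 1%, growth = 0.05 per 1/Angstrom: the relative error
grows linearly with `q`, mimicking photon statistics on a decaying signal.
Thermal unfolding is emulated as a two-state mixture of the folded model
and an isotropically expanded copy (default linear expansion 1.6) with a
logistic melt curve (default width 2.5 degrees C); self-association as a
monomer/dimer mixture with a side-by-side clash-free dimer. These choices
reproduce the *observable* signatures the analysis layer consumes —
size-stability below the melt, simultaneous Rg/Dmax growth with
concentration — but not the physics behind them: no self-avoiding-walk
unfolded state, no inter-particle structure factor, no glycans, no atomic
detail. Tests passing on the surrogate therefore validate the analysis
machinery, not any claim about real antibody chemistry.

# Numerical choices in the invariant layer

**Guinier window.** The fit is a weighted linear regression of `ln I` on
`q^2`, iterated so the window is the widest satisfying
`q * Rg <= 1.3`. Two guards refine it. First, a low-q upturn (five leading
residuals all positive, mean above two sigma — the aggregation signature)
advances the window start. Second, the full 1.3 window carries a
systematic bias on sharply curved profiles: for an ideal sphere it
overestimates Rg by about 1.9%. The fit therefore shrinks the window while
a weighted `q^4` term is statistically significant (|t| > 3), which on
noise-free globular curves recovers Rg to a few tenths of a percent and on
noisy data (where the quartic term is not resolvable) leaves the
conventional window untouched. This mirrors how automated Guinier tools
choose their windows.

**Kratky identity.** The dimensionless Kratky curve `(qRg)^2 I/I0` of a
*Gaussian* (Guinier-limit) intensity peaks exactly at `qRg = sqrt(3)` with
height `3/e`. The exact sphere form factor peaks lower (`qRg` about 1.61,
height about 1.03) because the Guinier approximation has already lost
accuracy at the peak position. The test suite asserts the identity on the
Guinier-limit curve and only the qualitative ordering on real form
factors; multi-domain particles push the first peak above `sqrt(3)`.

**IFT.** `P(r)` is expanded in `sin(n pi r / Dmax)` so the boundary
conditions `P(0) = P(Dmax) = 0` hold by construction; the number of terms
defaults to the Shannon channel count `qmax Dmax / pi`. The objective is
the error-weighted chi-square plus `alpha` times the L1 norm of the
discrete second derivative of `P(r)` (plus an optional constant
background), minimized by iteratively reweighted least squares (80
iterations, relative tolerance 1e-9, a relative ridge of 1e-10 on the
normal equations for conditioning). The default `alpha` follows the
discrepancy principle: the largest value on an internal grid whose
chi-square stays within 10% of the best achievable. We initially used the
L-curve corner instead, but on realistically noisy synthetic profiles the
corner detector drifted to alphas with reduced chi-squares in the
hundreds and biased the derived Rg by several percent, while the
discrepancy rule tracks the ground-truth Rg to better than one percent
across the usable alpha range.

**Dmax scan.** Each candidate `Dmax` is scored by
`exp(-chi2_red/2) * (1 - negative-area fraction)`, maximized over alpha.
Long candidates plateau (the basis simply lets `P` decay early), so the
reported optimum is the *smallest* `Dmax` within 1% of the best score — a
parsimony tie-break. The suggested usable `qmax` is the largest `q` where
the smoothed `q I(q)` signal-to-noise stays above 2.

# Envelope reconstruction

The annealer flips bead occupancies on a hexagonal-close-packed lattice
(bead radius `Dmax/24`, so roughly 24 beads across the particle) inside
the `Dmax` sphere, scoring the scale-fitted reduced chi-square of the
bead-model Debye curve against the target — by default the P(r)-smoothed
intensity, as in standard dummy-atom practice — plus a looseness penalty
(mean fraction of empty neighbour sites, weight 2). Two deliberate
deviations from a textbook objective:

* **Fit range.** The chi-square is evaluated only for
  `q <= pi / (4 a)` (`a` = lattice spacing). Beyond that the lattice
  granularity dominates the residuals and the ranking inverts — a bead
  configuration matching the true shape can score *worse* than a compact
  blob. The cut keeps exactly the resolution band the lattice can
  represent.
* **Connectivity as a hard constraint.** Rather than a weighted
  disconnection penalty, growth moves only attach to the occupied surface
  and removal moves that would disconnect the model (checked by a local
  flood fill with early exit) are rejected outright. The final model is
  therefore always one connected component, and the annealing temperature
  never has to out-compete a connectivity weight.

The schedule cools geometrically (factor 0.8 over 28 levels from an
initial temperature of 5% of the starting objective, about twice the
lattice size in moves per level). Early stopping is off by default: on
multi-lobed targets all objective improvement happens in the cold phase,
and a patience rule keyed to best-so-far improvement would abort during
the hot exploration phase. Models are compared by NSD after rigid
alignment (principal-axes initialization over all four proper flips and
the enantiomer, refined by iterative closest point), clustered by average
linkage, and averaged on the reference member's lattice at an occupancy
threshold of 0.5. Voxelization deposits mass-normalized Gaussian kernels,
so widening the blur lowers peaks but conserves total mass.

# Restrained refinement

The density potential is applied per bead:
`V = k sum_i (1 - rho(r_i)/rho_max)`, with `rho` trilinearly interpolated
and the force the analytic gradient of the trilinear form (verified
against central finite differences to 1e-6 relative). `k` defaults to 0.1
in the package's reduced energy units; only the ratio of `k` to the
elastic-network spring constant matters for the dynamics. The network
restrains all intra-domain bead pairs within 12 Angstrom at their initial
distances — hinges stay free, domains stay rigid (the coarse-grained
stand-in for secondary-structure restraints; at bead resolution there are
no peptide geometry or chirality monitors to preserve, so domain rigidity
is the invariant we track instead). Integration is explicit
overdamped Euler; stability requires
`step_size * spring_k * mean pair degree` well below 2, and the defaults
(step 2, spring 0.03, degree about 12 at the default bead density) sit at
about a quarter of that bound while leaving equilibrium domain distortion
under half an Angstrom. Pure gradient descent (temperature 0) is the
default since final model selection is a deterministic argmin of
chi-square along the trajectory anyway; divergence (rising energy beyond a
patience, or non-finite forces) aborts with a step-size diagnostic. This
whole layer replaces all-atom restrained molecular dynamics — the major
simplification in the package — which is appropriate exactly because the
envelope potential acts on one interaction site per residue and SAXS
cannot discriminate finer detail.

# Ensemble selection and flexibility metrics

The genetic algorithm evolves multisets of pool members (default:
population 100, 200 generations, tournament of 5, uniform crossover,
mutation rate 0.1, single elitism — all seeded); fitness is the reduced
chi-square of the uniform-weighted mean member profile with a fitted
scale. Weights are multiplicities divided by the ensemble size. `Rflex` is
the normalized histogram entropy of a size distribution on 20 fixed bins
spanning the pool range (0% = one bin occupied, 100% = uniform); `Rsigma`
is the ratio of selected to pool standard deviation. Because near-duplicate
conformers are indistinguishable at the experimental noise level, recovery
experiments credit planted states by weight at the planted member and, in
the mixture experiment, average over independent noise realizations.

# Geometric descriptors

Domain labels follow the arm-distance rule (the arm farther from the stem
COM is `Fa`; ties break by chain order, with a message). Inertia planes
are spanned by the two largest-variance principal axes of the
mass-weighted gyration tensor; inter-plane angles are the acute angle
between normals. SASA uses the Shrake-Rupley construction with 960
golden-spiral points and a 1.4 Angstrom probe, validated against the
analytic isolated-sphere area. The Fab elbow angle extracts the
pseudo-two-fold axes as the rotation axes of the Kabsch superpositions
VL onto VH and CL onto CH1 and reports `180 - theta` (theta = angle
between the axes), pushed to the reflex branch `360 - (180 - theta)` when
the triple product `(u_V x u_C) . (COM_C - COM_V)` is negative. Parallel
dyads thus give the fully extended 180 degrees, and a dyad tilted by 37
degrees gives 143 — the convention of the standard crystallographic
tool. Superpositions with internal rotations under 5 degrees leave the
dyad undefined and fail loudly.

# Comparative statistics

Profile matrices stack `log I(q)` rows (profiles with non-positive
intensities in the window are excluded with a message); feature matrices
should be z-scored before PCA since they mix Angstrom, degrees and
squared-Angstrom units. PCA is an eigendecomposition via `prcomp` with a
fixed sign convention (largest-magnitude loading positive) so scores are
reproducible. Frame screening correlates *log* intensities against the
pointwise median frame (threshold 0.995): raw-intensity correlation is
blind to high-q shape changes because the low-q decades dominate.
Concentration-series merging fits the high/low intensity ratio on the
overlap window by error-weighted least squares and places the crossover
where the smoothed scaled discrepancy is smallest; the crossover can be
pinned manually.

# Problem sizes and determinism

The test suite and the acceptance script run the full workflow at desk
scale: 234-bead surrogates, 100-to-200-conformer pools, 4-to-6 envelope
replicas, 120-point profiles, 6000-step refinements — sizes chosen so the
round-trip accuracy targets (Rg within 1-2%, envelope NSD ordering,
mixture weights within 10 percentage points) are met with comfortable
margin while a complete run stays in the minutes range. Every stochastic
stage takes an explicit integer seed and restores the caller's RNG state;
identical seeds reproduce coordinates, envelopes, trajectories and
selections bitwise.

# Interfaces and limitations

The package's interface is its exported functions; the three workflow
drivers (`run_static()`, `run_flexibility()`, `run_comparison()`) accept
nested-list or YAML configurations with per-stage seeds. Density grids are
serialized in a plain-text format (`write_density_grid()`) rather than
binary MRC/CCP4. Known limitations: the Debye forward model has no
excluded-volume or hydration-shell term, so absolute chi-squares against
real beamline data will differ from tools that model the solvent; bead
models carry no sequence information; the elastic-network dynamics is a
relaxation scheme, not a thermodynamic sampler — its trajectory ordering
and endpoint matter, its timescale does not; and ambiguity scoring of
envelope reconstructions is out of scope.
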