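# flexsaxs

Small-angle X-ray scattering (SAXS) analysis for flexible multi-domain
proteins — the archetype being a full-length IgG antibody, whose two Fab
arms swing about hinges relative to the central Fc stem. Crystallography
and cryo-EM routinely fail on such molecules precisely because of that
flexibility; SAXS measures them in solution, but at low resolution, so
the information must be pulled out by careful invariant analysis and
model-based inference. `flexsaxs` implements that full workflow for
structural biologists and beamline users, end to end and reproducibly:

* **Reduction** — exposure-frame averaging with radiation-damage
  screening, buffer subtraction, merging of a concentration series on
  overlapping q-ranges.
* **Model-free invariants** — Guinier fits (`Rg`, `I0`), dimensionless
  Kratky curves, the pair distance distribution `P(r)` by regularized
  indirect Fourier transform in a sine basis
  (`chi^2 + alpha * |P''|_1`, constant background optional), and a
  `Dmax` likelihood scan.
* **Shape reconstruction** — ab initio dummy-atom envelopes by simulated
  annealing against the data, pairwise comparison by normalized spatial
  discrepancy (NSD), clustering, consensus averaging, voxelization.
* **Envelope-restrained flexible fitting** — the density potential
  `V(r) = k [1 - rho(r)/rho_max]` (default `k = 0.1`, applied per
  C-alpha-level bead) drives a model into the envelope under an
  intra-domain elastic network; the reported model is the trajectory
  frame with the lowest reduced chi-square against the measured profile.
* **Ensemble flexibility** — genetic-algorithm selection of the
  sub-ensemble of hinge conformers whose mean profile fits the data,
  quantified by `Rflex` (normalized histogram entropy of the size
  distribution: 0% rigid, 100% fully flexible) and `Rsigma`
  (selected/pool standard-deviation ratio).
* **Geometric descriptors and statistics** — domain centres of mass,
  distances and angles, inertia-plane angles, per-domain Rg and SASA,
  the Fab elbow angle from pseudo-two-fold axes, Kabsch RMSD, and
  PCA/hierarchical clustering of profile and feature matrices.

A first-class synthetic-data module generates an antibody-like
three-domain surrogate with known coordinates, conformational pools with
known hinge distributions, and noisy profiles — including temperature
series (thermal unfolding) and concentration series (self-association) —
so the entire pipeline is validated against ground truth.

## Worked example

```r
library(flexsaxs)

# ground-truth surrogate and a noisy measurement
truth   <- build_antibody_surrogate(surrogate_spec(seed = 1))
q       <- seq(0.008, 0.35, length.out = 120)
profile <- simulate_profile(truth, q, noise_spec(seed = 1))

# model-free invariants
g  <- guinier_fit(profile)
sc <- scan_dmax(profile, seq(70, 160, by = 10))
pr <- ift_pr(profile, Dmax = sc$optimal_dmax)

# flexibility: one conformation or an ensemble?
pool <- build_pool(truth, n = 100, q_grid = q, seed = 2)
sel  <- select_ensemble(pool, profile, ensemble_size = 5, seed = 3)
fx   <- flexibility_report(pool, sel)

cat(sprintf("true Rg        %.1f A\n", model_rg(truth)))
cat(sprintf("Guinier Rg     %.1f A  (qmax*Rg = %.2f)\n", g$Rg, g$qmax_Rg))
cat(sprintf("P(r) Rg        %.1f A,  Dmax %.0f A (true %.0f A)\n",
            pr$Rg, pr$Dmax, model_dmax(truth)))
cat(sprintf("P(r) peaks at  %s A\n",
            paste(round(pr_peaks(pr), 1), collapse = ", ")))
cat(sprintf("ensemble chi2  %.2f\n", sel$chi2))
cat(sprintf("Rflex          %.1f%% (pool %.1f%%),  Rsigma %.2f\n",
            fx$rflex_selected, fx$rflex_pool, fx$rsigma))
```

which prints:

```
true Rg        45.4 A
Guinier Rg     44.8 A  (qmax*Rg = 1.52)
P(r) Rg        45.5 A,  Dmax 130 A (true 127 A)
P(r) peaks at  18.9, 75.4 A
ensemble chi2  0.76
Rflex          22.5% (pool 92.4%),  Rsigma 0.31
```

Reading it: the Guinier and `P(r)` estimates of the radius of gyration
agree with each other and with the known model to about a percent, and
the scanned `Dmax` lands within a grid step of the true maximum
dimension. The two `P(r)` maxima are the intra-domain (~19 A) and
inter-domain (~75 A) distance peaks typical of a multi-domain particle.
Because this profile was simulated from a *single* conformation, the
selected ensemble collapses onto a narrow size distribution: `Rflex` far
below the pool's and `Rsigma` well under 1 — the signature of a rigid
sample. A genuinely flexible sample yields `Rflex` close to the pool
value and `Rsigma` near 1.

The three workflow drivers bundle these stages with YAML-configurable
parameters and mandatory seeds: `run_static()` (reduce, invariants,
envelopes, restrained fit, model selection), `run_flexibility()` (pool,
ensemble selection, Rflex/Rsigma), `run_comparison()` (per-condition
invariants, profile PCA, size-versus-concentration trends).

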