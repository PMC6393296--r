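# smcurtain

Quantification pipeline for double-tethered DNA curtain experiments, in
which fluorescently labeled DNA-repair complexes (the motivating system
is the yeast mismatch-repair endonuclease Mlh1–Pms1) are tracked as
they diffuse along naked or nucleosome-coated ~48.5 kb DNA molecules.
The package is aimed at single-molecule biophysicists who need the
standard analysis chain — spot localization, trajectory linking, MSD
diffusion analysis, nucleosome-bypass scoring, photobleaching
stoichiometry — plus the companion genetics readout (fluctuation-assay
mutation rates), with every stage reproducible and testable against a
built-in synthetic-data generator with known ground truth.

## What it computes

* **Localization/tracking** — 2D Gaussian fits of diffraction-limited
  spots in TIFF stacks (Levenberg–Marquardt, moment initialization,
  amplitude-significance gating), greedy nearest-neighbor linking with
  gap closing.
* **Diffusion** — per-molecule MSD over the first ten time intervals,

      MSD(nΔt) = 1/(N−n) · Σᵢ (yᵢ₊ₙ − yᵢ)²,

  fit to a line; in 1D, MSD = 2Dt, so **D = slope/2**, with the
  intercept as a localization-noise estimate. Mobility classification
  against the static noise floor 2σ², condition means ± SEM (flagged
  below 30 molecules), and two-sample Kolmogorov–Smirnov comparisons
  (α = 0.05).
* **Nucleosome bypass** — collisions are maximal excursions into a
  ±0.08 µm collision zone (three sd of the spatial resolution,
  ~300 bp) around each nucleosome; a collision whose entry and exit
  sides differ is a bypass. Binary codes get a percentile-bootstrap 95%
  CI; conditions are compared by logistic regression (Fisher's exact
  test under separation). `free_walk_bypass_reference()` measures the
  50% free-random-walk ceiling on unobstructed simulated trajectories.
* **Stoichiometry** — penalized change-point detection of bleaching
  steps, single-fluorophore calibration from single-step traces,
  molecules per punctum by intensity normalization, foci-per-DNA
  summaries, and RPA-footprint conversion of counts to ssDNA lengths.
* **Mutation rates** — the median-based fluctuation-assay estimator
  µ = f/ln(N·µ), solved to 10⁻¹² relative residual, with bootstrap CIs
  over cultures and paired-bootstrap fold changes between strains.
* **Synthetic data** — reflected Brownian motion with partially
  permeable obstacles, synthetic TIRF stacks, stepwise bleaching
  traces, and Luria–Delbrück cultures, all seed-deterministic.

## Worked example

Simulate fifty molecules diffusing past a partially permeable
nucleosome (microscopic pass probability 0.3 per attempted crossing),
then recover diffusion coefficients and bypass statistics:

```r
library(smcurtain)

cfg <- simulation_config(diffusion_coefficient = 1, frame_interval = 0.1,
                         n_frames = 2000, localization_sigma = 0,
                         obstacle_positions = 6.5, obstacle_bypass_prob = 0.3,
                         seed = 42)
sims <- simulate_ensemble(cfg, 50)

ests <- lapply(sims$trajectories, function(tr)
  fit_diffusion_coefficient(compute_msd(tr, n_max = 10)))
summarize_condition(ests, condition = "obstructed", noise_sigma = 0)
#> <condition_summary> obstructed: D = 0.8068 +- 0.01067 um^2/s (mean +- SEM), N = 50; mobile 50/50 (100%)

zones <- collision_zones(6.5, half_width = 0.08)
recs <- do.call(rbind, lapply(sims$trajectories, segment_collisions, zones = zones))
summarize_bypass(recs, seed = 42, condition = "nucleosome")
#> <bypass_summary> nucleosome: bypass 23.5% (241/1025 collisions), 95% CI [21.0, 26.2]%, 1 censored

free_walk_bypass_reference(n_trajectories = 50, seed = 42)
#> <bypass_summary> free_walk: bypass 48.6% (537/1104 collisions), 95% CI [45.9, 51.6]%, 1 censored
```

The fitted mean D (0.81 µm²/s) sits below the generating 1 µm²/s
because the obstacle and the reflecting tethered ends both restrict
long-lag displacements — see the vignette's discussion of confinement.
The nucleosome cuts bypass to 23.5% against the ~50% free-walk
ceiling; a logistic-regression comparison of the two summaries gives
p ≈ 3 × 10⁻³². A fluctuation assay closes the loop on the genetics
side:

```r
assay <- simulate_fluctuation_cultures(30, 1e8, mutation_rate = 1e-7, seed = 42)
estimate_rate(assay, seed = 42)
#> <rate_estimate> simulated: mu = 1.35e-07 [95% CI 1.1e-07, 1.56e-07] per cell per division (N = 30 cultures)
```

A thin command-line front end over the same functions lives at
`inst/cli/smcurtain.R` (subcommands `simulate`, `track`, `diffusion`,
`bypass`, `stoichiometry`, `flucrate`, `run`), and `run_pipeline()`
executes the simulate → track → diffusion → bypass chain with a JSON
run manifest.

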