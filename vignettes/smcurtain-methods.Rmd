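---
title: "Models and methods behind smcurtain"
author: "smcurtain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smcurtain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcurtain)
```

# The experiment being modeled

smcurtain quantifies double-tethered DNA curtain experiments: a ~48.5 kb
DNA is stretched between two anchor points over a passivated surface,
a quantum-dot-labeled DNA-repair complex (the motivating case is the
mismatch-repair endonuclease Mlh1–Pms1) slides along it by facilitated
1D diffusion, and a TIRF microscope records TIFF stacks at 50–100 ms
frame rates. Four quantities are extracted:

1. **1D diffusion coefficients** from mean-squared-displacement (MSD)
   analysis of tracked trajectories;
2. **nucleosome bypass probabilities** from collision-zone scoring of
   trajectories on nucleosome-coated DNA;
3. **fluorophore stoichiometry** of fluorescent puncta (e.g. RPA bound
   at ssDNA gaps) from photobleaching step counting;
4. **mutation rates** from Luria–Delbrück fluctuation assays, the
   genetic readout of mismatch-repair capacity.

Raw microscopy data are rarely portable, so the package ships a
synthetic-data generator that emulates each input with known ground
truth. Every estimator is therefore testable end to end, and the test
suite doubles as a statement of the conditions under which each
estimator is reliable.

# The synthetic-data generator

`simulate_trajectory()` draws reflected Brownian motion on
`[0, dna_length]`: per-frame displacements are N(0, 2·D·Δt), mirrored
at the tethered ends (reflection preserves the equilibrium occupancy of
the interval, the natural choice for a doubly tethered substrate).
Nucleosome obstacles are instantaneous Bernoulli barriers: a step whose
straight-line path crosses an obstacle succeeds with probability
`obstacle_bypass_prob`, otherwise the endpoint is mirrored back across
the obstacle onto the pre-step side. Every attempted crossing is logged
in the ground truth, so the microscopic pass probability is directly
auditable (a binomial test on the logged attempts is part of the test
suite). Localization error is added post hoc as i.i.d. Gaussian noise;
the default sd of 0.08/3 µm makes three standard deviations equal the
0.08 µm collision-zone half-width used downstream. Positions convert to
base pairs at 3750 bp/µm (0.08 µm ≈ 300 bp); since the end-to-end
extension of the curtain is not independently known, this calibration
is a config parameter, not a constant.

`simulate_image_stack()` renders each trajectory as a 2D Gaussian spot
(PSF sd 0.17 µm, pixel 0.1 µm by default) on a constant background with
Poisson (or Gaussian) noise. Trajectories are placed on parallel rows
1 µm apart, as DNA molecules are on a curtain; this matters for
testing, because spots on a shared row collide optically and no tracker
can resolve them — a limitation of the real assay as much as of the
simulation.

`simulate_bleach_trace()` gives each fluorophore a geometric bleaching
time (default 0.008/frame over 600 frames, so essentially every
fluorophore bleaches within the trace while near-simultaneous
two-fluorophore drops stay rare). `simulate_fluctuation_cultures()`
draws the number of mutation events per culture as Poisson(µ·N) and
assigns each event to a division with probability proportional to the
cells present, the clone doubling until harvest — the classic
Luria–Delbrück jackpot mechanism. A direct generation-by-generation
birth-process simulation is kept in the test suite as the brute-force
oracle for this shortcut.

**What the generator does not emulate:** heterogeneous photophysics
(quantum-dot blinking is off by default; a simple linear gap-bridging
flag exists), flow-stretched single-tethered geometry, drift, uneven
illumination, camera gain structure, ATP-state switching within a
trajectory, and post-plating phenotypic lag in the fluctuation assay.
Passing round-trip tests therefore certify the estimators, not the
microscope.

# Localization and tracking

Spot candidates are local maxima above median + k·MAD (default k = 5),
non-maximum-suppressed within one PSF width. Each candidate window
(radius 3 px) is fit with a 2D elliptical Gaussian plus constant
background by Levenberg–Marquardt, initialized from centroid moments. A
fit is kept only when the amplitude is at least three standard errors
above zero; windows without a significant spot report
`converged = FALSE` rather than disappearing silently. Because a
candidate on a bright spot's shoulder can converge onto the same spot,
fits closer than the suppression radius are deduplicated, keeping the
brighter. Linking is greedy nearest neighbor with per-frame jump limit
and gap closing (default 2 frames, bridged by linear interpolation so
trajectories stay uniformly sampled); ties break toward the lower
molecule id, making the tracker fully deterministic. The transverse
coordinate is carried along for QC but never enters the 1D analysis.

Localization accuracy is judged against the shot-noise-limited
Thompson–Larson–Webb precision (`localization_precision()`). The
round-trip requirement in the test suite — ≥95% of frames within 3×
the theoretical sd — holds at the default imaging parameters (peak
1000 photons, background 20, i.e. ~2000 integrated photons and a
theoretical sd of ~1.3 nm); least-squares fitting of Poisson data is
mildly super-Cramér-Rao, which the 3× margin absorbs.

# MSD and diffusion coefficients

For a trajectory of N positions, `compute_msd()` averages squared
displacements over all overlapping pairs at each of the first ten time
intervals, and `fit_diffusion_coefficient()` fits an unweighted
ordinary-least-squares line through the (lag, MSD) points. In 1D,
MSD = 2·D·t, so **D = slope/2**; this divisor choice rescales every
coefficient and is therefore stated prominently. The intercept absorbs
the static localization-noise offset 2σ² and is reported as a noise
estimate. The covariance between overlapping pairs is deliberately
ignored (unweighted OLS over a fixed ten-lag window is the field's
convention); the cost is a modest variance inflation, not bias, and the
estimator-consistency test (N = 100, 400, 1600 frames) bounds the
residual bias at under 5% for 1600-frame trajectories.

Two practical caveats are built into the defaults and tests:

* **Confinement.** On the 12.93 µm substrate a molecule with
  D = 1 µm²/s explores the full tether-to-tether span within seconds;
  reflecting ends then bend the MSD curve downward and the fitted slope
  underestimates D by ~10%. Estimator-recovery tests therefore use an
  effectively unconfined domain; users comparing fast molecules on
  short substrates should expect the same compression in real data.
* **Mobility calls.** A static molecule observed with noise σ has
  MSD = 2σ² at every lag. `classify_mobile()` calls a molecule mobile
  when the MSD at the largest fitted lag exceeds that floor threefold.
  The threefold factor is this package's choice: percent-moving figures
  are conventionally reported without a stated criterion, so the
  definition here is explicit and config-exposed. Condition means are
  flagged as non-reportable below 30 molecules.

Conditions are compared with the exact two-sample Kolmogorov–Smirnov
statistic and its asymptotic p-value at α = 0.05; the suite checks the
statistic against brute-force ECDF enumeration on all 21 945 pairs of
multisets of size ≤ 6 over {0, 1, 2, 3}.

# Collision-zone bypass scoring

A collision zone is the interval within ±0.08 µm (three sd of the
spatial resolution; ~300 bp) of a nucleosome's estimated position. One
maximal excursion of the sampled positions inside the zone is one
collision; the entry side comes from the last outside position before
entry, the exit side from the first outside position after exit, and a
collision is a bypass when the sides differ. Excursions truncated by
either trajectory end are censored: they count as encounters but never
enter the bypass denominator. Whether 0.08 µm is σ or 3σ of the
resolution is not decidable from the available description; the
half-width is config-exposed for exactly that reason. Overlapping zones
(dense arrays) are merged into compound zones, since sides are only
well defined for an isolated interval.

The pooled bypass probability is the bypass fraction of non-censored
collisions, with a 95% percentile bootstrap CI over the binary codes
(default 1000 resamples; resampling by molecule is available when
within-molecule correlation is a concern). Conditions are compared by
binomial-family logistic regression (Wald test, α = 0.05), falling back
to Fisher's exact test under complete separation.

## The 50% free-walk ceiling and the sampling-rate caveat

An unbiased 1D random walk steps forward or backward with probability
1/2, so 50% is the theoretical maximum bypass probability in the
absence of an obstacle. `free_walk_bypass_reference()` measures this
ceiling empirically by scoring unobstructed simulated trajectories at a
mid-DNA zone.

The classifier reads *sampled* positions, which makes the measured
fraction depend on the ratio of the per-frame rms displacement
√(2·D·Δt) to the zone width. When frames are fine relative to the zone,
the first sampled position inside the zone sits close to the entry
edge (its overshoot follows the ladder-height distribution of the step
process, with mean ≈ 0.58·√(2DΔt)), and by the gambler's-ruin argument
a walker starting near one edge of an interval mostly exits through
that edge: same-side exits are over-counted and the measured fraction
falls below the ceiling. At √(2DΔt) = 0.1 µm against the 0.16 µm zone
(e.g. D = 0.1 µm²/s at Δt = 0.05 s) the classifier reports ~41%. In the
coarse-sampling regime the entry position becomes nearly uniform across
the zone and the corrected gambler's-ruin probability integrates to
exactly 1/2; attenuation is under ~1% once √(2DΔt) ≳ 2.5× the zone
width. The reference defaults — D = 1 µm²/s, Δt = 0.1 s, rms step
0.45 µm — satisfy this condition while staying within the experiment's
frame-rate range and the plausible diffusion coefficients of an
ATP-bound sliding clamp; with 200 trajectories (~4000 collisions) the
reference reproduces 50% within its bootstrap CI.

The same geometry-dependent undercounting applies to *measured*
nucleosome bypass in real data: slow molecules measured at fast frame
rates will have their macroscopic bypass probability underestimated,
which is conservative for detecting barriers but matters when comparing
conditions whose diffusion coefficients differ. Comparisons in this
package are therefore always made at matched acquisition settings.

# Photobleaching stoichiometry

`detect_bleach_steps()` fits a piecewise-constant model by exact
penalized least-squares change-point detection (O(n²) optimal
partitioning — traces are short enough that no pruning is needed). The
per-changepoint penalty defaults to 8·σ²·log(n), with σ estimated from
the median absolute successive difference. Plain BIC (2·σ²·log n)
admits spurious changepoints inside long segments at the trace lengths
used here; the inflated multiplier was fixed once against the
generator's reference conditions (unit steps at SNR 5, 600-frame
traces) to give essentially zero false steps on flat noise-matched
traces while keeping ≥90% exact step recovery for up to three
fluorophores, and it is config-exposed.

Single-fluorophore intensity is calibrated as the mean step height over
traces showing exactly one downward step (at least five such traces
required). `count_molecules()` divides the pre-bleach plateau — median
of the first five frames, minus background; the median definition is
this package's, as the upstream measurement protocol is unstated — by
the unit intensity, reporting both the raw ratio (what condition-level
means such as "2.6 ± 1.2 per punctum" average) and the rounded count
(which feeds `ssdna_length_from_count()`: one RPA marks ~10–30 nt of
ssDNA, n ≥ 2 RPA mark between 10+30(n−1) and 30n nt, so three or more
RPA expose >60 nt). Plateau-based counting fails when a fluorophore
bleaches within the first ~3 frames; at the default bleaching rate this
affects a few percent of traces and is the main contributor to the
residual error budget of the round-trip battery (exact recovery ≥90%
for n ≤ 3, ≥85% pooled over n ∈ {1, 2, 3, 5}).

# Fluctuation-assay mutation rates

`solve_drake()` solves the median-based estimator µ = f/ln(N·µ) — with
f the median per-culture mutant frequency and N the cells per culture —
by bracketed root-finding plus Newton polishing to a relative residual
below 10⁻¹², on the branch N·µ > 1 (the branch N·µ < 1, where the
logarithm is negative, is spurious and never returned). N is the number
of viable cells at plating: the formula is only meaningful with that
reading. At f = e/N the solution is exactly µ = f, a fixed point the
tests assert to machine precision.

Two statistical properties deserve emphasis:

* **Bias.** The formula's implied median, µ·ln(N·µ), understates the
  Lea–Coulson median ≈ m(ln m + 1.24)/N of the Luria–Delbrück
  distribution, so the estimator runs ~20–35% high at m = µ·N ≈ 10.
  That is well within the order-of-magnitude scale on which fluctuation
  assays are interpreted (the simulation battery recovers µ₀ = 10⁻⁷
  within twofold), but it means the bootstrap CI — cultures resampled
  with replacement, the estimator re-solved per resample — covers the
  estimator's own population target at near-nominal rates while
  covering the true µ substantially less often. The CI quantifies
  sampling noise, not this structural bias.
* **Zeros.** An assay with no revertants anywhere is reported as
  below-detection with an upper bound from f = 1/N, not as a failure.
  Fold changes between strains pair bootstrap replicates index by
  index; when the denominator is below detection the fold is a lower
  bound.

Maximum-likelihood (Ma–Sandri–Sarkar) estimation and plating-efficiency
corrections are intentionally out of scope; the median estimator is the
method this pipeline standardizes.

# Numerical and reproducibility choices

* All randomness flows from explicit integer seeds; ensemble members
  get seeds derived deterministically from the master seed, so every
  simulation, bootstrap and pipeline run is bit-reproducible.
* Degenerate inputs are contracts, not crashes: negative MSD slopes
  report D = 0 with a flag, all-censored collision sets and all-zero
  assays raise named conditions, below-background plateaus count zero
  molecules with a flag.
* Linking ties break toward the lower molecule id; changepoint ties
  resolve toward fewer segments (penalty strictly positive).
* Image stacks round-trip through 32-bit float TIFF with a YAML sidecar
  carrying pixel size, frame interval and the intensity scale.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely from simulation,
at sizes chosen to keep each check statistically meaningful at desktop
scale: 200 trajectories × 2000 frames for the free-walk reference
(~4000 collisions), 100 molecules × 400 frames per diffusion condition,
100 seeded assays of 30 cultures for rate recovery, 50 traces per
stoichiometry battery arm, and 21 945 enumerated sample pairs for the
K–S oracle. Larger runs sharpen nothing qualitative; the estimators'
asymptotics are covered by the consistency tests.

# Known limitations

* The tracker is greedy nearest-neighbor: adequate for curtain-geometry
  data where molecules occupy distinct rows, inadequate for dense
  same-row traffic or frequent crossings (no global assignment, no
  motion model).
* Bypass scoring is resolution-limited by construction; microscopic
  bypass events shorter than the zone or faster than the frame rate are
  invisible, as discussed above.
* The mobility criterion, plateau definition and changepoint penalty
  are declared package choices where the field reports numbers without
  definitions; all three are config-exposed.
* Condition-level bypass comparisons assume collisions are independent;
  molecule-level bootstrap is offered but event-level coding is the
  default, matching the binary-regression convention.
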