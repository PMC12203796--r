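---
title: "v1phys: models, measurement definitions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{v1phys: models, measurement definitions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's methods account: what each stage computes,
the assumptions behind it, the tunable parameters with their units and
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices a maintainer would want written down. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Action-potential metrology

### Measurement definitions

* **Threshold**: the membrane potential at which dV/dt first reaches
  15.2 mV/ms on the upstroke. The extractor scans backward from the peak
  for the last sample whose central-difference dV/dt is below the
  criterion and interpolates voltage and time linearly at the crossing.
* **Amplitude**: threshold-to-peak. Reported thresholds near −44 mV with
  amplitudes near 65 mV imply peaks near +21 mV, and the rise/fall-time
  definitions ("threshold to amplitude", "amplitude to threshold") only
  cohere under this reading, so threshold-to-peak is the package's fixed
  convention.
* **Half-width**: time above the half-height (threshold + amplitude/2),
  with sub-sample linear interpolation at both crossings — at 50 kHz the
  half-width would otherwise be quantised to 0.02 ms.
* **Total rise/fall time**: threshold crossing → peak, and peak → first
  return to the threshold potential. A membrane that never returns to
  threshold within the analysed window yields a *missing* fall time while
  the cell still contributes its other features.
* **Max rates of rise/fall**: extrema of dV/dt between threshold and
  return-to-threshold, reported in mV/s (the field's tables print values
  like 227,203 unitless; ≈227 mV/ms is the physiological reading, so mV/s
  is assumed and documented).
* **Passive properties** (−50 pA sweep): R_in from the steady-state
  deflection averaged over the **last 25 % of the step** (the onset
  transient with τ ≤ ~40 ms has decayed to < 10⁻³ of its amplitude by
  then); τ from a single-exponential `nls` fit to the onset transient
  (`scaleOffset = 1` so noiseless traces with zero residual variance
  converge); capacitance ≡ τ/R_in; sag = |min − steady|; rebound =
  post-step max − baseline; rheobase = smallest step with ≥ 1 detected AP.
* **Detection** (`detect_aps`): upward crossing of the dV/dt criterion
  followed within 5 ms by a local maximum above a −10 mV peak floor, with
  a 2 ms refractory period. The peak floor, not the slope criterion, is
  what rejects noise: at 50 kHz, 0.5 mV white noise alone produces slope
  excursions beyond 15.2 mV/ms constantly, but never a peak near −10 mV.

### Open choices resolved

τ is fitted to the **onset** transient (the offset transient is equally
defensible; onset was chosen and is what the simulator reproduces). The
missing-fall-time rule is one plausible reading of why a published cohort
can have n = 23 fall times from 25 cells; no exclusion criterion is
available to copy.

## 2. The synthetic current-clamp world

Sub-rheobase sweeps are an RC membrane: V(t) = V₀ + IR(1 − e^(−t/τ)),
τ = RC. Defaults: 50 kHz sampling, 200 ms steps from −50 to 650 pA in
50 pA increments, holding −70 mV, R = 100 MΩ, C = 150 pF. Sweeps at and
above the configured rheobase depolarise toward a plateau capped 8 mV
below threshold and fire spliced AP templates: one more AP per 50 pA
above rheobase, 20 ms apart, as many as fit.

The AP template is piecewise analytic so that every extracted feature has
a closed form: exponential foot → **quadratic blend spanning the
threshold crossing** → second quadratic blend → linear rise → parabolic
peak → linear fall → exponential tail. The threshold-spanning blend is
the one non-obvious piece: dV/dt is *linear in t* through the crossing
(reaching exactly 15.2 mV/ms at exactly the configured threshold
voltage), which makes the central-difference derivative exact there. A
template with a slope kink at threshold — e.g. foot directly onto a fast
linear rise — biases the interpolated threshold by ~0.3 mV at 50 kHz,
which would make the ±0.1 mV recovery tolerance unattainable for reasons
that have nothing to do with the extractor. The blend parameters (±30 %
slope swing over ±0.06 ms, 0.1 ms acceleration blend) bound the template
family from below: half-widths need rise_fraction × half_width >
0.17 ms, comfortably met by physiological pyramidal-cell widths
(0.7–1.2 ms). The fall side (parabola → linear → exponential tail) gives
closed forms for the half-width (solved as a quadratic in the max fall
rate), fall time, and max fall rate.

Template geometry is verified in the tests against brute-force
measurement of the same waveform on a 10 MHz grid — the independent
oracle the closed forms are checked by.

Noise is white Gaussian per sample (default 0 in the config; the
command-line default run uses 0.3 mV). Real recordings are low-pass
filtered (6 kHz), so equal-σ white noise at 50 kHz is *harsher* on the
derivative-based rules than real noise of the same amplitude; green noise
tests are therefore conservative in that one respect. The generator does
not emulate: voltage sag/rebound dynamics (no h-current; extracted sag ≈
0 is itself a test), spike-frequency adaptation, channel kinetics, or
electrode artefacts.

## 3. Calcium imaging and the CSF pipeline

### Generator

Each cell's expected evoked amplitude is log-Gaussian SF tuning ×
Naka–Rushton contrast response:
r(sf, c) = r_max · exp(−log₂(sf/pref)² / (2·bw²)) · cⁿ/(cⁿ + c₅₀ⁿ).
The rate boxcar (3 s per stimulus) is convolved with a double-exponential
indicator kernel (rise 45 ms, decay 400 ms — typical fast GCaMP-class
values; the source protocol specifies none) normalised to unit integral,
so a sustained rate r plateaus at ΔF/F = r. Gaussian noise (default
σ = 0.05 ΔF/F) is added per frame. Defaults mirror the emulated design:
7 SFs (0.014…0.512 cpd) × 6 contrasts (100…3.4 %), 5 repeats, 3 s
stimulus + 3 s baseline at 9.6 Hz, 4 WT / 5 TS animals. `cells_per_animal`
defaults to a desk-scale 100 (the emulated study had ~800/animal); all
simulation-based tests state their sizes. Genotype enters through the SF
preference distribution (WT centred at 0.02 cpd, TS ~1.3 octaves higher,
σ = 1.5 octaves) and optionally through c₅₀. A configurable fraction of
cells (default 0.3) is nonresponsive (r_max = 0).

The SF grid reconciles a count/list discrepancy in the source protocol
(seven SFs stated, six listed) by appending 0.512 cpd, the only other SF
the text prints. The lowest contrast is 3.4 % (the methods value; a
figure caption says 3.2 %); both are configurable.

### Pipeline and the ground-truth contract

Evoked response = stimulus-window mean ΔF/F − immediately-preceding
baseline-window mean (frames 0-based, windows half-open). A
(cell, SF, contrast) triple is **responsive** iff an exact one-sided
sign-permutation test over the repeats gives p < 0.05 *and* the mean
evoked amplitude is ≥ 0.05 ΔF/F. Both knobs are configurable and logged;
the criterion is the package's own (the emulated study's criterion lives
in unavailable supplementary material). With 5 repeats the permutation
test is enumerated exactly (32 sign assignments, minimum attainable
p = 1/32); the amplitude floor therefore does most of the rejecting.

c_min at an SF is the smallest responsive grid contrast, **taken
literally** — a cell responsive at 100 % and 12.5 % but not 25 % gets
c_min = 12.5 % (no monotonic fill-in). Category = log₂(1/c_min), or NR.
A cell is visually responsive iff it responds to ≥ 1 of the 42 stimuli;
only such cells enter population summaries and the CLMM. Population CSFs
report the mean and IQR over non-NR cells plus the NR fraction — a mean
over an ordinal set that includes NR is undefined, and reporting the NR
fraction alongside loses nothing.

The generator's ground-truth category applies the *same two-part
criterion* to the noiseless trace, with its own independent window-mean
and permutation code. The permutation part is not redundant even without
noise: the indicator decay (400 ms) leaks ~13 % of the previous
stimulus's response into the next trial's 3 s baseline, so noiseless
evoked values vary across repeats (the presentation order differs per
block), and near-margin stimuli can pass the amplitude floor yet fail the
permutation test. Oracle equivalence (pipeline ≡ truth, exactly, on
noiseless cohorts) is the pipeline's core acceptance test.

ΔF/F conversion for raw-fluorescence input uses a rolling 10th-percentile
baseline over a trailing 30 s window (conventional; configurable); cells
with a non-positive baseline anywhere are dropped by name. The generator
emits ΔF/F directly. Not emulated: pixel-level imaging, segmentation,
neuropil contamination, slow drift, behavioural state — so a green CSF
suite establishes correctness of the trial algebra and classification
logic, not robustness to upstream imaging artefacts.

## 4. The cumulative link mixed model

P(Y ≤ k | u_a) = F(θ_k − x′β − u_a), u_a ~ N(0, σ_u²) per animal,
F = logistic (probit available). Fixed effects default to genotype × SF
with SF an **unordered factor** — per-SF genotype contrasts are the
target of inference, so a factorial parameterisation, not a continuous
SF trend, is wanted. NR enters as the lowest ordinal level so
nonresponding cells inform the model (a `drop_nr` toggle provides the
alternative). Random intercept per animal only; no random slopes, no
field-of-view nesting.

### Numerics

* Marginal likelihood per animal by **adaptive Gauss–Hermite quadrature**
  (default 15 nodes) centred on the conditional mode with curvature
  scaling; 1 node reduces to Laplace. The log-integrand is concave for
  both links, so the per-animal mode search is undamped Newton with step
  halving (tolerance 10⁻⁸).
* Nodes/weights by Golub–Welsch on the Hermite Jacobi matrix (base-R
  `eigen`), checked in the tests against closed-form Gaussian moments.
* Optimisation: BFGS on an unconstrained parameterisation — θ₁, log
  successive threshold increments (thresholds stay strictly ordered at
  every iterate by construction), β, log σ_u — started from a
  fixed-effects proportional-odds fit (`MASS::polr`), σ_u start 0.1.
  Gradients are forward differences computed in C++ against a cached
  base value; the fixed-effect covariance is a numerically differentiated
  Hessian (delta method for the contrasts).
* σ_u = 0 is handled exactly (no integration) and reproduces `polr` to
  10⁻⁴ — the dual-route check. On tiny instances the likelihood is
  checked against dense 1-d adaptive integration (substituting u = σz so
  a near-degenerate σ̂ cannot hide the integrand's needle) to 10⁻⁶.

Inference: analysis of deviance χ² = 2Δll between nested fits; Cox–Snell
pseudo-R² = 1 − exp((2/n)(ll₀ − ll₁)); per-SF genotype contrasts as
latent-scale linear-predictor differences with delta-method SEs, normal
Z, and BH correction across the SF levels tested. The emulated study's
corrected post-hoc p-values imply a step-up procedure over an unstated
family; BH over the tested SFs is this package's documented choice.

## 5. Group statistics and multiplicity

Two-sample comparisons pass each group through a Shapiro–Wilk gate
(α = 0.05): both normal → Welch t-test with mean ± SD summaries,
otherwise a Wilcoxon rank-sum test with median + IQR. Welch rather than
pooled variance is the default (safer under unequal spread; toggleable).
The rank test is rank-sum by default although the emulated analysis names
the signed-rank test for one variable — the genotype groups are
independent samples, so signed-rank (offered as an option) would need an
artificial pairing; the discrepancy is documented rather than copied.

Corrections: Bonferroni min(1, p·m) for the primary tier (m = 3);
Benjamini–Hochberg step-up for the secondary tier (family m = 12, padded
with p = 1 when fewer tests are supplied, so a partial re-analysis is
corrected as conservatively as the declared family). The proportions test
is the χ² test of equal proportions with continuity correction — the
conventional reading of "test of equal proportions" — with per-group
Wilson score intervals; exactly equal sample proportions return p = 1
directly (the χ² statistic is 0/0 when both proportions are 0 or 1).
PV⁺ density: one-way ANOVA on section-level densities (count/area) by
genotype — the emulated analysis — with an **advisory animal-level
re-analysis** (mean density per animal, Welch t) reported alongside,
because sections within an animal are pseudoreplicates. Summaries print
at 2 significant figures.

One spec-level expectation did not survive derivation: simulating groups
at the printed half-width summaries (0.978 ± 0.184, n = 25 vs
0.826 ± 0.243, n = 11) gives analytic Welch power ≈ 0.44 at α = 0.05, not
a majority; the test checks the empirical rejection rate against the
closed-form noncentral-t power instead of asserting a majority.

## 6. Exchange formats and reproducibility

All containers are plain text: matrices as CSV (doubles printed as
`%.17g`, so round trips are bit-exact) with a JSON sidecar for
attributes; tables as tidy CSV with a `# units:` comment line; configs as
YAML validated against the full default tree (unknown keys are errors);
every CLI run writes a manifest (version, resolved-config MD5, seed,
input checksums, outputs). Frame indices are 0-based with half-open
windows. An HDF5 container was considered and rejected: no R HDF5
binding is available in the supported environment, and the deliverable
must be text-only. ABF ingestion is delegated to a bundled Python
`pyabf` converter script and is exercised only through its error paths in
the tests, since binary fixtures cannot ship.

All randomness flows from explicit integer seeds; generators save and
restore the global RNG state, so library calls never perturb a caller's
stream.

## 7. Known limitations

* The CLMM's numeric-Hessian covariance is adequate at the package's
  design sizes (10²–10⁴ observations) but has no analytic-gradient
  fallback for ill-conditioned fits; complete separation is not
  penalised, only warned about through convergence diagnostics.
* The responsiveness criterion is the package's own; nothing here claims
  to reproduce the emulated study's (unpublished) detection procedure.
* Simulation-based acceptance checks run at stated desk scales (e.g.
  parameter recovery at 9 animals × 70 cells × 3 SF levels rather than
  300 cells/animal × 7 SFs); the scaled-down sizes are in the test code.
* The indicator kernel is deterministic and linear; saturation,
  spike-history nonlinearity, and deconvolution are out of scope.
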