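---
title: "Benchmarking forearm interfaces for proportional finger-force prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking forearm interfaces for proportional finger-force prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmibench)
```

## The problem

Dexterous hand prostheses expose several independently drivable degrees of
freedom (DOFs), but controlling them proportionally — predicting *how hard*
the user intends to press with each finger, not merely *which* grasp to
form — requires a human–machine interface (HMI) on the forearm whose signals
can be regressed onto fingertip forces. Three sensing modalities compete for
this role:

* **sEMG** — surface electromyography electrodes yielding amplified,
  rectified, smoothed muscle-activation envelopes (10 channels here);
* **FSR / force myography** — a bracelet of force-sensing resistors reading
  the pressure signature of the bulging forearm musculature (10 channels);
* **ultrasound imaging** — B-mode frames of the forearm cross-section,
  summarized by 543 local gray-level features.

`hmibench` implements the comparative benchmark: a stimulus protocol in
which a subject isolates one DOF at a time (little, ring, middle, index
flexion, thumb adduction, thumb flexion), at a high (80% of maximal
voluntary contraction, MVC) and a low (15% MVC) force level, five
repetitions per phase; decoders trained under a *realistic scenario*; and
two evaluation protocols — cross-validated accuracy and drift stability.
Because the original human-subject recordings were never deposited, the
package ships a synthetic-session generator with the statistical structure
the analysis assumes, so the full pipeline is exercisable (and testable)
end to end.

## Decoding model

All decoders are closed-form ridge regressions without intercept,

$$ W = (X^\top X + \lambda I)^{-1} X^\top Y, \qquad \lambda = 1, $$

fitted jointly for the six DOFs. For the ultrasound features a linear model
suffices; sEMG and FSR signals relate nonlinearly to force, so their inputs
are first lifted through **Random Fourier Features** (RFF),

$$ \phi(x) = \sqrt{2/D}\,\cos(\Omega x + b), \qquad
   \Omega_{ij} \sim \mathcal N(0, \sigma^{-2}),\;
   b_j \sim \mathcal U[0, 2\pi), $$

whose inner products approximate the radial-basis-function kernel
$k(x,x') = \exp(-\lVert x-x'\rVert^2 / 2\sigma^2)$ (that parametrization is
fixed throughout the package and in the bandwidth search). $D = 300$
features are used; the bandwidth $\sigma$ is chosen by grid search over a
median-heuristic grid (10 log-spaced values spanning 0.1–10 times the
median pairwise training distance; study runs default to a 5-point grid to
bound compute). The search is run once per subject, interface and
ground-truth mode on the phase's realistic training set and the chosen
$\sigma$ is reused across cross-validation folds; `grid_search_sigma()`
exposes fold-internal search for callers who want strict per-fold tuning.
`ridge_fit()` solves by Cholesky factorization and switches to the
mathematically identical dual form $W = X^\top (XX^\top + \lambda I)^{-1}Y$
when the feature dimension exceeds the sample count, so wide RFF expansions
stay cheap; `krr_rbf_oracle()` provides the exact kernel-ridge predictions
that the RFF model must converge to as $D \to \infty$, and the test suite
asserts that convergence.

## Preprocessing

Signals are acquired at 50 Hz. sEMG channels pass through a 1st-order
low-pass Butterworth filter at 1 Hz (envelope smoothing); FSR channels
through a 3rd-order high-pass Butterworth at 0.5 Hz, which removes their
slow additive baseline drift; ultrasound features are used as extracted.
Filtering is causal (forward-only, zero initial conditions) because the
intended deployment is real-time control — zero-phase forward–backward
filtering would be non-causal. Filter transients are not trimmed; instead
the realistic-scenario selector excludes ramp regions. One consequence
worth stating plainly: a 0.5 Hz high-pass also attenuates the
quasi-static plateau response itself, so the filtered FSR stream retains
mostly transient force information — its absolute accuracy is accordingly
modest in this simulation, while its *stability* across repetitions is
excellent, which is the property the stability analysis isolates.

The ultrasound feature extractor computes, at interest points on a
configurable lattice, the windowed local mean gray level and first-order
spatial gray-level differences. The default geometry — 181 points (a
14 × 13 lattice with the last point dropped) × 3 feature kinds — meets the
543-feature dimensionality contract exactly; the original extractor's
geometry is not recoverable from published material, so 543 is the only
quantity we pin.

## Evaluation protocols

**Realistic scenario.** Training uses only samples an amputee could
plausibly label: rest (stimulus exactly zero on all DOFs) and the central
80% of each activation plateau. Targets are either the measured forces or
the MVC-scaled stimulus; *testing is always against measured forces over
every sample of the held-out repetition*, ramps included.

**Accuracy.** Repetition-wise five-fold cross-validation: train on four
repetitions, test on the fifth, per subject and interface. The error
metric is nRMSE — RMSE divided by the per-DOF ground-truth range within
the test fold (the range convention is ours; only "range" is specified
upstream).

**Stability.** Train on repetition 1 only, test on repetitions 2–5
separately; summarize with the per-DOF ordinary-least-squares slope of
nRMSE against repetition index, averaged over DOFs. The low-force phase is
treated identically with its own five repetitions re-indexed 1–5. A
drifting signal (sEMG under fatigue/sweat/electrode shift) shows a positive
slope; a stationary or drift-corrected one (high-passed FSR) stays flat.

`compare_hmis()` runs two-tailed paired t-tests across subjects between
interfaces, per DOF; p-values are deliberately unadjusted for multiple
testing (mirroring common practice in this literature) and the output is
flagged accordingly.

## The synthetic cohort

The generator reproduces the *structure* the analysis relies on, not
forearm physiology:

* **Protocol**: trapezoidal activations, rest–ramp–plateau–ramp–rest =
  2/1/3/1/2 s (timing is unspecified upstream; these defaults make
  plateaus dominate and extreme-force selection unambiguous). One
  activation per DOF per repetition, exactly one DOF active at a time.
  All streams share the 50 Hz time base, ultrasound included — a single
  clock avoids resampling machinery irrelevant to the analysis.
* **Subjects**: per-DOF MVC drawn around a population mean of 22.6 N with
  2.1 N across-subject SD and 2 N per-DOF jitter; tracking of the visual
  stimulus modelled as a 0.15 s first-order lag plus 0.5 N tracking noise,
  clipped at zero.
* **sEMG**: channels couple to DOFs through a smooth non-negative
  ring-topology mixing matrix (each DOF excites a few neighbouring
  electrodes), a saturating `tanh` response, baseline 0.05, noise SD 0.03,
  and — the signature failure mode — a multiplicative gain ramp of
  0.002 s⁻¹ plus a 3 × 10⁻⁴ s⁻¹ additive offset ramp. Over a 270 s phase
  the gain grows by roughly half, a magnitude consistent with reports of
  substantial within-session sEMG non-stationarity; crucially, the 1 Hz
  low-pass cannot remove it.
* **FSR**: same coupling form with a Hill-type saturation, noise SD 0.02,
  and additive baseline drift (per-channel ramp ~0.002 units/s plus a slow
  random walk) whose spectrum lies below the 0.5 Hz high-pass corner, so
  the stated filter removes it — drift enters additively and leaves the
  force-locked component intact.
* **Ultrasound**: features are exactly linear in normalized forces through
  a dense seeded map plus offset and noise SD 0.02, encoding the working
  assumption that this modality is linearly decodable. A geometric frame
  phantom (`simulate_us_images()`: Gaussian blobs displaced affinely by
  force) feeds the real feature extractor for tests of that path.
* **Seeding** is hierarchical (master → subject → stream), so adding a
  stream never perturbs another stream's draws, and every generator is a
  pure function of (configuration, seed) — regenerate-and-compare is
  bit-exact.

What the generator does **not** emulate: raw unrectified sEMG, ultrasound
speckle physics, electrode lift-off artifacts, crosstalk between
simultaneously active DOFs (the protocol never activates two), or
inter-subject anatomical covariance. Passing benchmarks on this cohort
therefore demonstrates correctness of the *pipeline* and qualitative
reproduction of the drift phenomenology — not field performance on real
limbs.

## Numerical and design choices

* Ridge solves use Cholesky backsubstitution; an exactly/numerically
  singular system at $\lambda = 0$ raises an error rather than returning
  garbage (checked via reciprocal condition number below $10^{-12}$).
* Bandwidth-search ties break toward the larger (smoother) $\sigma$.
* nRMSE errors out on a zero target range instead of dividing by zero; a
  degenerate fold inside the bandwidth search falls back to unnormalized
  RMSE for scoring only.
* The Butterworth designs come from the bilinear transform; at 50 Hz the
  frequency warping is material above a few hertz, so analytic checks in
  the tests evaluate the first-order magnitude response at prewarped
  frequencies.
* Model serialization is plain JSON at 17 significant digits (lossless for
  doubles); sessions round-trip through per-stream CSVs plus a JSON
  sidecar to better than $10^{-12}$ relative.
* Study outputs (`run_study()`) are deterministic to the byte given the
  configuration and master seed; the run manifest lists every result file
  with its MD5 content hash.

## Problem sizes used in tests and the acceptance script

Unit tests run on shortened protocols (1 s segments) where only algebraic
identities are at stake, and on full default sessions (13 500 samples,
5 repetitions) for the study-condition properties. The stochastic
cohort-level properties (stability discrimination, null calibration of the
two-bracelet comparison) use 20 master seeds with one and four subjects per
seed respectively; the acceptance script runs a 3-subject cohort over both
phases. These sizes were chosen so the whole battery completes comfortably
on a laptop while keeping every statistical check at the protocol's native
session length.

## Known limitations

* The FSR high-pass destroys quasi-static force information by design
  fidelity to the stated preprocessing; absolute FSR accuracy here should
  not be read as the modality's ceiling.
* The stimulus-as-ground-truth condition inherits the generator's perfect
  stimulus/force alignment up to lag and noise; real subjects track
  stimuli with richer errors.
* The 543-feature extractor is a documented stand-in; only its
  dimensionality and locality properties are contractual.
* t-tests are unadjusted and assume per-subject means are exchangeable
  across paired conditions.
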