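# hmibench

Benchmarking forearm human–machine interfaces (HMIs) for **simultaneous,
proportional finger-force prediction** — the regression problem at the heart
of dexterous prosthetic hand control. The package compares three sensing
modalities on equal footing:

* **sEMG** — 10-channel surface-electromyography envelopes,
* **FSR** — 10-channel force-sensing-resistor pressure signatures
  (force myography),
* **ultrasound** — 543 local gray-level features of the forearm
  cross-section,

each decoding a 6-DOF fingertip-force ground truth (little/ring/middle/index
flexion, thumb adduction, thumb flexion). Because the original human-subject
recordings were never released, `hmibench` includes a seeded synthetic
session generator that reproduces the statistical structure the analysis
assumes — stimulus protocol, monotone saturating sensor responses, sEMG
gain drift, slow FSR baseline wander — so the complete analysis runs and is
testable end to end with no downloads.

## The method

Decoding is closed-form **ridge regression** without intercept,

```
W = (XᵀX + λI)⁻¹ XᵀY,   λ = 1,
```

linear on the ultrasound features and, for the nonlinear sEMG/FSR streams,
on a **Random Fourier Feature** expansion `φ(x) = √(2/D)·cos(Ωx + b)` with
`D = 300`, `Ω ~ N(0, σ⁻²)` approximating the RBF kernel
`exp(−‖x−x′‖²/2σ²)`; the bandwidth `σ` is grid-searched. Preprocessing at
50 Hz: causal 1st-order Butterworth low-pass at 1 Hz for sEMG, causal
3rd-order high-pass at 0.5 Hz for FSR (removes baseline drift).

Two evaluation protocols, both under the **realistic scenario** (training
only on rest and plateau samples — what an amputee could provide — with
either measured forces or the stimulus as training targets, always *tested
against measured forces* over full repetitions):

* **Accuracy** — repetition-wise 5-fold cross-validated nRMSE
  (RMSE / target range, per DOF);
* **Stability** — train on repetition 1, test on repetitions 2–5; the mean
  over DOFs of the least-squares slope of nRMSE vs repetition index
  measures drift-induced degradation.

## Worked example

```r
library(hmibench)

protocol <- make_protocol(force_level = 0.8)        # high-force phase
subject  <- sample_subject(seed = 42)               # MVC ~ 22.6 ± 2.1 N
session  <- simulate_session(protocol, subject, seed = 42)
session
#> <session_recording> subject 1, phase high: 13500 samples at 50 Hz; streams: semg, fsr, us_features

crossval_repetitionwise(session, "semg", gt = "force", seed = 1)
#> <evaluation_result> semg, gt = force, phase = high: mean nRMSE 0.048
#>     little       ring     middle      index  thumb_add thumb_flex
#>      0.049      0.047      0.044      0.048      0.051      0.047

stability_eval(session, "semg", seed = 1)
#> <stability_summary> semg, phase = high: slope 0.03636 nRMSE/repetition
stability_eval(session, "fsr", seed = 1)
#> <stability_summary> fsr, phase = high: slope -0.00007 nRMSE/repetition
```

Read: this subject's sEMG decodes forces to ~4.8% of the force range under
cross-validation, but when the model is frozen after repetition 1 its error
*grows* by ~0.036 nRMSE per repetition as the simulated gain drift (sweat,
electrode shift, fatigue) accumulates — while the high-pass-filtered FSR
stream, whose baseline drift the 0.5 Hz filter removes, stays flat
(slope ≈ 0). That accuracy-vs-stability trade-off is the benchmark's core
finding on synthetic cohorts.

A full multi-subject study (simulation → preprocessing → fitting →
evaluation → tidy CSVs + JSON summary + hashed manifest):

```r
report <- run_study(study_config(n_subjects = 10, master_seed = 1), out_dir = "study_out")
compare_hmis(report)   # paired two-tailed t-tests between HMIs, per DOF
```

A thin command-line front end with verbs `simulate`, `evaluate`, `study`
and `report` is installed at `inst/scripts/hmibench`.

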