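---
title: "Modelling depolarization-induced failure of excitation-contraction coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling depolarization-induced failure of excitation-contraction coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Elevating extracellular K⁺ depolarizes the skeletal-muscle resting potential
and, past a narrow voltage range, abolishes excitation-contraction coupling
(ECC). Two distinct links in the chain degrade: action potentials (APs) lose
peak amplitude and widen as Nav1.4 channels inactivate, and the Ca²⁺
transient that Cav1.1 gating charge triggers from the sarcoplasmic reticulum
(SR) collapses. `eccfail` analyses recordings of this process — AP sweeps at
10 kHz paired with ROI fluorescence frames at 30 frames/s, one stimulation
every 5 s during the infusion ramp — and ships a synthetic cohort generator
that reproduces the statistical structure of such recordings, so the whole
pipeline is exercised end-to-end without data files.

Two electrode layouts are modelled. In the **close** layout both electrodes
sit within 0.1 mm and a single ROI reports local Ca²⁺ release; this is the
protocol for the per-fiber voltage relationships. In the **far** layout the
stimulating and recording electrodes are separated by 1.6 mm (about three
passive length constants) with 20 ROIs spanning the distance; this is the
protocol for AP conduction analysis.

## The Boltzmann fits

Every voltage relationship is fitted with the two-asymptote sigmoid
`Out = LV + (HV − LV)/(1 + exp((V50 − V)/k))`. The three presets
(`boltzmann_preset()`) encode the constraints under which the relationships
are identifiable:

* `peak_vs_vrest` — the minimal AP peak (`HV`) is bounded to [−50, −30] mV.
  Runs end while the AP is still collapsing, so an unconstrained `HV` is
  poorly determined; the bound also means that fibers whose true asymptote
  lies below −50 mV are reported *at* the bound, which is expected behaviour
  and covered by tests.
* `dff_vs_vrest` — `LV` is fixed to 1 because the dF/F is normalized to its
  value at the −70 mV reference, and `HV` is bounded to [0, 0.1]; only
  stimulations depolarized beyond the reference enter this fit.
* `dff_vs_peak` — `LV = 0`, `HV = 1`: APs peaking very negative release
  nothing, very positive APs release the reference amount.

Fitting is ordinary least squares over the free parameters with box
constraints, via Levenberg-Marquardt (`minpack.lm::nls.lm`). Starting values
are data-driven (edge means for the asymptotes, the steepest finite
difference for `V50`, the 25–75% span over `ln 9` for `k`) and the solver is
restarted from a deterministic table of jittered initializations, keeping
the best residual sum of squares. Fits whose optimum runs away — `V50` more
than one data range outside the data, or a free `k` pinned at its ceiling —
are flagged `converged = FALSE` and excluded from cohort aggregates, rather
than silently reporting boundary parameters. Derived quantities are the
half-maximal output `(LV + HV)/2` and the 10–90% transition span
`k·ln 81`.

## AP features

* **Peak / amplitude**: maximum voltage outside the stimulus-artifact
  window (the window plus a 0.1 ms guard is excluded from every search;
  trace values are never modified).
* **Half-width**: time spent at or above `vrest + amplitude/2`, with linear
  interpolation at the crossings. The level is defined against the sweep's
  own resting potential; when the level is never reached the half-width is
  an explicit missing value, excluded from aggregates.
* **Area above −30 mV**: trapezoidal integral of `max(V + 30, 0)` with
  linearly interpolated sub-sample crossings — linear interpolation matches
  the trapezoid's integration order. The baseline of this integral is the
  cutoff, not the resting potential, so "APs at or below −30 mV have zero
  area" holds exactly.
* **Normalization**: peaks are zeroed at the cutoff and scaled by the
  within-run maximum (`max(peak − cutoff, 0)/(max_j peak_j − cutoff)`);
  areas are scaled by the within-run maximum. The within-run maximum (not
  the first stimulation) is used because potentiation places the maximum
  mid-run.

## dF/F extraction

Per ROI, `F0` is the mean fluorescence of the signal between stimuli — the
last 10 frames of the preceding capture block; the first stimulation uses
its own pre-response frame at t = 0 — and the series is `(F − F0)/F0`,
which cancels multiplicative illumination gradients exactly. The peak is
searched over the whole 48-frame block: with indicator kinetics calibrated
to a 44.3 ms time-to-peak, the best 30 Hz frame captures at least 96% of
the continuous peak, a small known underestimate. Negative dF/F values are
retained (they are noise), except that classification clips them at zero.

Two normalizations are computed per ROI: the run maximum, and the value of
the stimulation whose resting potential is nearest −70 mV (within a
configurable ±2 mV; the nearest-neighbour rule is our choice, the source
protocol does not specify how the reference sweep was selected).

The indicator impulse response is a rise-times-decay product
`g(t) = (1 − exp(−t/τ_on))·exp(−t/τ_off)` whose peak time has the closed
form `t_p = τ_on·ln((τ_on + τ_off)/τ_on)`. `calibrate_kinetics()` inverts
the pair (time-to-peak 44.3 ms, fraction 0.962 at 33 ms) with a bracketed
one-dimensional root search to 10⁻⁶ relative tolerance; an unattainable
pair (for example a fraction of 1, i.e. no finite peak) is an error.

## ECC classification and the conduction transition

A stimulation succeeds when the normalized dF/F of the ROI at the recording
electrode is at least 0.75, fails at or below 0.25, and is indeterminate in
between — both bounds inclusive toward the definite classes, because the
indeterminate band is defined as *between* 75% and 25%. Per fiber the
transition is the last success and the first fail after it; indeterminate
stimulations in between are skipped, and fibers that never reach a definite
fail are excluded from transition aggregates and reported separately. A
fail that recovers before the last success is logged as an anomaly.

Muscle-level aggregation is the unweighted mean of a muscle's fibers, then
mean ± SD across muscles, matching how the conduction experiments were
summarized (each muscle contributing 2–6 fibers).

## What the generator simulates

Each fiber draws ground truth from `fiber_prior()` in its own RNG
sub-stream (derived from the root seed so that enlarging a cohort never
perturbs existing fibers), and the truth table is written to a separate
file that no analysis stage reads.

* **Resting-potential ramp**: exponential approach
  `V(t) = V_end − (V_end − V_start)·exp(−t/τ)` with τ = 150 s over 240 s,
  traversing ≈ 28 of the 32 mV from −80 toward −48 mV. The slow tail
  matters: it samples the failure transition at ~0.3 mV per stimulation,
  the density at which the steep dF/F collapse is resolvable by the fits.
* **AP peak**: per-fiber Boltzmann in the resting potential, with
  `LV ~ U(15, 30)` mV, `HV ~ U(−58, −48)` mV (below the −50 mV fitting
  bound, so constrained fits pin there, and the fitted half-maximal peak
  lands near −14 mV), `V50 ~ N(−58.2, 3.3)` truncated to [−63, −57] — the
  cohorts emulate a study design that followed fibers *until ECC failed*,
  so fibers whose failure would fall outside the recorded ramp never enter
  a cohort — and `k ~ N(1.8, 0.6)` mV. Once the modelled peak falls below
  `vrest + 2` mV the response is the passive stimulus remnant.
* **Waveform**: a sigmoidal rise (τ ≈ 0.1 ms) times exponential decay,
  numerically rescaled so the sampled peak and the target half-width are
  met exactly (the decay constant is solved by bisection per sweep); a
  stimulus artifact occupies the injection window. Feature definitions are
  honoured by construction, so generator→extractor round trips are exact to
  stated tolerances.
* **AP widening and broadening**: the half-width grows linearly with
  depolarization (0.6%/mV default) and, crucially, gains a factor
  `((LV + 30)/(peak + 30))^1.1` (capped at 10×) as the AP decays — failing
  APs become long depolarized humps. This is what makes the AP *integral*
  above −30 mV fall far more slowly than the peak: normalized integrals
  remain ≈ 0.4–0.8 for peaks down to ≈ −21 mV, as the conduction
  experiments report, and it is the geometric reason the integral predicts
  Ca²⁺ release better than the peak does.
* **Ca²⁺ release**: a Hill function of the AP area (h = 1, half-saturation
  at 2.5× the baseline area) behind a soft saturation ceiling anchored at
  the baseline release level (sharpness p = 6): full-sized APs already
  nearly saturate SR release, so area gains above baseline add little
  dF/F, while area losses below ~70% of baseline register almost
  proportionally.
* **Potentiation**: a multiplicative release gain rises with mild
  depolarization (per-fiber gain `U(0.02, 0.15)` over 14 mV) and fades 60%
  over the next 8 mV (elevated resting Ca²⁺ followed by Ca²⁺-dependent
  inactivation). The rising phase of dF/F is deliberately *not* driven by
  the AP integral — the source observations are explicit that the integral
  does not correlate with the rise — which is why the dF/F-vs-area
  relationship is imperfect even without noise.
* **Conduction** (far mode): each fiber has a threshold
  `N(−21, 1.5)` mV on the near AP peak. Above it the AP reaches the far
  electrode with a small jitter; below it the far peak either drops
  suddenly by 30–60 mV (`all_or_none`) or declines at ≈ 3 mV per mV of
  near-peak shortfall (`continuous`); `mixed` flips a per-fiber coin.
  Release beyond the failure point decays with the 0.5 mm passive length
  constant. ROIs within 0.25 mm of the stimulating electrode retain
  near-baseline release while the fiber is still locally excitable,
  emulating the sustained local depolarization of the injected current —
  this keeps the near ROI near its reference value at the moment conduction
  fails, as observed. The stimulus-zone floor is not applied in close mode,
  where the analysis ROI sits away from the pipette.
* **Noise**: voltage noise 0.05 mV; half-width jitter 12% per stimulation;
  dF/F measurement noise 0.08 (units of the fiber's baseline dF/F); a slow
  AR(1) drift of the release gain (stationary SD 0.08, lag-1 correlation
  0.9) standing in for slow fluctuations of SR load and resting Ca²⁺; frame
  shot noise 0.5% of F0. An optional dropout mechanism (stimulations that
  partially fail to activate under strong depolarization) ships disabled.
* **Long-pulse probe**: with `long_pulse = TRUE` each run ends with a 5 ms
  command pulse to +10…+35 mV after ECC failure; its release is the
  SR-availability fraction (default 0.92) of the fiber's −70 mV reference
  response, emulating the finding that release inactivation is modest at
  failure.

### What the generator does not emulate

No conductance-based membrane model: AP shapes are phenomenological
templates with controlled features, so tests exercise the *analysis*, not
channel biophysics. No t-tubule cable structure, no raw camera frames (ROI
traces only), no bleaching or movement artifacts, no BTS pharmacology or
force transduction. Passing tests therefore demonstrate that the pipeline
recovers known structure from data with realistic statistics — not that the
generator is a substitute for recordings.

## Interpretation choices worth knowing

* **Identity-line R²**: the per-fiber comparison of normalized dF/F against
  normalized AP area and peak is summarized by default as R² against the
  line of identity (`identity_r2()`), i.e. the fraction of dF/F variance
  explained by the model *dF/F = normalized predictor*. That is the
  comparison the normalized plots draw, and it is what separates area from
  peak: the area tracks the identity line closely, while dF/F stays high as
  the normalized peak falls, bowing far off it. The squared Pearson
  correlation (`linear_r2()`, `method = "ols"`) is available and is used
  for all other statistics.
* **Geometry of the area above a cutoff**: even with widening disabled, the
  area above −30 mV *rises* during early depolarization, because lifting
  the resting potential toward the cutoff lengthens the supra-cutoff
  segment at constant half-width. Monotonicity of area against peak
  therefore only holds through the declining phase, which is how the
  corresponding property test is framed.
* **Normalized-peak convention**: the source wording ("peaks at or below
  −30 mV set to 0, amplitude normalized") is ambiguous between
  `(peak − cutoff)/(max peak − cutoff)` and a raw-amplitude rule; the
  former is implemented (it makes the zeroing exact) and is configurable
  through the cutoff argument.
* **dF/F-vs-vrest fit window**: stimulations with resting potential at or
  depolarized beyond the −70 mV reference enter the fit; potentiated points
  above the reference value are retained (with `LV` fixed at 1 they add
  constant residuals and do not move the transition).

## Problem sizes and runtime

The standard analyses use cohorts of 12 fibers in 6 muscles
(close-electrode, 49 stimulations per fiber) and 8 muscles of 2–6 fibers
(far-electrode); a full close cohort generates and analyses in a few
seconds, and the complete test suite — including a 50-replicate check that
the area-based R² dominates the peak-based one — runs in about three
minutes on one CPU. `scripts/acceptance.R` regenerates both cohorts from a
single seed and reports the cohort-level quantities as JSON.

## Known limitations

* The generator's release model is calibrated at the cohort level; single
  synthetic fibers are not meant to be compared against single real fibers.
* The constrained `dff_vs_vrest` slope factor is estimated from the ~3–5
  stimulations that fall inside the steep collapse; with noisier data or a
  faster ramp its estimate inflates. The runaway-fit guard catches the
  degenerate cases but cannot repair sparse sampling.
* Far-electrode classification assumes one transition per run (monotone
  ramp). Protocols with recovery phases would need the anomaly log rather
  than the transition table.
* The 0.2 ms stimulus artifact is modelled as a clean rectangle; real
  capacitive transients with ringing would need a wider guard.
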