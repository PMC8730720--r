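# eccfail

Simulation and analysis of depolarization-induced failure of
excitation-contraction coupling (ECC) in skeletal muscle fibers.

When extracellular K⁺ rises, the muscle resting potential depolarizes and,
over a window of only a few millivolts, excitation stops producing force.
The chain breaks in two measurable places: action potentials (APs) shrink
and widen as Na⁺ channels inactivate, and the Ca²⁺ transient that APs
trigger from the sarcoplasmic reticulum collapses. `eccfail` implements the
quantitative analysis of this failure mode for experiments that pair sharp-
electrode AP recordings (10 kHz) with Ca²⁺-indicator imaging (20 ROIs along
the fiber, 48 frames at 30 frames/s per stimulation, one stimulation every
5 s during a high-K⁺ infusion ramp), together with a fully seeded synthetic
cohort generator so that every stage of the pipeline is testable without any
recordings.

## The model at the core

All three voltage relationships are described by a two-asymptote Boltzmann
sigmoid

    Out = LV + (HV − LV) / (1 + exp((V50 − V) / k))

where `LV` and `HV` are the limiting values at very negative and very
positive `V`, `V50` the half-maximal voltage and `k` the slope factor (mV).
Three constrained presets are provided:

| preset | Out | V | constraints |
|---|---|---|---|
| `peak_vs_vrest` | AP peak (mV) | resting potential | `HV` ∈ [−50, −30] mV |
| `dff_vs_vrest` | normalized ΔF/F | resting potential | `LV` = 1, `HV` ∈ [0, 0.1] |
| `dff_vs_peak` | normalized ΔF/F | AP peak | `LV` = 0, `HV` = 1 |

Around the fits, the package extracts the AP features that matter for ECC —
peak, amplitude, half-width, and the integral of voltage above a −30 mV
cutoff (APs peaking below −30 mV release no Ca²⁺, so their area is exactly
0) — computes per-ROI ΔF/F with background taken from the signal between
stimuli, applies both normalization conventions (run maximum; the value at
the −70 mV reference), classifies ECC success (normalized far-ROI ΔF/F
≥ 0.75), indeterminate, or failure (≤ 0.25) along the fiber, and summarizes
each fiber's conduction transition.

## Worked example

```r
library(eccfail)

cfg <- cohort_config(n_muscles = 6, fibers_per_muscle = 2, seed = 1,
                     protocol = protocol_config("close"))
cohort <- make_cohort(cfg)
cohort
#> Synthetic ECC cohort: 6 muscles, 12 fibers, 588 stimulations, close mode
#>   seed 1; ramp -80 -> -48 mV over 240 s; 1 ROI(s)

feats <- extract_ap_features(cohort$sweeps, cohort$metadata)
dff   <- extract_calcium_features(cohort$calcium, cohort$metadata)
fits  <- fit_cohort(feats, dff)

attr(fits, "fits")[["m01_f01.peak_vs_vrest"]]
#> Boltzmann fit (peak_vs_vrest), n = 49, converged
#>   LV = 16.29, HV = -50, V50 = -58.5, k = 2.692
#>   rss = 1.786, half-max output = -16.85, 10-90 span = 11.83 mV

aggregate_cohort(subset(as.data.frame(fits),
                        relationship == "peak_vs_vrest" & converged),
                 c("V50", "k", "half_max_output"), level = "fiber")
#>          quantity level       mean        sd n_groups          label
#> 1             V50 fiber -58.903648 2.2505079       12 -58.9 +/- 2.25
#> 2               k fiber   1.451809 0.5322473       12 1.45 +/- 0.532
#> 3 half_max_output fiber -14.334146 2.2501726       12 -14.3 +/- 2.25

r2 <- correlate_cohort(feats, dff)
sprintf("mean R2: area %.2f, peak %.2f", mean(r2$r2_area), mean(r2$r2_peak))
#> [1] "mean R2: area 0.88, peak 0.68"
```

Reading the numbers: for this seeded cohort the AP peak is half-maximal at
a resting potential of −58.9 ± 2.3 mV with slope factor 1.45 ± 0.53 mV, and
the half-maximal AP peak itself is −14.3 mV — the fiber still fires APs well
after it has lost most of its Ca²⁺ release, because the ΔF/F collapse
(slope factor ≈ 0.4 mV in resting potential) is an order of magnitude
steeper than the AP decline. The ΔF/F tracks the AP integral above −30 mV
(identity-line R² 0.88) much more closely than it tracks the AP peak
(0.68): the widening of decaying APs buys Ca²⁺ release that the peak alone
does not predict.

For the conduction experiment, generate a far-electrode cohort and classify:

```r
far <- make_cohort(cohort_config(8, c(2, 6), seed = 2,
                                 protocol = protocol_config("far"),
                                 conduction_mode = "mixed"))
cls <- classify_cohort(extract_calcium_features(far$calcium, far$metadata),
                       far$metadata,
                       features = extract_ap_features(far$sweeps, far$metadata))
aggregate_cohort(cls$transitions, "d_vrest", level = "muscle")
```

`run_ecc_pipeline(out_dir, config)` orchestrates all stages as a file-based,
resumable pipeline (CSV/JSON artifacts, checksum manifest, deterministic
under a fixed seed).

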