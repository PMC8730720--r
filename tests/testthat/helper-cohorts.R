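# Shared fixtures: cohorts are generated once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Default close-electrode study cohort (12 fibers / 6 muscles) plus its
# analysis products; the configuration the voltage-relationship results use.
close_run <- function(seed = 1L) {
  cached(paste0("close", seed), {
    cfg <- cohort_config(n_muscles = 6, fibers_per_muscle = 2, seed = seed,
                         protocol = protocol_config("close"))
    co <- make_cohort(cfg)
    feats <- extract_ap_features(co$sweeps, co$metadata)
    dff <- extract_calcium_features(co$calcium, co$metadata)
    fits <- fit_cohort(feats, dff)
    list(cohort = co, features = feats, dff = dff, fits = fits)
  })
}

# Far-electrode conduction cohort (8 muscles, 2-6 fibers each).
far_run <- function(seed = 1001L) {
  cached(paste0("far", seed), {
    cfg <- cohort_config(n_muscles = 8, fibers_per_muscle = c(2, 6), seed = seed,
                         protocol = protocol_config("far"),
                         conduction_mode = "mixed")
    co <- make_cohort(cfg)
    feats <- extract_ap_features(co$sweeps, co$metadata)
    dff <- extract_calcium_features(co$calcium, co$metadata)
    cls <- classify_cohort(dff, co$metadata, features = feats)
    list(cohort = co, features = feats, dff = dff, classes = cls)
  })
}

# Noise-free configuration helpers.
no_noise <- function() {
  noise_config(vm_sd_mV = 0, vrest_jitter_mV = 0, width_jitter_frac = 0,
               dff_sd = 0, dff_drift_sd = 0, frame_shot_frac = 0,
               far_peak_jitter_mV = 0)
}

# A minimal fiber-truth list for direct release/calcium synthesis tests.
toy_fiber <- function(q50 = 50, hill = 1, knee = 0, dff_scale = 1,
                      F0_base = 1000) {
  list(release_q50 = q50, release_hill = hill, release_knee_p = knee,
       release_sat_base = NULL, release_norm = 1,
       dff_scale = dff_scale, F0_base = F0_base)
}

# Triangle AP used by several worked examples: rises -80 -> +20 mV in
# 0.5 ms, falls back to -80 mV in 2 ms.
triangle_sweep <- function(dt = 0.1) {
  t_up <- seq(0, 0.5, by = dt)
  t_dn <- seq(0.5 + dt, 2.5, by = dt)
  v <- c(-80 + 200 * t_up, 20 - 50 * (t_dn - 0.5))
  ap_sweep(c(t_up, t_dn), v, vrest = -80)
}
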