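test_that("cohort bookkeeping matches the protocol arithmetic", {
  proto <- protocol_config("close", ramp_duration_s = 10, sweep_duration_ms = 20)
  cfg <- cohort_config(1, 1, 5, proto)
  co <- make_cohort(cfg)
  n_samples <- proto$sweep_duration_ms * proto$ap_sample_rate_per_ms + 1
  expect_equal(nrow(co$metadata), 3) # 10 s / 5 s + 1 stimulations
  expect_equal(nrow(co$sweeps), 3 * n_samples)
  expect_equal(nrow(co$calcium), 3 * proto$frames_per_stim * proto$n_rois)
  expect_equal(nrow(co$truth), 1)

  # default protocol: 240 s ramp, one stimulation every 5 s -> 49 per fiber
  co2 <- make_cohort(cohort_config(1, 1, 5, protocol_config("close")))
  expect_equal(nrow(co2$metadata), 49)
})

test_that("generation is deterministic and writes byte-identical files", {
  cfg <- cohort_config(1, 2, 17, protocol_config("close", ramp_duration_s = 20,
                                                 sweep_duration_ms = 20))
  c1 <- make_cohort(cfg)
  c2 <- make_cohort(cfg)
  expect_identical(c1$sweeps, c2$sweeps)
  expect_identical(c1$calcium, c2$calcium)
  expect_identical(c1$truth, c2$truth)

  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(c1, d1, overwrite = TRUE)
  write_cohort(c2, d2, overwrite = TRUE)
  for (f in c("sweeps.csv", "calcium.csv", "metadata.csv", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("adding fibers never perturbs existing fibers' data", {
  proto <- protocol_config("close", ramp_duration_s = 20, sweep_duration_ms = 20)
  small <- make_cohort(cohort_config(1, 1, 99, proto))
  big <- make_cohort(cohort_config(1, 3, 99, proto))
  f1 <- small$sweeps$fiber_id[1]
  expect_identical(small$sweeps[small$sweeps$fiber_id == f1, ],
                   big$sweeps[big$sweeps$fiber_id == f1, ])
})

test_that("the AP peak model is a monotone Boltzmann with guarded parameters", {
  fiber <- list(LV = 30, HV = -40, V50 = -58.2, k = 1.8)
  expect_equal(ap_peak_model(-58.2, fiber), -5)
  expect_equal(ap_peak_model(-1e5, fiber), 30)
  expect_equal(ap_peak_model(-50, fiber),
               30 + (-40 - 30) / (1 + exp((-58.2 + 50) / 1.8)), tolerance = 1e-12)
  v <- seq(-90, -40, by = 0.5)
  expect_true(all(diff(ap_peak_model(v, fiber)) <= 0))
  expect_error(ap_peak_model(-60, list(LV = 30, HV = -40, V50 = -58, k = 0)),
               "positive")
  expect_error(ap_peak_model(-60, list(LV = -50, HV = -40, V50 = -58, k = 1)),
               "LV > HV")
})

test_that("synthesized sweeps hit the requested peak, width and baseline", {
  proto <- protocol_config("close")
  fiber <- list(LV = 25, HV = -53, V50 = -58.2, k = 1.8, width0_ms = 1.4,
                width_growth_per_mV = 0, width_broadening_beta = 0,
                width_broadening_max = 1)
  sw <- synthesize_ap(-80, fiber, proto, noise = NULL, width_jitter = 0)
  sw <- trim_artifact(sw)
  expect_equal(ap_peak(sw), 25, tolerance = 0.1)
  expect_equal(ap_half_width(sw), 1.4, tolerance = 1.4 * 0.02)
  # baseline before and long after the AP equals vrest
  tail_v <- sw$voltage_mV[sw$time_ms > 35]
  expect_true(all(abs(tail_v - (-80)) < 1))

  # a peak parameter below the cutoff produces zero area above -30 mV
  sw0 <- synthesize_ap(-80, fiber, proto, noise = NULL, target_peak = -35,
                       width_jitter = 0)
  expect_equal(area_above(trim_artifact(sw0), -30), 0)
  expect_error(synthesize_ap(-20, fiber, proto), "within \\[-100, -30\\]")
})

test_that("disabling widening keeps the half-width constant along the run", {
  proto <- protocol_config("close")
  fiber <- list(LV = 25, HV = -53, V50 = -58.2, k = 1.8, width0_ms = 1.4,
                width_growth_per_mV = 0, width_broadening_beta = 0,
                width_broadening_max = 1)
  hw <- sapply(c(-80, -72, -66, -62), function(v) {
    ap_half_width(trim_artifact(synthesize_ap(v, fiber, proto, noise = NULL,
                                              width_jitter = 0)))
  })
  expect_lt(diff(range(hw)) / mean(hw), 0.02)
})

test_that("conduction fails abruptly below the per-fiber threshold", {
  fiber <- list(conduction_threshold = -21)
  set.seed(3)
  ok <- apply_conduction(30, fiber, "all_or_none", noise = NULL)
  expect_equal(unclass(ok), 30, ignore_attr = TRUE)
  expect_true(attr(ok, "conducted"))
  for (i in 1:50) {
    far <- apply_conduction(-25, fiber, "all_or_none", noise = NULL)
    expect_false(attr(far, "conducted"))
    expect_gte(far, -85); expect_lte(far, -55) # 30-60 mV sudden drops
  }
  cont <- apply_conduction(-25, fiber, "continuous", noise = NULL)
  expect_lt(cont, -25 - 3 * (25 - 21) + 1e-9 + 1)
})

test_that("per-fiber conduction thresholds centre on -21 mV", {
  proto <- protocol_config("close", ramp_duration_s = 5, sweep_duration_ms = 15)
  co <- make_cohort(cohort_config(30, 2, 123, proto))
  thr <- co$truth$conduction_threshold
  se <- 1.5 / sqrt(length(thr))
  expect_equal(nrow(co$truth), 60)
  expect_lt(abs(mean(thr) - (-21)), 3 * se + 0.2)
})

test_that("release saturation and passive decay shape the ROI profile", {
  kin <- calibrate_kinetics()
  proto <- protocol_config("far")
  pos <- roi_positions(proto)
  fiber <- toy_fiber(q50 = 50, hill = 1, knee = 0)

  # zero area everywhere -> zero amplitude everywhere
  ca0 <- synthesize_calcium(rep(0, 20), kin, pos, proto, fiber, noise = NULL)
  expect_equal(ca0$true_amplitude, rep(0, 20))
  # area at the half-saturation -> half of the saturating level
  ca_half <- synthesize_calcium(rep(50, 20), kin, pos, proto, fiber, noise = NULL)
  expect_equal(unique(round(ca_half$true_amplitude, 10)), 0.5)

  # beyond the failure point the amplitude decays e-fold per 0.5 mm
  ca_fail <- synthesize_calcium(rep(150, 20), kin, pos, proto, fiber,
                                failure_point_mm = 0.25, noise = NULL)
  beyond <- pos > 0.25
  expect_equal(ca_fail$true_amplitude[beyond],
               ca_fail$true_amplitude[!beyond][1] *
                 exp(-(pos[beyond] - 0.25) / 0.5), tolerance = 1e-10)
  expect_error(synthesize_calcium(rep(-1, 20), kin, pos, proto, fiber),
               "non-negative")
  expect_error(synthesize_calcium(rep(1, 20), kin, pos, proto,
                                  toy_fiber(F0_base = -5)), "F0_base")
})

test_that("potentiation gives the per-fiber area an interior maximum", {
  run <- close_run()
  f <- run$features
  for (fid in unique(f$fiber_id)) {
    a <- f$area_mVms[f$fiber_id == fid][order(f$stim_index[f$fiber_id == fid])]
    i <- which.max(a)
    expect_gt(i, 1) # rises first (widening + rising floor)
    expect_lt(i, length(a)) # then collapses
    expect_lt(a[length(a)], 0.05 * max(a))
  }
})

test_that("without widening, area increases with peak through the decline", {
  pr <- fiber_prior(width_growth_per_mV = 0, width_broadening_beta = 0)
  cfg <- cohort_config(1, 1, 4, protocol_config("close"), prior = pr,
                       noise = no_noise())
  co <- make_cohort(cfg)
  f <- extract_ap_features(co$sweeps, co$metadata)
  f <- f[order(f$stim_index), ]
  post <- seq(which.max(f$area_mVms), nrow(f))
  keep <- post[f$area_mVms[post] > 0]
  # through the declining phase both fall together: area strictly increasing
  # as a function of peak
  expect_true(all(diff(f$area_mVms[keep]) < 0))
  expect_true(all(diff(f$peak_mV[keep]) < 0))
})

test_that("far-electrode peaks collapse by >40 mV within 2 mV of the ramp", {
  run <- far_run()
  f <- run$features
  meta <- run$cohort$metadata
  n_checked <- 0
  n_ok <- 0
  for (fid in unique(f$fiber_id)) {
    g <- f[f$fiber_id == fid, ]
    g <- g[order(g$stim_index), ]
    drop_ok <- FALSE
    for (i in seq_len(nrow(g) - 1)) {
      within <- which(g$vrest_mV > g$vrest_mV[i] &
                      g$vrest_mV <= g$vrest_mV[i] + 2)
      if (length(within) > 0 &&
          g$peak_mV[i] - min(g$peak_mV[within]) > 40) {
        drop_ok <- TRUE
        break
      }
    }
    if (max(g$peak_mV) > 0) { # fibers that started well polarized
      n_checked <- n_checked + 1
      n_ok <- n_ok + drop_ok
    }
  }
  expect_gt(n_checked, 10)
  # sudden 30-60 mV drops plus the steep near decline: a >40 mV collapse
  # within 2 mV of ramp in (almost) every fiber
  expect_gte(n_ok / n_checked, 0.9)
})

test_that("the truth file is separate and never needed by the analysis", {
  dir <- file.path(tempdir(), "truthsep")
  cfg <- cohort_config(1, 2, 31, protocol_config("close", ramp_duration_s = 60,
                                                 sweep_duration_ms = 20))
  co <- make_cohort(cfg)
  write_cohort(co, dir, overwrite = TRUE)
  file.remove(file.path(dir, "truth.json"))
  back <- read_cohort(dir)
  expect_null(back$truth)
  feats <- extract_ap_features(back$sweeps, back$metadata)
  expect_equal(nrow(feats), nrow(back$metadata))
  unlink(dir, recursive = TRUE)
})

test_that("generator configuration round-trips through YAML losslessly", {
  cfg <- cohort_config(3, c(2, 5), 11, protocol_config("far"),
                       conduction_mode = "mixed", long_pulse = TRUE)
  path <- file.path(tempdir(), "cfg.yaml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back, cfg)
  file.remove(path)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(protocol_config("close", frame_rate_hz = -1), "frame_rate_hz")
  expect_error(protocol_config("close", vrest_end_mV = -90), "vrest_end_mV")
  expect_error(protocol_config("close", frames_per_stim = 300),
               "frames_per_stim")
  expect_error(cohort_config(0), "n_muscles")
  expect_error(cohort_config(2, c(4, 2)), "fibers_per_muscle")
  expect_error(noise_config(dff_sd = -0.1), "dff_sd")
  expect_error(fiber_prior(release_q_frac = 0), "release_q_frac")
})

test_that("the 5 ms artificial AP releases the SR availability fraction", {
  cfg <- cohort_config(6, 2, 7, protocol_config("close"), long_pulse = TRUE)
  co <- make_cohort(cfg)
  dff <- extract_calcium_features(co$calcium, co$metadata)
  last <- ave(dff$stim_index, dff$fiber_id, FUN = max) == dff$stim_index
  lp <- dff[last & dff$roi_index == min(dff$roi_index), ]
  expect_equal(mean(lp$norm_ref70), 0.92, tolerance = 0.12)
  # its sweep is a 5 ms command pulse reaching +10 to +35 mV
  feats <- extract_ap_features(co$sweeps, co$metadata)
  flp <- feats[ave(feats$stim_index, feats$fiber_id, FUN = max) == feats$stim_index, ]
  expect_true(all(flp$peak_mV > 9 & flp$peak_mV < 36))
  expect_true(all(flp$half_width_ms > 3))
})
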