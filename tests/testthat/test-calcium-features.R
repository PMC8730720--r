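test_that("dF/F computation subtracts per-ROI background exactly", {
  fl <- cbind(c(100, 100, 150, 120), c(50, 50, 75, 60))
  res <- compute_dff(fl, background_frames = 1:2)
  expect_equal(res$F0, c(100, 50))
  expect_equal(max(res$dff[, 1]), 0.5)
  expect_equal(max(res$dff[, 2]), 0.5) # gradient cancels in the ratio
  expect_equal(compute_dff(matrix(80, 10, 1), 1:3)$dff, matrix(0, 10, 1))
  expect_error(compute_dff(cbind(c(0, 0, 5)), 1:2), "ROI\\(s\\): 1")
})

test_that("dF/F peak search respects its window", {
  s <- c(0, 0.1, 0.5, 0.2, 0)
  expect_equal(dff_peak(s), 0.5)
  expect_equal(dff_peak(s, window = 1:2), 0.1)
  expect_equal(dff_peak(rep(0, 10)), 0)
  expect_equal(dff_peak(c(0, 2, 0)), 2)
  expect_error(dff_peak(s, window = integer(0)), "empty")
})

test_that("reference normalization picks the stimulation nearest -70 mV", {
  peaks <- c(2, 1.6, 0.8)
  r <- normalize_to_ref70(peaks, c(-70, -60, -55))
  expect_equal(r$ref_index, 1L)
  expect_equal(r$norm[1], 1)
  # -70.4 beats -69.1 (|0.4| < |0.9|)
  r2 <- normalize_to_ref70(c(1.5, 2), c(-70.4, -69.1))
  expect_equal(r2$ref_index, 1L)
  expect_error(normalize_to_ref70(peaks, c(-80, -76, -73), tol = 2),
               "no stimulation within")
})

test_that("run-max normalization maps the maximum to exactly 1", {
  x <- c(2, 1.5, 1, 0.5)
  expect_equal(normalize_to_runmax(x)[1], 1) # monotone declining run
  x2 <- c(1.6, 2, 1) # interior maximum (potentiation)
  expect_lt(normalize_to_runmax(x2)[1], 1)
  expect_equal(max(normalize_to_runmax(x2)), 1)
  expect_warning(z <- normalize_to_runmax(c(0, 0)), "not positive")
  expect_equal(z, c(0, 0))
})

test_that("indicator kinetics calibration matches its closed forms", {
  # tp = tau_on * log((tau_on + tau_off) / tau_on): 10 * log(11) for (10, 100)
  g <- function(t, on, off) (1 - exp(-t / on)) * exp(-t / off)
  tfine <- seq(0.01, 200, by = 0.01)
  tp_direct <- tfine[which.max(g(tfine, 10, 100))]
  expect_equal(10 * log(11), tp_direct, tolerance = 1e-3)

  kin <- calibrate_kinetics(time_to_peak_ms = 44.3, frac_at_t = 0.962)
  # simulate-and-remeasure round trip
  gv <- indicator_response(tfine, kin)
  expect_equal(tfine[which.max(gv)], 44.3, tolerance = 0.02)
  expect_equal(gv[tfine == 33] / max(gv), 0.962, tolerance = 1e-5)
  # a response with no finite peak is infeasible
  expect_error(calibrate_kinetics(frac_at_t = 1), "infeasible|between 0 and 1")
  expect_error(calibrate_kinetics(44.3, 0.2), "infeasible")
})

test_that("30 Hz sampling captures at least 96% of the continuous peak", {
  kin <- calibrate_kinetics()
  proto <- protocol_config("close")
  fiber <- toy_fiber(q50 = 50)
  ca <- synthesize_calcium(150, kin, roi_positions(proto), proto, fiber,
                           noise = NULL)
  A <- ca$true_amplitude
  res <- compute_dff(ca$fluorescence, background_frames = 1L)
  got <- dff_peak(res$dff[, 1])
  expect_gte(got, 0.96 * A)
  expect_lte(got, A + 1e-9)
  # equality with the closed-form best frame of the indicator response
  gn <- indicator_response(ca$frame_times_ms, kin)
  expect_equal(got, A * max(gn), tolerance = 1e-6)
})

test_that("dF/F is invariant to illumination gradients and rescaling", {
  kin <- calibrate_kinetics()
  proto <- protocol_config("far")
  fiber <- toy_fiber(q50 = 50, F0_base = 1000)
  ca <- synthesize_calcium(rep(150, 20), kin, roi_positions(proto), proto,
                           fiber, noise = NULL)
  expect_equal(ca$F0, 1000 * seq(1, 0.6, length.out = 20))
  res <- compute_dff(ca$fluorescence, background_frames = 1L)
  peaks <- apply(res$dff, 2, max)
  expect_equal(max(peaks) - min(peaks), 0, tolerance = 1e-9)

  # global rescaling of the raw fluorescence leaves dF/F unchanged
  res2 <- compute_dff(ca$fluorescence * 3.2, background_frames = 1L)
  expect_equal(res2$dff, res$dff, tolerance = 1e-12)
})

test_that("cohort dF/F extraction normalizes per ROI and flags the reference", {
  run <- close_run()
  d <- run$dff
  expect_true(all(c("dff_peak", "norm_ref70", "norm_runmax",
                    "ref_stim_index") %in% names(d)))
  # reference stimulation normalizes to 1 and run max to exactly 1, per fiber
  for (fid in unique(d$fiber_id)[1:4]) {
    g <- d[d$fiber_id == fid, ]
    expect_equal(g$norm_ref70[g$stim_index == g$ref_stim_index[1]], 1)
    expect_equal(max(g$norm_runmax), 1)
    ref_v <- run$cohort$metadata$vrest_mV[
      run$cohort$metadata$fiber_id == fid &
      run$cohort$metadata$stim_index == g$ref_stim_index[1]]
    expect_lt(abs(ref_v - (-70)), 2)
  }
})
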