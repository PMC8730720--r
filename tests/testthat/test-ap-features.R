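test_that("triangle AP worked example gives exact features", {
  sw <- triangle_sweep()
  expect_equal(ap_peak(sw), 20)
  expect_equal(ap_amplitude(sw), 100)
  # half level -30 mV: crossings at 0.25 ms (rise) and 1.5 ms (fall)
  expect_equal(ap_half_width(sw), 1.25, tolerance = 1e-10)
  # area above -30: 0.5 * 1.25 * 50 by triangle geometry
  expect_equal(area_above(sw, cutoff = -30), 31.25, tolerance = 1e-10)
})

test_that("half-width handles rectangles, time scaling and missing levels", {
  t <- seq(0, 10, by = 0.1)
  v <- ifelse(t >= 2 & t <= 5, 20, -80) # 3 ms rectangle above any level
  sw <- ap_sweep(t, v, vrest = -80)
  expect_equal(ap_half_width(sw), 3, tolerance = 0.11) # edges within 1 sample

  sw2 <- triangle_sweep()
  sw2_slow <- ap_sweep(sw2$time_ms * 2, sw2$voltage_mV, vrest = -80)
  expect_equal(ap_half_width(sw2_slow), 2 * ap_half_width(sw2), tolerance = 1e-9)

  flat <- ap_sweep(t, rep(-80, length(t)), vrest = -80)
  expect_equal(ap_peak(flat), -80)
  expect_equal(ap_amplitude(flat), 0)
  expect_true(is.na(ap_half_width(flat)))
})

test_that("area above cutoff is exact on boundaries and matches a dense oracle", {
  # peak exactly at the cutoff -> zero area
  t <- seq(0, 5, by = 0.1)
  sw <- ap_sweep(t, -80 + 50 * exp(-(t - 2)^2), vrest = -80) # peak -30
  expect_equal(area_above(sw, -30), 0, tolerance = 1e-12)

  # random smooth waveforms: 10 kHz result within 0.5% of a 100x-oversampled
  # trapezoidal oracle computed from the same analytic waveform
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 55, 110); mu <- runif(1, 3, 12); s <- runif(1, 0.6, 3)
    f <- function(tt) -80 + a * exp(-(tt - mu)^2 / (2 * s^2)) +
      0.3 * a * exp(-(tt - mu - 2)^2 / 2)
    t10 <- seq(0, 20, by = 0.1)
    fine <- seq(0, 20, by = 0.001)
    oracle <- sum(diff(fine) * (pmax(f(fine) - (-30), 0)[-1] +
                                pmax(f(fine) - (-30), 0)[-length(fine)]) / 2)
    got <- area_above(ap_sweep(t10, f(t10), vrest = -80), -30)
    if (oracle > 5) expect_equal(got, oracle, tolerance = 0.005)
  }
})

test_that("adding a constant raises the area as the sub-sample oracle predicts", {
  set.seed(12)
  t10 <- seq(0, 20, by = 0.1)
  f <- function(tt) -80 + 90 * exp(-(tt - 8)^2 / 3)
  fine <- seq(0, 20, by = 0.001)
  for (shift in c(5, 10)) {
    oracle <- sum(diff(fine) * (pmax(f(fine) + shift + 30, 0)[-1] +
                                pmax(f(fine) + shift + 30, 0)[-length(fine)]) / 2)
    got <- area_above(ap_sweep(t10, f(t10) + shift, vrest = -80 + shift), -30)
    expect_equal(got, oracle, tolerance = 0.005)
  }
})

test_that("artifact trimming excludes the window plus a one-sample guard", {
  t <- seq(0, 5, by = 0.1)
  v <- rep(-80, length(t))
  v[t >= 2 & t <= 3] <- -80 + 60 * sin(pi * (t[t >= 2 & t <= 3] - 2)) # AP
  v[t <= 0.2] <- 100 # artifact 3x larger than the AP peak
  sw <- ap_sweep(t, v, vrest = -80, artifact_window = c(0, 0.2))
  sw <- trim_artifact(sw)
  expect_lt(ap_peak(sw), -10) # peak found outside the artifact
  expect_equal(sum(sw$excluded), 4) # 3 window samples + 1 guard (right side)
  # an interior window gains exactly one guard sample per side
  swi <- trim_artifact(ap_sweep(t, v, vrest = -80, artifact_window = c(1, 1.2)))
  expect_equal(sum(swi$excluded), 5)
  # artifact content is irrelevant once trimmed
  v2 <- v; v2[t <= 0.2] <- 500
  sw2 <- trim_artifact(ap_sweep(t, v2, vrest = -80, artifact_window = c(0, 0.2)))
  expect_identical(ap_peak(sw), ap_peak(sw2))
  expect_identical(area_above(sw, -30), area_above(sw2, -30))

  # zero-length window leaves the sweep unchanged
  sw3 <- trim_artifact(ap_sweep(t, v, vrest = -80, artifact_window = c(1, 1)))
  expect_false(any(sw3$excluded))
  expect_error(trim_artifact(ap_sweep(t, v, vrest = -80,
                                      artifact_window = c(0, 5))),
               "entire trace")
})

test_that("peak and area normalization follow the cutoff rules", {
  expect_equal(normalize_peaks(c(20, -10, -25, -32), cutoff = -30),
               c(1, 0.4, 0.1, 0))
  expect_equal(normalize_peaks(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(normalize_peaks(c(10, -30))[2], 0)
  expect_warning(z <- normalize_peaks(c(-35, -40)), "all 0")
  expect_equal(z, c(0, 0))

  expect_equal(normalize_areas(c(10, 20, 40)), c(0.25, 0.5, 1))
  expect_equal(normalize_areas(7), 1)
  expect_equal(normalize_areas(c(10, 20, 40) * 3.7),
               normalize_areas(c(10, 20, 40)))
  expect_warning(z2 <- normalize_areas(c(0, 0)), "all 0")
  expect_equal(z2, c(0, 0))
})

test_that("features extracted from synthetic sweeps reproduce their targets", {
  proto <- protocol_config("close")
  fiber <- list(LV = 25, HV = -53, V50 = -58.2, k = 1.8, width0_ms = 1.25,
                width_growth_per_mV = 0, width_broadening_beta = 0,
                width_broadening_max = 1)
  sw <- synthesize_ap(-80, fiber, proto, noise = NULL, target_peak = 20,
                      target_half_width = 1.25, width_jitter = 0)
  sw <- trim_artifact(sw)
  expect_equal(ap_peak(sw), 20, tolerance = 0.1)
  expect_equal(ap_half_width(sw), 1.25, tolerance = 0.025)

  sw2 <- synthesize_ap(-58, fiber, proto, noise = NULL, target_peak = -12.8,
                       width_jitter = 0)
  expect_equal(ap_peak(trim_artifact(sw2)), -12.8, tolerance = 0.1)
})
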