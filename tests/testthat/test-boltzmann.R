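test_that("Boltzmann evaluation obeys midpoint, asymptotes and symmetry", {
  # midpoint identity: Out(V50) = (LV + HV) / 2
  expect_equal(boltzmann(-58.2, LV = 30, HV = -40, V50 = -58.2, k = 1.8), -5)
  # direct scalar evaluation: 1 - 1 / (1 + exp(-3.75))
  expect_equal(boltzmann(-56, LV = 1, HV = 0, V50 = -57.5, k = 0.4),
               1 - 1 / (1 + exp(-3.75)), tolerance = 1e-12)
  # asymptotes
  expect_equal(boltzmann(-1e6, LV = 30, HV = -40, V50 = -58, k = 1.8), 30)
  expect_equal(boltzmann(1e6, LV = 30, HV = -40, V50 = -58, k = 1.8), -40)

  set.seed(42)
  for (i in 1:25) {
    LV <- runif(1, -50, 50); HV <- LV - runif(1, 1, 80)
    V50 <- runif(1, -80, 0); k <- runif(1, 0.2, 10); d <- runif(1, 0, 30)
    expect_equal(boltzmann(V50 + d, LV, HV, V50, k) +
                 boltzmann(V50 - d, LV, HV, V50, k), LV + HV, tolerance = 1e-10)
    expect_equal(boltzmann(V50, LV, HV, V50, k), (LV + HV) / 2, tolerance = 1e-12)
  }
  expect_error(boltzmann(-60, 1, 0, -58, -1), "must be positive")
})

test_that("half-max output and 10-90 span follow their closed forms", {
  expect_equal(half_max_output(c(LV = 30, HV = -40)), -5)
  expect_equal(half_max_output(c(LV = 1, HV = 0)), 0.5)
  expect_equal(span_10_90(1.8), 1.8 * log(81))
  expect_equal(span_10_90(0.4), 0.4 * log(81))
  expect_equal(span_10_90(3.6), 2 * span_10_90(1.8))
  expect_error(span_10_90(0), "must be positive")
})

test_that("noise-free fits recover their generating parameters", {
  x <- seq(-75, -45, by = 1)
  truth <- c(LV = 25, HV = -42, V50 = -58.2, k = 1.8)
  y <- boltzmann(x, truth["LV"], truth["HV"], truth["V50"], truth["k"])
  fit <- fit_boltzmann(x, y, boltzmann_preset("peak_vs_vrest"))
  expect_true(fit$converged)
  expect_equal(unname(fit$params[names(truth)]), unname(truth), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
  expect_equal(fit$half_max_output, (25 - 42) / 2, tolerance = 1e-3)

  # dff presets honour their fixed parameters exactly
  y2 <- boltzmann(x, 1, 0.02, -57.5, 0.6)
  fit2 <- fit_boltzmann(x, y2, boltzmann_preset("dff_vs_vrest"))
  expect_identical(unname(fit2$params["LV"]), 1)
  expect_equal(unname(fit2$params["V50"]), -57.5, tolerance = 1e-3)
  y3 <- boltzmann(x, 0, 1, -58, 2.2)
  fit3 <- fit_boltzmann(x, y3, boltzmann_preset("dff_vs_peak"))
  expect_identical(unname(fit3$params[c("LV", "HV")]), c(0, 1))
  expect_equal(unname(fit3$params["k"]), 2.2, tolerance = 1e-3)
})

test_that("bound constraints pin parameters and beat a coarse grid search", {
  x <- seq(-75, -45, by = 1)
  y <- boltzmann(x, 25, -60, -58, 2) # true HV below the [-50, -30] bound
  fit <- fit_boltzmann(x, y, boltzmann_preset("peak_vs_vrest"))
  expect_equal(unname(fit$params["HV"]), -50, tolerance = 1e-6)

  # exhaustive coarse grid over the free parameters never beats the fit
  grid <- expand.grid(LV = seq(15, 35, 5), HV = seq(-50, -30, 5),
                      V50 = seq(-65, -50, 2.5), k = c(0.5, 1, 2, 4))
  grid_rss <- apply(grid, 1, function(p) {
    sum((y - boltzmann(x, p["LV"], p["HV"], p["V50"], p["k"]))^2)
  })
  expect_lte(fit$rss, min(grid_rss))
})

test_that("fits are shift-equivariant in x and flag degenerate data", {
  set.seed(7)
  x <- seq(-70, -45, by = 1)
  y <- boltzmann(x, 20, -45, -58, 2) + rnorm(length(x), 0, 0.8)
  f1 <- fit_boltzmann(x, y, boltzmann_preset("peak_vs_vrest"))
  f2 <- fit_boltzmann(x + 13, y, boltzmann_preset("peak_vs_vrest"))
  expect_equal(unname(f2$params["V50"] - f1$params["V50"]), 13, tolerance = 1e-5)
  expect_equal(unname(f2$params["k"]), unname(f1$params["k"]), tolerance = 1e-6)

  expect_warning(flat <- fit_boltzmann(x, rep(2, length(x)),
                                       boltzmann_preset("dff_vs_peak")),
                 "no variance")
  expect_false(flat$converged)
  expect_error(fit_boltzmann(c(-60, -55, -50), c(1, 0.5, 0),
                             boltzmann_preset("peak_vs_vrest")),
               "fewer data points|at least 4 points")
})

test_that("parameters are recovered from noisy data across all presets", {
  # 200 simulated datasets, n = 30, noise sd = 5% of the response range
  set.seed(2024)
  presets <- c("peak_vs_vrest", "dff_vs_vrest", "dff_vs_peak")
  for (preset in presets) {
    cfg <- boltzmann_preset(preset)
    err_v50 <- err_k <- numeric(200)
    for (i in 1:200) {
      truth <- switch(preset,
        peak_vs_vrest = c(LV = runif(1, 15, 35), HV = runif(1, -48, -35),
                          V50 = runif(1, -62, -55), k = runif(1, 1, 3)),
        dff_vs_vrest = c(LV = 1, HV = runif(1, 0, 0.08),
                         V50 = runif(1, -62, -55), k = runif(1, 0.3, 1.5)),
        dff_vs_peak = c(LV = 0, HV = 1,
                        V50 = runif(1, -25, -15), k = runif(1, 3, 8)))
      x <- switch(preset, dff_vs_peak = seq(-45, 25, length.out = 30),
                  seq(-75, -45, length.out = 30))
      y0 <- boltzmann(x, truth["LV"], truth["HV"], truth["V50"], truth["k"])
      y <- y0 + rnorm(30, 0, 0.05 * diff(range(y0)))
      fit <- fit_boltzmann(x, y, cfg)
      err_v50[i] <- abs(fit$params["V50"] - truth["V50"])
      err_k[i] <- abs(fit$params["k"] - truth["k"])
    }
    expect_lt(median(err_v50), 0.5)
    expect_lt(median(err_k), 0.3)
  }
})
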