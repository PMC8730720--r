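#' Recording-protocol configuration
#'
#' Describes one stimulation protocol of the high-K+ infusion experiment:
#' voltage sampled at 10 kHz, 48 fluorescence frames at 30 frames/s per
#' stimulation, one stimulation every 5 s while the resting potential ramps
#' from `vrest_start_mV` to `vrest_end_mV` (about 30 mV over about 4 min).
#' Two presets mirror the two electrode layouts: `"close"` (both electrodes
#' within 0.1 mm, a single analysis ROI; used for the per-fiber voltage
#' relationships) and `"far"` (electrodes separated by 1.6 mm, 20 ROIs along
#' the fiber; used for conduction analysis).
#'
#' @param mode electrode layout preset, `"close"` or `"far"`.
#' @param ap_sample_rate_per_ms voltage samples per ms (default 10, i.e. 10 kHz).
#' @param frame_rate_hz fluorescence frame rate (default 30).
#' @param frames_per_stim frames captured per stimulation (default 48).
#' @param stim_interval_s time between stimulations (default 5 s).
#' @param stim_duration_ms current-injection duration (default 0.2 ms; the
#'   long-pulse "artificial AP" mode uses 5 ms).
#' @param stim_current_nA injected current (metadata only).
#' @param n_rois number of ROIs along the fiber.
#' @param electrode_separation_mm distance between stimulating and recording
#'   electrodes.
#' @param vrest_start_mV,vrest_end_mV resting potential at the start and the
#'   asymptote of the infusion ramp (depolarizing, so end > start).
#' @param ramp_tau_s time constant of the exponential approach of the resting
#'   potential to `vrest_end_mV`.
#' @param ramp_duration_s length of the recorded run.
#' @param sweep_duration_ms length of each voltage sweep.
#' @param k_condition_mM extracellular K+ of the infusion (metadata).
#' @return a list of class `ecc_protocol`.
#' @export
protocol_config <- function(mode = c("close", "far"),
                            ap_sample_rate_per_ms = 10,
                            frame_rate_hz = 30,
                            frames_per_stim = 48L,
                            stim_interval_s = 5,
                            stim_duration_ms = 0.2,
                            stim_current_nA = 300,
                            n_rois = NULL,
                            electrode_separation_mm = NULL,
                            vrest_start_mV = -80,
                            vrest_end_mV = -48,
                            ramp_tau_s = 150,
                            ramp_duration_s = 240,
                            sweep_duration_ms = 40,
                            k_condition_mM = 16) {
  mode <- match.arg(mode)
  if (is.null(n_rois)) n_rois <- if (mode == "far") 20L else 1L
  if (is.null(electrode_separation_mm)) {
    electrode_separation_mm <- if (mode == "far") 1.6 else 0.075
  }
  p <- structure(list(
    mode = mode,
    ap_sample_rate_per_ms = ap_sample_rate_per_ms,
    frame_rate_hz = frame_rate_hz,
    frames_per_stim = as.integer(frames_per_stim),
    stim_interval_s = stim_interval_s,
    stim_duration_ms = stim_duration_ms,
    stim_current_nA = stim_current_nA,
    n_rois = as.integer(n_rois),
    electrode_separation_mm = electrode_separation_mm,
    vrest_start_mV = vrest_start_mV,
    vrest_end_mV = vrest_end_mV,
    ramp_tau_s = ramp_tau_s,
    ramp_duration_s = ramp_duration_s,
    sweep_duration_ms = sweep_duration_ms,
    k_condition_mM = k_condition_mM
  ), class = "ecc_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  pos <- c("ap_sample_rate_per_ms", "frame_rate_hz", "frames_per_stim",
           "stim_interval_s", "stim_duration_ms", "n_rois",
           "electrode_separation_mm", "ramp_tau_s", "ramp_duration_s",
           "sweep_duration_ms")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) || p[[f]] <= 0) {
      stop_input("protocol field '%s' must be a single positive number", f)
    }
  }
  if (p$frames_per_stim / p$frame_rate_hz >= p$stim_interval_s) {
    stop_input("protocol: frames_per_stim / frame_rate_hz (%.2f s) must be shorter than stim_interval_s (%.2f s)",
               p$frames_per_stim / p$frame_rate_hz, p$stim_interval_s)
  }
  if (p$vrest_end_mV <= p$vrest_start_mV) {
    stop_input("protocol: vrest_end_mV (%.1f) must be more depolarized than vrest_start_mV (%.1f)",
               p$vrest_end_mV, p$vrest_start_mV)
  }
  invisible(p)
}

#' ROI positions along the fiber
#'
#' ROIs span the stimulating electrode (position 0) to the recording
#' electrode (`electrode_separation_mm`). A single ROI sits at the recording
#' electrode.
#'
#' @param protocol an `ecc_protocol`.
#' @return numeric vector of positions (mm), ascending.
#' @export
roi_positions <- function(protocol) {
  n <- protocol$n_rois
  if (n == 1L) return(protocol$electrode_separation_mm)
  seq(0, protocol$electrode_separation_mm, length.out = n)
}

#' Per-fiber parameter priors of the cohort generator
#'
#' Distributions from which each synthetic fiber's ground-truth parameters are
#' drawn. The AP-peak dependence on resting potential is Boltzmann-shaped with
#' per-fiber `LV` (maximal peak), `HV` (asymptotic minimal peak), `V50` and
#' slope `k`; the true `HV` sits below the -50 mV fitting bound so that
#' constrained fits pin at the bound, as observed for the real fibers. Ca2+
#' release is a saturating (Hill) function of the AP integral above -30 mV,
#' modulated by a resting-Ca2+ potentiation gain that rises with mild
#' depolarization; `release_q_frac` and `release_hill` are calibrated so the
#' emergent dF/F-vs-AP-peak relationship is half-maximal near -21 mV with a
#' 10-90 span of about 26 mV.
#'
#' @param peak_LV_range,peak_HV_range uniform ranges (mV) for the Boltzmann
#'   asymptotes of the AP peak.
#' @param peak_V50_mean,peak_V50_sd,peak_k_mean,peak_k_sd normal priors (mV)
#'   for the AP-peak Boltzmann midpoint and slope.
#' @param peak_V50_trunc truncation range of the V50 draw: the study followed
#'   fibers until ECC failed, so only fibers whose excitation failure falls
#'   inside the recorded ramp enter a cohort.
#' @param width0_mean_ms,width0_sd_ms baseline AP half-width prior.
#' @param width_growth_per_mV fractional half-width growth per mV of
#'   resting-potential depolarization (AP widening).
#' @param width_broadening_beta exponent of the amplitude-dependent AP
#'   broadening near excitation failure: the half-width gains a factor
#'   `((LV + 30) / (peak + 30))^beta`, so decaying APs become long
#'   depolarized humps and the AP integral above the cutoff falls much more
#'   slowly than the peak (as observed: normalized integrals of 0.43-0.81
#'   for peaks down to -21 mV).
#' @param width_broadening_max cap on that broadening factor.
#' @param conduction_threshold_mean,conduction_threshold_sd per-fiber AP-peak
#'   threshold (mV) below which propagation fails (near -21 mV).
#' @param release_q_frac half-saturation of Ca2+ release, as a fraction of the
#'   fiber's baseline AP area above the cutoff.
#' @param release_hill Hill coefficient of the release saturation.
#' @param release_knee_p sharpness of the soft saturation ceiling at the
#'   baseline release level (full-sized APs nearly saturate SR release, so
#'   area gains above baseline add little dF/F); 0 disables the ceiling.
#' @param pot_gain_range,pot_range_mV per-fiber uniform range of the
#'   potentiation gain reached after `pot_range_mV` of depolarization from
#'   the ramp start (elevated resting Ca2+; the rising phase of dF/F is not
#'   driven by the AP integral, and its size varies between fibers).
#' @param pot_fade_frac,pot_fade_range_mV fraction of the potentiation gain
#'   that fades over the next `pot_fade_range_mV` of depolarization
#'   (Ca2+-dependent inactivation makes the potentiation transient).
#' @param dff_scale_mean,dff_scale_sd absolute dF/F scale prior.
#' @param F0_range arbitrary-units range of the baseline fluorescence.
#' @param sr_availability_longpulse fraction of the reference Ca2+ release
#'   available to a 5 ms "artificial AP" after ECC failure.
#' @return a list of class `ecc_prior`.
#' @export
fiber_prior <- function(peak_LV_range = c(15, 30),
                        peak_HV_range = c(-58, -48),
                        peak_V50_mean = -58.2, peak_V50_sd = 3.3,
                        peak_V50_trunc = c(-63, -57),
                        peak_k_mean = 1.8, peak_k_sd = 0.6,
                        width0_mean_ms = 1.4, width0_sd_ms = 0.15,
                        width_growth_per_mV = 0.002,
                        width_broadening_beta = 1.1,
                        width_broadening_max = 10,
                        conduction_threshold_mean = -21,
                        conduction_threshold_sd = 1.5,
                        release_q_frac = 2.5,
                        release_hill = 1,
                        release_knee_p = 6,
                        pot_gain_range = c(0.02, 0.15),
                        pot_range_mV = 14,
                        pot_fade_frac = 0.6,
                        pot_fade_range_mV = 8,
                        dff_scale_mean = 1.5, dff_scale_sd = 0.3,
                        F0_range = c(800, 1200),
                        sr_availability_longpulse = 0.92) {
  pr <- structure(as.list(environment()), class = "ecc_prior")
  if (pr$peak_k_mean <= 0) stop_input("prior field 'peak_k_mean' must be positive")
  if (pr$release_q_frac <= 0 || pr$release_hill <= 0) {
    stop_input("prior fields 'release_q_frac' and 'release_hill' must be positive")
  }
  if (pr$sr_availability_longpulse <= 0 || pr$sr_availability_longpulse > 1) {
    stop_input("prior field 'sr_availability_longpulse' must be in (0, 1]")
  }
  pr
}

#' Measurement-noise configuration of the generator
#'
#' @param vm_sd_mV additive voltage recording noise (mV).
#' @param vrest_jitter_mV jitter of the measured resting potential around the
#'   infusion ramp (mV).
#' @param width_jitter_frac per-stimulation fractional jitter of the AP
#'   half-width.
#' @param dff_sd dF/F measurement noise, in units of the fiber's dF/F scale.
#' @param dff_drift_sd,dff_drift_phi stationary SD and lag-1 autocorrelation
#'   of a slow multiplicative drift of the release gain along the run
#'   (fluctuations of SR load and resting Ca2+); set `dff_drift_sd = 0` to
#'   disable.
#' @param dropout_prob,dropout_onset_mV once the fiber has depolarized by
#'   `dropout_onset_mV` from the ramp start, each stimulation fails to fully
#'   activate with probability `dropout_prob`, scaling its release by a
#'   random factor in \[0.4, 0.85\] (depolarized fibers fire APs of variable
#'   amplitude and incomplete t-tubule activation).
#' @param frame_shot_frac per-frame shot noise as a fraction of `F0`.
#' @param far_peak_jitter_mV jitter of the conducted far-electrode AP peak.
#' @return a list of class `ecc_noise`. Set fields to 0 for noise-free data.
#' @export
noise_config <- function(vm_sd_mV = 0.05,
                         vrest_jitter_mV = 0.05,
                         width_jitter_frac = 0.12,
                         dff_sd = 0.08,
                         dff_drift_sd = 0.08,
                         dff_drift_phi = 0.9,
                         dropout_prob = 0,
                         dropout_onset_mV = 10,
                         frame_shot_frac = 0.005,
                         far_peak_jitter_mV = 0.5) {
  nz <- structure(as.list(environment()), class = "ecc_noise")
  for (f in names(nz)) {
    if (!is.numeric(nz[[f]]) || length(nz[[f]]) != 1L || !is.finite(nz[[f]]) || nz[[f]] < 0) {
      stop_input("noise field '%s' must be a single non-negative number", f)
    }
  }
  nz
}

#' Cohort-generator configuration
#'
#' @param n_muscles number of muscles in the cohort.
#' @param fibers_per_muscle fibers per muscle: a single count, or a range
#'   `c(min, max)` sampled per muscle (the conduction experiments used 2-6
#'   fibers per muscle).
#' @param seed integer root seed; each fiber derives its own RNG sub-stream,
#'   so enlarging the cohort never perturbs existing fibers.
#' @param protocol an [protocol_config()].
#' @param prior an [fiber_prior()].
#' @param noise a [noise_config()].
#' @param conduction_mode how propagation fails beyond the per-fiber
#'   threshold: `"all_or_none"` (sudden 30-60 mV drops), `"continuous"`
#'   (steep graded decline), or `"mixed"` (per-fiber coin flip).
#' @param long_pulse if `TRUE`, append one 5 ms "artificial AP" stimulation at
#'   the end of each run (SR-release availability probe).
#' @return a list of class `ecc_config`.
#' @export
cohort_config <- function(n_muscles = 6L, fibers_per_muscle = 2L, seed = 1L,
                          protocol = protocol_config("close"),
                          prior = fiber_prior(),
                          noise = noise_config(),
                          conduction_mode = c("all_or_none", "continuous", "mixed"),
                          long_pulse = FALSE) {
  conduction_mode <- match.arg(conduction_mode)
  cfg <- structure(list(
    n_muscles = as.integer(n_muscles),
    fibers_per_muscle = as.integer(fibers_per_muscle),
    seed = as.integer(seed),
    protocol = protocol, prior = prior, noise = noise,
    conduction_mode = conduction_mode,
    long_pulse = isTRUE(long_pulse)
  ), class = "ecc_config")
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config an `ecc_config` to validate.
#' @export
validate_cohort_config <- function(config) {
  if (!is_count(config$n_muscles)) stop_input("config field 'n_muscles' must be a count >= 1")
  f <- config$fibers_per_muscle
  if (!(length(f) %in% 1:2) || any(!is.finite(f)) || any(f < 1) || any(f != round(f))) {
    stop_input("config field 'fibers_per_muscle' must be a count or a c(min, max) range")
  }
  if (length(f) == 2L && f[2L] < f[1L]) {
    stop_input("config field 'fibers_per_muscle' range must be increasing")
  }
  if (!is_count(abs(config$seed) + 1)) stop_input("config field 'seed' must be an integer")
  validate_protocol(config$protocol)
  if (!inherits(config$prior, "ecc_prior")) stop_input("config field 'prior' must come from fiber_prior()")
  if (!inherits(config$noise, "ecc_noise")) stop_input("config field 'noise' must come from noise_config()")
  invisible(config)
}

#' Serialize a generator configuration to YAML
#'
#' @param config an `ecc_config`.
#' @param path file path for the YAML configuration.
#' @export
write_cohort_config <- function(config, path) {
  validate_cohort_config(config)
  plain <- unclass(config)
  plain$protocol <- unclass(plain$protocol)
  plain$prior <- unclass(plain$prior)
  plain$noise <- unclass(plain$noise)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  proto_args <- lapply(raw$protocol, unlist)
  proto_args$mode <- NULL
  cohort_config(
    n_muscles = raw$n_muscles,
    fibers_per_muscle = unlist(raw$fibers_per_muscle),
    seed = raw$seed,
    protocol = do.call(protocol_config, c(list(mode = raw$protocol$mode), proto_args)),
    prior = do.call(fiber_prior, lapply(raw$prior, unlist)),
    noise = do.call(noise_config, lapply(raw$noise, unlist)),
    conduction_mode = raw$conduction_mode,
    long_pulse = raw$long_pulse
  )
}

# --- indicator kinetics -----------------------------------------------------

#' Calibrate the slow-indicator response kinetics
#'
#' The indicator impulse response is modelled as a rise-times-decay product
#' `g(t) = (1 - exp(-t/tau_on)) * exp(-t/tau_off)`. Its peak time obeys the
#' closed form `tp = tau_on * log((tau_on + tau_off) / tau_on)`. This routine
#' finds `(tau_on, tau_off)` such that the peak occurs at
#' `time_to_peak_ms` and the response at `t_frac_ms` (one 30 Hz frame, 33 ms)
#' is `frac_at_t` of the peak, to within 1e-6 relative tolerance.
#'
#' @param time_to_peak_ms target time to peak (default 44.3 ms).
#' @param frac_at_t target fractional response at `t_frac_ms` (default 0.962).
#' @param t_frac_ms time of the fractional constraint (default 33 ms).
#' @return a list of class `ecc_kinetics` with `tau_on`, `tau_off`,
#'   `time_to_peak_ms`, `frac_at_t`, and the peak response `g_peak`.
#' @export
calibrate_kinetics <- function(time_to_peak_ms = 44.3, frac_at_t = 0.962,
                               t_frac_ms = 33) {
  if (!is.finite(frac_at_t) || frac_at_t <= 0 || frac_at_t >= 1) {
    stop_input("frac_at_t must lie strictly between 0 and 1 (a response with no finite peak is infeasible)")
  }
  if (time_to_peak_ms <= 0) stop_input("time_to_peak_ms must be positive")
  g <- function(t, on, off) (1 - exp(-t / on)) * exp(-t / off)
  tau_off_of <- function(on) on * (exp(time_to_peak_ms / on) - 1)
  ratio <- function(on) {
    off <- tau_off_of(on)
    g(t_frac_ms, on, off) / g(time_to_peak_ms, on, off)
  }
  # bracket the root over a wide tau_on scan
  grid <- exp(seq(log(time_to_peak_ms / 50), log(time_to_peak_ms * 20), length.out = 200))
  vals <- vapply(grid, ratio, numeric(1)) - frac_at_t
  sgn <- which(diff(sign(vals)) != 0)
  if (length(sgn) == 0L) {
    stop_input("kinetics calibration infeasible: attainable fraction at %g ms spans [%.4f, %.4f], target %.4f",
               t_frac_ms, min(vals) + frac_at_t, max(vals) + frac_at_t, frac_at_t)
  }
  i <- sgn[1L]
  root <- stats::uniroot(function(on) ratio(on) - frac_at_t,
                         lower = grid[i], upper = grid[i + 1L], tol = 1e-12)
  tau_on <- root$root
  tau_off <- tau_off_of(tau_on)
  resid <- abs(ratio(tau_on) - frac_at_t) / frac_at_t
  if (resid > 1e-6) {
    stop_input("kinetics calibration did not reach tolerance (relative residual %.2e)", resid)
  }
  structure(list(tau_on = tau_on, tau_off = tau_off,
                 time_to_peak_ms = time_to_peak_ms, frac_at_t = frac_at_t,
                 t_frac_ms = t_frac_ms,
                 g_peak = g(time_to_peak_ms, tau_on, tau_off)),
            class = "ecc_kinetics")
}

#' Normalized indicator response
#'
#' @param t_ms time since the stimulus (ms), vectorized.
#' @param kinetics an `ecc_kinetics` from [calibrate_kinetics()].
#' @param normalize if `TRUE` (default) scale so the peak response is 1.
#' @return the indicator response at `t_ms` (0 for `t_ms <= 0`).
#' @export
indicator_response <- function(t_ms, kinetics, normalize = TRUE) {
  g <- ifelse(t_ms <= 0, 0,
              (1 - exp(-t_ms / kinetics$tau_on)) * exp(-t_ms / kinetics$tau_off))
  if (normalize) g / kinetics$g_peak else g
}

# --- fiber truth ------------------------------------------------------------

fiber_seed <- function(seed, muscle, fiber) {
  as.integer((seed + 100003 * ((muscle - 1) * 64 + fiber)) %% .Machine$integer.max)
}

# Draw one fiber's ground-truth parameters from the prior (uses the current
# RNG stream; callers wrap in with_seed()).
draw_fiber_truth <- function(prior, protocol, conduction_mode = "all_or_none") {
  tr <- list(
    LV = stats::runif(1, prior$peak_LV_range[1L], prior$peak_LV_range[2L]),
    HV = stats::runif(1, prior$peak_HV_range[1L], prior$peak_HV_range[2L]),
    # V50 truncated so excitation failure occurs within the recorded ramp:
    # the study followed fibers until ECC failed, so fibers whose transition
    # would fall outside the protocol are never part of the cohort
    V50 = min(max(stats::rnorm(1, prior$peak_V50_mean, prior$peak_V50_sd),
                  prior$peak_V50_trunc[1L]), prior$peak_V50_trunc[2L]),
    k = max(stats::rnorm(1, prior$peak_k_mean, prior$peak_k_sd), 0.5),
    width0_ms = max(stats::rnorm(1, prior$width0_mean_ms, prior$width0_sd_ms), 0.6),
    width_growth_per_mV = prior$width_growth_per_mV,
    width_broadening_beta = prior$width_broadening_beta,
    width_broadening_max = prior$width_broadening_max,
    conduction_threshold = stats::rnorm(1, prior$conduction_threshold_mean,
                                        prior$conduction_threshold_sd),
    release_hill = prior$release_hill,
    pot_gain = stats::runif(1, prior$pot_gain_range[1L], prior$pot_gain_range[2L]),
    pot_range_mV = prior$pot_range_mV,
    pot_fade_frac = prior$pot_fade_frac,
    pot_fade_range_mV = prior$pot_fade_range_mV,
    dff_scale = max(stats::rnorm(1, prior$dff_scale_mean, prior$dff_scale_sd), 0.5),
    F0_base = stats::runif(1, prior$F0_range[1L], prior$F0_range[2L]),
    sr_availability = prior$sr_availability_longpulse,
    conduction_kind = if (conduction_mode == "mixed") {
      if (stats::runif(1) < 0.5) "all_or_none" else "continuous"
    } else conduction_mode
  )
  # baseline AP area above the cutoff, for the release half-saturation
  base <- synthesize_ap(protocol$vrest_start_mV, tr, protocol,
                        noise = NULL, width_jitter = 0)
  tr$baseline_area <- attr(base, "true_area")
  tr$release_q50 <- prior$release_q_frac * tr$baseline_area
  tr$release_knee_p <- prior$release_knee_p
  h <- tr$release_hill
  tr$release_sat_base <- tr$baseline_area^h / (tr$baseline_area^h + tr$release_q50^h)
  # normalize so dff_scale is the baseline (ramp-start) dF/F of the fiber
  tr$release_norm <- .release_sat(tr$baseline_area, tr)
  tr
}

#' Boltzmann model of the AP peak at a given resting potential
#'
#' @param vrest resting potential (mV), vectorized.
#' @param fiber a fiber-truth list with elements `LV`, `HV`, `V50`, `k`
#'   (`LV > HV`).
#' @return modelled AP peak (mV), monotonically non-increasing in `vrest`.
#' @export
ap_peak_model <- function(vrest, fiber) {
  if (is.null(fiber$k) || fiber$k <= 0) stop_input("fiber truth must have a positive slope factor 'k'")
  if (fiber$LV <= fiber$HV) stop_input("fiber truth must satisfy LV > HV")
  boltzmann(vrest, fiber$LV, fiber$HV, fiber$V50, fiber$k)
}

# potentiation gain: elevated resting Ca2+ boosts release with mild
# depolarization, then fades with further depolarization (Ca2+-dependent
# inactivation), so the dF/F potentiation is transient
.pot_gain <- function(vrest, fiber, vrest_start) {
  rise <- pmin(pmax((vrest - vrest_start) / fiber$pot_range_mV, 0), 1)
  fade <- pmin(pmax((vrest - vrest_start - fiber$pot_range_mV) /
                      (fiber$pot_fade_range_mV %||% 8), 0), 1)
  1 + fiber$pot_gain * rise * (1 - (fiber$pot_fade_frac %||% 0) * fade)
}

# Saturating release as a function of AP area above the cutoff. A Hill term
# sets the decline below baseline; a soft ceiling at the baseline release
# level encodes that full-sized APs already near-saturate SR release
# (depolarization beyond ~0 mV adds little dF/F). Scaled so the fiber's
# baseline area maps to 1 once release_norm is set.
.release_sat <- function(area, fiber) {
  a <- pmax(area, 0)
  h <- fiber$release_hill
  s <- a^h / (a^h + fiber$release_q50^h)
  p <- fiber$release_knee_p %||% 0
  sb <- fiber$release_sat_base
  if (p > 0 && !is.null(sb)) {
    r <- s / sb
    s <- (r^(-p) + 1)^(-1 / p)
    s[r <= 0] <- 0
  }
  s / (fiber$release_norm %||% 1)
}

# --- AP synthesis -----------------------------------------------------------

.ap_shape <- function(t, t0, tau_rise, tau_decay) {
  stats::plogis((t - t0) / tau_rise) * exp(-(t - t0) / tau_decay)
}

# Solve the decay time constant so the scaled waveform has the requested
# half-width on the protocol's sample grid.
.solve_tau_decay <- function(time_ms, t0, vrest, peak, half_width_ms, tau_rise = 0.1) {
  hw_of <- function(tau) {
    u <- .ap_shape(time_ms, t0, tau_rise, tau)
    v <- vrest + (peak - vrest) * u / max(u)
    time_above(time_ms, v, vrest + (peak - vrest) / 2) - half_width_ms
  }
  lo <- 0.02
  hi <- max(time_ms) - t0
  if (hw_of(hi) < 0) return(hi) # cap: sweep shorter than the requested width
  stats::uniroot(hw_of, lower = lo, upper = hi, tol = 1e-6)$root
}

#' Synthesize one action-potential sweep
#'
#' Builds a voltage trace as a sigmoidal rise times exponential decay,
#' numerically rescaled so the sampled peak equals the modelled AP peak and
#' the half-width equals the widened target
#' `width0 * (1 + width_growth_per_mV * (vrest - vrest_start))`. A
#' stimulus-artifact segment occupies `[0, stim_duration_ms]` and the AP
#' onset follows it. The modelled peak is floored at `vrest + 2` mV (the
#' passive stimulus response once the fiber is inexcitable).
#'
#' @param vrest resting potential (mV), within \[-100, -30\].
#' @param fiber fiber-truth list (see [ap_peak_model()]).
#' @param protocol an [protocol_config()].
#' @param noise a [noise_config()], or `NULL` for a noise-free trace.
#' @param target_peak,target_half_width optional overrides (mV / ms) of the
#'   modelled peak and half-width.
#' @param width_jitter fractional half-width jitter already drawn for this
#'   stimulation (`NULL` means draw from `noise`).
#' @return an `ap_sweep`; attributes `true_peak`, `true_half_width` and
#'   `true_area` carry the noise-free values (area above -30 mV, artifact
#'   excluded).
#' @export
synthesize_ap <- function(vrest, fiber, protocol, noise = noise_config(),
                          target_peak = NULL, target_half_width = NULL,
                          width_jitter = NULL) {
  if (vrest < -100 || vrest > -30) {
    stop_input("vrest must lie within [-100, -30] mV (got %.2f)", vrest)
  }
  dt <- 1 / protocol$ap_sample_rate_per_ms
  time_ms <- seq(0, protocol$sweep_duration_ms, by = dt)
  peak <- target_peak %||% max(ap_peak_model(vrest, fiber), vrest + 2)
  hw0 <- target_half_width %||% {
    base <- fiber$width0_ms *
      (1 + fiber$width_growth_per_mV * (vrest - protocol$vrest_start_mV))
    # near excitation failure the AP decays into a long depolarized hump:
    # half-width gains ((LV + 30) / (peak + 30))^beta, capped
    u <- max(peak + 30, 0.5)
    u_ref <- fiber$LV + 30
    broad <- min(max((u_ref / u)^(fiber$width_broadening_beta %||% 0), 1),
                 fiber$width_broadening_max %||% 6)
    base * broad
  }
  if (is.null(width_jitter)) {
    width_jitter <- if (is.null(noise)) 0 else stats::rnorm(1, 0, noise$width_jitter_frac)
  }
  hw <- max(hw0 * (1 + width_jitter), 0.3)

  t0 <- protocol$stim_duration_ms + 0.35
  tau_rise <- 0.1
  tau_decay <- .solve_tau_decay(time_ms, t0, vrest, peak, hw, tau_rise)
  u <- .ap_shape(time_ms, t0, tau_rise, tau_decay)
  v <- vrest + (peak - vrest) * u / max(u)

  # noise-free feature values (artifact-free trace)
  true_area <- integral_above(time_ms, v, -30)
  true_hw <- time_above(time_ms, v, vrest + (peak - vrest) / 2)

  # stimulus artifact: large deflection confined to the injection window
  artifact <- time_ms <= protocol$stim_duration_ms + 1e-9
  v[artifact] <- vrest + 90 * (protocol$stim_current_nA / 300)
  if (!is.null(noise) && noise$vm_sd_mV > 0) {
    v <- v + stats::rnorm(length(v), 0, noise$vm_sd_mV)
  }
  sw <- ap_sweep(time_ms, v, vrest = vrest,
                 artifact_window = c(0, protocol$stim_duration_ms),
                 stim_duration_ms = protocol$stim_duration_ms,
                 stim_current_nA = protocol$stim_current_nA)
  attr(sw, "true_peak") <- peak
  attr(sw, "true_half_width") <- true_hw
  attr(sw, "true_area") <- true_area
  sw
}

#' Propagate an AP peak to the far electrode
#'
#' Above the per-fiber conduction threshold (near -21 mV) the AP conducts
#' without decrement (small jitter only). Below it, propagation fails: in
#' `all_or_none` mode the far peak drops suddenly by 30-60 mV; in
#' `continuous` mode it declines steeply (several mV of far peak per mV of
#' near peak below threshold, i.e. >40 mV of far peak over 1-2 mV of resting
#' potential).
#'
#' @param near_peak AP peak at the stimulating electrode (mV).
#' @param fiber fiber-truth list with `conduction_threshold`.
#' @param mode `"all_or_none"` or `"continuous"`.
#' @param noise a [noise_config()], or `NULL`.
#' @return far-electrode AP peak (mV) with attribute `conducted`.
#' @export
apply_conduction <- function(near_peak, fiber, mode = c("all_or_none", "continuous"),
                             noise = noise_config()) {
  mode <- match.arg(mode)
  thr <- fiber$conduction_threshold
  jit <- if (is.null(noise)) 0 else noise$far_peak_jitter_mV
  if (near_peak >= thr) {
    far <- near_peak + stats::rnorm(1, 0, jit)
    attr(far, "conducted") <- TRUE
    return(far)
  }
  far <- if (mode == "all_or_none") {
    near_peak - stats::runif(1, 30, 60)
  } else {
    near_peak - 3 * (thr - near_peak) + stats::rnorm(1, 0, jit)
  }
  attr(far, "conducted") <- FALSE
  far
}

# --- calcium synthesis ------------------------------------------------------

#' Synthesize one stimulation's ROI fluorescence frames
#'
#' Per ROI, the true release amplitude is the saturating (Hill) function of
#' the AP area above the cutoff, times `gain`; beyond a conduction-failure
#' point the amplitude decays passively with the fiber's length constant
#' (0.5 mm). The frame series is
#' `F0 * (1 + amplitude * g(t))` plus shot noise, where `g` is the normalized
#' indicator response and `F0` carries a monotone illumination gradient
#' (1 down to 0.6) across ROIs.
#'
#' @param area_by_roi AP area above the cutoff driving each ROI (mV*ms, >= 0).
#' @param kinetics an `ecc_kinetics`.
#' @param roi_positions_mm ROI positions (mm), ascending.
#' @param protocol an [protocol_config()].
#' @param fiber fiber-truth list (`release_q50`, `release_hill`, `dff_scale`,
#'   `F0_base`).
#' @param gain multiplicative release gain (e.g. the potentiation factor).
#' @param failure_point_mm position beyond which the AP failed to conduct
#'   (`NULL` if it conducted).
#' @param length_constant_mm passive length constant (default 0.5 mm).
#' @param noise a [noise_config()], or `NULL` for noise-free frames.
#' @return a list of class `calcium_sweep` with `fluorescence` (frames x
#'   ROIs), `frame_times_ms`, `roi_positions_mm`, `F0`, and `true_amplitude`.
#' @export
synthesize_calcium <- function(area_by_roi, kinetics, roi_positions_mm,
                               protocol, fiber, gain = 1,
                               failure_point_mm = NULL,
                               length_constant_mm = 0.5,
                               noise = noise_config()) {
  if (length(area_by_roi) != length(roi_positions_mm)) {
    stop_input("area_by_roi and roi_positions_mm must have the same length")
  }
  if (any(area_by_roi < 0)) stop_input("ROI areas must be non-negative")
  if (is.unsorted(roi_positions_mm)) stop_input("roi_positions_mm must be ascending")
  if (fiber$F0_base <= 0) stop_input("fiber F0_base must be positive")
  n_roi <- length(area_by_roi)

  amp <- fiber$dff_scale * gain * .release_sat(area_by_roi, fiber)
  if (!is.null(failure_point_mm)) {
    beyond <- roi_positions_mm > failure_point_mm
    amp[beyond] <- amp[beyond] *
      exp(-(roi_positions_mm[beyond] - failure_point_mm) / length_constant_mm)
  }
  true_amp <- amp
  if (!is.null(noise) && noise$dff_sd > 0) {
    amp <- amp + stats::rnorm(n_roi, 0, noise$dff_sd * fiber$dff_scale)
  }

  illum <- if (n_roi == 1L) 1 else seq(1, 0.6, length.out = n_roi)
  F0 <- fiber$F0_base * illum
  t_ms <- (seq_len(protocol$frames_per_stim) - 1L) * 1000 / protocol$frame_rate_hz
  gnorm <- indicator_response(t_ms, kinetics)
  fl <- outer(gnorm, amp) # frames x ROIs of amplitude * g(t)
  fl <- sweep(1 + fl, 2L, F0, "*")
  if (!is.null(noise) && noise$frame_shot_frac > 0) {
    fl <- fl + matrix(stats::rnorm(length(fl), 0, 1), nrow = nrow(fl)) *
      rep(noise$frame_shot_frac * F0, each = nrow(fl))
  }
  fl <- pmax(fl, 1e-3)
  structure(list(fluorescence = fl, frame_times_ms = t_ms,
                 roi_positions_mm = roi_positions_mm, F0 = F0,
                 true_amplitude = true_amp),
            class = "calcium_sweep")
}

# --- cohort assembly --------------------------------------------------------

#' Generate a seeded synthetic fiber cohort
#'
#' Simulates, for every fiber of every muscle, a full high-K+ infusion run:
#' the resting potential follows an exponential depolarization ramp sampled
#' every `stim_interval_s`, each stimulation yields one AP sweep (recorded at
#' the far electrode in `"far"` mode, after the conduction stage) and one
#' block of ROI fluorescence frames. Ground-truth parameters are drawn from
#' the prior in per-fiber RNG sub-streams and returned in a separate `truth`
#' table that no analysis stage reads.
#'
#' In `"far"` mode, ROIs within the stimulus zone (0.25 mm of the stimulating
#' electrode) retain near-baseline release while the fiber is still locally
#' excitable, emulating the sustained local depolarization produced by the
#' injected current; when conduction fails, release beyond the stimulus zone
#' decays with the 0.5 mm length constant.
#'
#' @param config an [cohort_config()].
#' @return a list of class `ecc_cohort` with data frames `sweeps`, `calcium`,
#'   `metadata`, `truth`, plus `config` and `kinetics`.
#' @export
make_cohort <- function(config) {
  validate_cohort_config(config)
  p <- config$protocol
  kin <- calibrate_kinetics()
  times_s <- seq(0, p$ramp_duration_s, by = p$stim_interval_s)
  ramp <- p$vrest_end_mV - (p$vrest_end_mV - p$vrest_start_mV) * exp(-times_s / p$ramp_tau_s)
  rois <- roi_positions(p)
  stim_zone_mm <- 0.25

  sweeps_l <- list(); calcium_l <- list(); meta_l <- list(); truth_l <- list()
  for (m in seq_len(config$n_muscles)) {
    muscle_id <- sprintf("m%02d", m)
    nf <- if (length(config$fibers_per_muscle) == 2L) {
      with_seed(fiber_seed(config$seed, m, 0L),
                sample(seq.int(config$fibers_per_muscle[1L], config$fibers_per_muscle[2L]), 1L))
    } else config$fibers_per_muscle
    for (f in seq_len(nf)) {
      fiber_id <- sprintf("%s_f%02d", muscle_id, f)
      res <- with_seed(fiber_seed(config$seed, m, f), {
        .simulate_fiber(fiber_id, muscle_id, config, p, kin, times_s, ramp,
                        rois, stim_zone_mm)
      })
      sweeps_l[[fiber_id]] <- res$sweeps
      calcium_l[[fiber_id]] <- res$calcium
      meta_l[[fiber_id]] <- res$metadata
      truth_l[[fiber_id]] <- res$truth
    }
  }
  structure(list(
    sweeps = do.call(rbind, c(sweeps_l, list(make.row.names = FALSE))),
    calcium = do.call(rbind, c(calcium_l, list(make.row.names = FALSE))),
    metadata = do.call(rbind, c(meta_l, list(make.row.names = FALSE))),
    truth = do.call(rbind, c(truth_l, list(make.row.names = FALSE))),
    config = config, kinetics = kin
  ), class = "ecc_cohort")
}

# One fiber's full infusion run (runs inside the fiber's RNG stream).
.simulate_fiber <- function(fiber_id, muscle_id, config, p, kin, times_s, ramp,
                            rois, stim_zone_mm) {
  noise <- config$noise
  truth <- draw_fiber_truth(config$prior, p, config$conduction_mode)
  n_stim <- length(times_s)
  vrest <- ramp + stats::rnorm(n_stim, 0, noise$vrest_jitter_mV)
  vrest <- pmin(pmax(vrest, -99.9), -30.1)
  wjit <- stats::rnorm(n_stim, 0, noise$width_jitter_frac)
  # slow AR(1) drift of the release gain along the run
  drift <- rep(0, n_stim)
  if (noise$dff_drift_sd > 0) {
    phi <- min(noise$dff_drift_phi, 0.999)
    innov <- stats::rnorm(n_stim, 0, noise$dff_drift_sd * sqrt(1 - phi^2))
    drift <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  }
  gain_drift <- pmax(1 + drift, 0.2)
  # partial-activation dropouts once the fiber is substantially depolarized
  eligible <- vrest >= p$vrest_start_mV + noise$dropout_onset_mV
  dropped <- eligible & stats::runif(n_stim) < noise$dropout_prob
  gain_drift[dropped] <- gain_drift[dropped] * stats::runif(sum(dropped), 0.4, 0.85)

  sw_rows <- vector("list", n_stim)
  ca_rows <- vector("list", n_stim)
  md_rows <- vector("list", n_stim)
  for (j in seq_len(n_stim)) {
    near <- synthesize_ap(vrest[j], truth, p, noise = noise, width_jitter = wjit[j])
    near_peak <- attr(near, "true_peak")
    area <- attr(near, "true_area")
    gain <- .pot_gain(vrest[j], truth, p$vrest_start_mV) * gain_drift[j]

    if (p$mode == "far") {
      far_peak <- apply_conduction(near_peak, truth, truth$conduction_kind, noise)
      conducted <- attr(far_peak, "conducted")
      rec <- synthesize_ap(vrest[j], truth, p, noise = noise,
                           target_peak = max(far_peak, vrest[j] + 0.5),
                           width_jitter = wjit[j])
      areas <- rep(area, length(rois))
      if (near_peak > -30) { # stimulus zone: sustained local depolarization
        areas[rois <= stim_zone_mm] <-
          pmax(areas[rois <= stim_zone_mm], 0.92 * truth$baseline_area)
      }
      ca <- synthesize_calcium(areas, kin, rois, p, truth, gain = gain,
                               failure_point_mm = if (conducted) NULL else stim_zone_mm,
                               noise = noise)
      sweep_out <- rec
    } else {
      ca <- synthesize_calcium(rep(area, length(rois)), kin, rois, p, truth,
                               gain = gain, noise = noise)
      sweep_out <- near
    }

    sw_rows[[j]] <- data.frame(
      muscle_id = muscle_id, fiber_id = fiber_id, stim_index = j,
      time_ms = sweep_out$time_ms, voltage_mV = sweep_out$voltage_mV,
      stringsAsFactors = FALSE)
    nfr <- p$frames_per_stim
    ca_rows[[j]] <- data.frame(
      muscle_id = muscle_id, fiber_id = fiber_id, stim_index = j,
      roi_index = rep(seq_along(rois), each = nfr),
      frame_index = rep(seq_len(nfr) - 1L, times = length(rois)),
      fluorescence_au = as.vector(ca$fluorescence),
      stringsAsFactors = FALSE)
    md_rows[[j]] <- data.frame(
      muscle_id = muscle_id, fiber_id = fiber_id, stim_index = j,
      time_s = times_s[j], vrest_mV = vrest[j],
      k_condition_mM = p$k_condition_mM,
      stim_duration_ms = p$stim_duration_ms,
      artifact_ms = p$stim_duration_ms,
      stim_current_nA = p$stim_current_nA,
      stringsAsFactors = FALSE)
  }

  if (config$long_pulse) {
    lp <- .simulate_long_pulse(fiber_id, muscle_id, config, p, kin, truth,
                               times_s, vrest, rois, n_stim, gain_drift, wjit)
    sw_rows <- c(sw_rows, list(lp$sweeps))
    ca_rows <- c(ca_rows, list(lp$calcium))
    md_rows <- c(md_rows, list(lp$metadata))
  }

  truth_df <- data.frame(
    muscle_id = muscle_id, fiber_id = fiber_id,
    LV = truth$LV, HV = truth$HV, V50 = truth$V50, k = truth$k,
    width0_ms = truth$width0_ms,
    width_growth_per_mV = truth$width_growth_per_mV,
    conduction_threshold = truth$conduction_threshold,
    conduction_kind = truth$conduction_kind,
    release_q50 = truth$release_q50, release_hill = truth$release_hill,
    pot_gain = truth$pot_gain, pot_range_mV = truth$pot_range_mV,
    dff_scale = truth$dff_scale, F0_base = truth$F0_base,
    baseline_area = truth$baseline_area,
    sr_availability = truth$sr_availability,
    stringsAsFactors = FALSE)

  list(sweeps = do.call(rbind, sw_rows), calcium = do.call(rbind, ca_rows),
       metadata = do.call(rbind, md_rows), truth = truth_df)
}

# 5 ms "artificial AP" probe appended after the run: a command pulse large
# enough to saturate release, scaled by the fiber's SR availability.
.simulate_long_pulse <- function(fiber_id, muscle_id, config, p, kin, truth,
                                 times_s, vrest, rois, n_stim,
                                 gain_drift = rep(1, n_stim),
                                 wjit = rep(0, n_stim)) {
  noise <- config$noise
  lp_proto <- p
  lp_proto$stim_duration_ms <- 5
  v_end <- vrest[n_stim]
  peak_lp <- stats::runif(1, 10, 35)

  dt <- 1 / p$ap_sample_rate_per_ms
  time_ms <- seq(0, p$sweep_duration_ms, by = dt)
  # square-ish command pulse with rounded edges plus decay back to rest
  u <- stats::plogis((time_ms - 0.5) / 0.15) * (1 - stats::plogis((time_ms - 5.4) / 0.4))
  v <- v_end + (peak_lp - v_end) * u / max(u)
  pulse_area <- integral_above(time_ms, v, -30)
  v[time_ms <= 0.3] <- v_end + 90 # onset artifact only
  if (noise$vm_sd_mV > 0) v <- v + stats::rnorm(length(v), 0, noise$vm_sd_mV)

  # release available to the commanded depolarization, relative to the
  # fiber's reference (-70 mV) response
  ref_j <- which.min(abs(vrest - (-70)))
  ref_gain <- .pot_gain(vrest[ref_j], truth, p$vrest_start_mV) * gain_drift[ref_j]
  ref_area <- synthesize_ap(vrest[ref_j], truth, p, noise = NULL,
                            width_jitter = wjit[ref_j])
  amp_ref <- truth$dff_scale * ref_gain * .release_sat(attr(ref_area, "true_area"), truth)
  # the 5 ms command pulse saturates release; the availability fraction is
  # defined relative to the fiber's reference (-70 mV) AP response
  amp_lp <- truth$sr_availability * amp_ref

  # frames: reuse synthesize_calcium with a uniform pseudo-area whose
  # saturated amplitude equals amp_lp by passing it through gain
  ca <- synthesize_calcium(rep(truth$baseline_area, length(rois)), kin, rois,
                           p, truth,
                           gain = amp_lp / (truth$dff_scale * .release_sat(truth$baseline_area, truth)),
                           noise = noise)
  j <- n_stim + 1L
  nfr <- p$frames_per_stim
  list(
    sweeps = data.frame(
      muscle_id = muscle_id, fiber_id = fiber_id, stim_index = j,
      time_ms = time_ms, voltage_mV = v, stringsAsFactors = FALSE),
    calcium = data.frame(
      muscle_id = muscle_id, fiber_id = fiber_id, stim_index = j,
      roi_index = rep(seq_along(rois), each = nfr),
      frame_index = rep(seq_len(nfr) - 1L, times = length(rois)),
      fluorescence_au = as.vector(ca$fluorescence), stringsAsFactors = FALSE),
    metadata = data.frame(
      muscle_id = muscle_id, fiber_id = fiber_id, stim_index = j,
      time_s = times_s[n_stim] + p$stim_interval_s, vrest_mV = v_end,
      k_condition_mM = p$k_condition_mM, stim_duration_ms = 5,
      artifact_ms = 0.3, stim_current_nA = p$stim_current_nA,
      stringsAsFactors = FALSE))
}

#' @export
print.ecc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ECC cohort: %d muscles, %d fibers, %d stimulations, %s mode\n",
              length(unique(x$metadata$muscle_id)),
              length(unique(x$metadata$fiber_id)),
              nrow(x$metadata), x$config$protocol$mode))
  cat(sprintf("  seed %d; ramp %.0f -> %.0f mV over %.0f s; %d ROI(s)\n",
              x$config$seed, x$config$protocol$vrest_start_mV,
              x$config$protocol$vrest_end_mV, x$config$protocol$ramp_duration_s,
              x$config$protocol$n_rois))
  invisible(x)
}

#' Write / read a cohort dataset as plain-text files
#'
#' Writes `sweeps.csv`, `calcium.csv`, `metadata.csv`, `config.yaml` and the
#' hidden generator parameters as `truth.json` (kept in a separate file that
#' the analysis stages never read).
#'
#' @param cohort an `ecc_cohort`.
#' @param dir output directory (created if needed).
#' @param overwrite overwrite existing files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "ecc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("sweeps.csv", "calcium.csv", "metadata.csv",
                            "truth.json", "config.yaml"))
  if (!overwrite && any(file.exists(paths))) {
    stop_input("output files already exist in '%s' (use overwrite = TRUE)", dir)
  }
  utils::write.csv(cohort$sweeps, paths[1L], row.names = FALSE)
  utils::write.csv(cohort$calcium, paths[2L], row.names = FALSE)
  utils::write.csv(cohort$metadata, paths[3L], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[4L], digits = NA, auto_unbox = TRUE)
  write_cohort_config(cohort$config, paths[5L])
  invisible(dir)
}

#' @rdname write_cohort
#' @param with_truth also load `truth.json` (recovery tests only; analysis
#'   stages must leave this `FALSE`).
#' @export
read_cohort <- function(dir, with_truth = FALSE) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  config <- read_cohort_config(file.path(dir, "config.yaml"))
  structure(list(
    sweeps = rd("sweeps.csv"),
    calcium = rd("calcium.csv"),
    metadata = rd("metadata.csv"),
    truth = if (with_truth) jsonlite::read_json(file.path(dir, "truth.json"),
                                                simplifyVector = TRUE),
    config = config,
    kinetics = calibrate_kinetics()
  ), class = "ecc_cohort")
}
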