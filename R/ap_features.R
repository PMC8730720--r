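#' Construct an action-potential sweep record
#'
#' A sweep holds one stimulation's membrane-voltage trace on a uniform time
#' grid (default 10 samples/ms, i.e. 10 kHz) together with the resting
#' potential and the stimulus-artifact window.
#'
#' @param time_ms uniform, strictly increasing time grid (ms).
#' @param voltage_mV membrane voltage per sample (mV).
#' @param vrest resting potential (mV), within \[-100, -30\].
#' @param artifact_window optional `c(t0, t1)` (ms) marking the stimulus
#'   artifact; samples inside it are excluded from feature searches after
#'   [trim_artifact()].
#' @param stim_duration_ms,stim_current_nA stimulus metadata (optional).
#' @param fiber_id,stim_index identifiers (optional).
#' @return an object of class `ap_sweep`.
#' @export
ap_sweep <- function(time_ms, voltage_mV, vrest,
                     artifact_window = NULL, stim_duration_ms = NA_real_,
                     stim_current_nA = NA_real_, fiber_id = NA_character_,
                     stim_index = NA_integer_) {
  if (length(time_ms) != length(voltage_mV)) {
    stop_input("time and voltage must have the same length")
  }
  if (length(time_ms) < 2L) stop_input("a sweep needs at least 2 samples")
  dt <- diff(time_ms)
  if (any(dt <= 0)) stop_input("time grid must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    stop_input("time grid must be uniform")
  }
  if (!is.finite(vrest) || vrest < -100 || vrest > -30) {
    stop_input("vrest must lie within [-100, -30] mV (got %.2f)", vrest)
  }
  if (!is.null(artifact_window)) {
    if (length(artifact_window) != 2L || artifact_window[2L] < artifact_window[1L]) {
      stop_input("artifact_window must be c(t0, t1) with t1 >= t0")
    }
    if (artifact_window[1L] < time_ms[1L] - 1e-9 ||
        artifact_window[2L] > time_ms[length(time_ms)] + 1e-9) {
      stop_input("artifact_window [%g, %g] lies outside the trace [%g, %g]",
                 artifact_window[1L], artifact_window[2L],
                 time_ms[1L], time_ms[length(time_ms)])
    }
  }
  structure(list(
    time_ms = as.numeric(time_ms), voltage_mV = as.numeric(voltage_mV),
    vrest = vrest, artifact_window = artifact_window,
    stim_duration_ms = stim_duration_ms, stim_current_nA = stim_current_nA,
    fiber_id = fiber_id, stim_index = stim_index,
    excluded = rep(FALSE, length(time_ms))
  ), class = "ap_sweep")
}

#' @export
print.ap_sweep <- function(x, ...) {
  cat(sprintf("AP sweep%s: %d samples, %.2f-%.2f ms, vrest = %.1f mV\n",
              if (is.na(x$fiber_id)) "" else paste0(" [", x$fiber_id, " #", x$stim_index, "]"),
              length(x$time_ms), x$time_ms[1L], x$time_ms[length(x$time_ms)], x$vrest))
  invisible(x)
}

#' Exclude the stimulus artifact from feature searches
#'
#' Marks samples inside the artifact window (widened by a guard on both sides)
#' as excluded; subsequent feature extraction ignores them. Trace values are
#' never modified. A zero-length window leaves the sweep unchanged.
#'
#' @param sweep an `ap_sweep`.
#' @param guard_ms guard added to both sides of the window (default 0.1 ms,
#'   one sample at 10 kHz).
#' @return the sweep with its exclusion mask set.
#' @export
trim_artifact <- function(sweep, guard_ms = 0.1) {
  stopifnot(inherits(sweep, "ap_sweep"))
  w <- sweep$artifact_window
  if (is.null(w) || w[2L] <= w[1L]) return(sweep)
  excl <- sweep$time_ms >= (w[1L] - guard_ms) & sweep$time_ms <= (w[2L] + guard_ms)
  if (all(excl)) {
    stop_input("artifact window (plus guard) excludes the entire trace")
  }
  sweep$excluded <- excl
  sweep
}

.sweep_included <- function(sweep) {
  inc <- !(sweep$excluded %||% rep(FALSE, length(sweep$time_ms)))
  if (!any(inc)) stop_input("all samples of the sweep are excluded")
  inc
}

#' Action-potential peak and amplitude
#'
#' The peak is the maximum voltage outside the excluded artifact window; the
#' amplitude is peak minus resting potential.
#'
#' @param sweep an `ap_sweep` (artifact trimmed with [trim_artifact()] when an
#'   artifact window is present).
#' @return peak voltage (mV) / amplitude (mV).
#' @export
ap_peak <- function(sweep) {
  stopifnot(inherits(sweep, "ap_sweep"))
  max(sweep$voltage_mV[.sweep_included(sweep)])
}

#' @rdname ap_peak
#' @export
ap_amplitude <- function(sweep) {
  ap_peak(sweep) - sweep$vrest
}

#' Action-potential half-width
#'
#' Duration for which the voltage is at or above the half-amplitude level
#' `vrest + amplitude / 2`, with linear interpolation at both crossings. When
#' the level is never reached (zero or negative amplitude) the half-width is
#' undefined and `NA` is returned.
#'
#' @param sweep an `ap_sweep`.
#' @return half-width in ms, or `NA_real_`.
#' @export
ap_half_width <- function(sweep) {
  stopifnot(inherits(sweep, "ap_sweep"))
  inc <- .sweep_included(sweep)
  amp <- ap_amplitude(sweep)
  if (!is.finite(amp) || amp <= 0) return(NA_real_)
  level <- sweep$vrest + amp / 2
  tw <- time_above(sweep$time_ms[inc], sweep$voltage_mV[inc], level)
  if (tw <= 0) NA_real_ else tw
}

#' Integral of the action potential above a voltage cutoff
#'
#' Trapezoidal integral of `max(voltage - cutoff, 0)` over time with linearly
#' interpolated sub-sample crossings. The cutoff (default -30 mV) is the
#' voltage below which action potentials trigger no Ca2+ release, so the area
#' of a sweep peaking at or below the cutoff is exactly 0.
#'
#' @param sweep an `ap_sweep`.
#' @param cutoff cutoff voltage (mV), default -30.
#' @return area in mV*ms (non-negative).
#' @export
area_above <- function(sweep, cutoff = -30) {
  stopifnot(inherits(sweep, "ap_sweep"))
  inc <- .sweep_included(sweep)
  integral_above(sweep$time_ms[inc], sweep$voltage_mV[inc], cutoff)
}

#' Cutoff-normalized AP peaks
#'
#' Peaks at or below the cutoff are set to 0 and the remainder normalized so
#' that the largest peak of the run maps to exactly 1:
#' `max(peak - cutoff, 0) / (max(peaks) - cutoff)`.
#'
#' @param peaks AP peaks of one fiber's run (mV).
#' @param cutoff cutoff voltage (mV), default -30.
#' @return fractions in \[0, 1\]; all zero (with a warning) when every peak is
#'   at or below the cutoff.
#' @export
normalize_peaks <- function(peaks, cutoff = -30) {
  out <- rep(NA_real_, length(peaks))
  ok <- is.finite(peaks)
  if (!any(ok)) return(out)
  m <- max(peaks[ok])
  if (m <= cutoff) {
    warning("all AP peaks are at or below the cutoff; normalized peaks are all 0")
    out[ok] <- 0
    return(out)
  }
  out[ok] <- pmax(peaks[ok] - cutoff, 0) / (m - cutoff)
  out
}

#' Run-maximum-normalized AP areas
#'
#' @param areas AP areas above the cutoff for one fiber's run (mV*ms).
#' @return `areas / max(areas)`; all zero (with a warning) when every area is 0.
#' @export
normalize_areas <- function(areas) {
  out <- rep(NA_real_, length(areas))
  ok <- is.finite(areas)
  if (!any(ok)) return(out)
  m <- max(areas[ok])
  if (m <= 0) {
    warning("all AP areas are zero; normalized areas are all 0")
    out[ok] <- 0
    return(out)
  }
  out[ok] <- areas[ok] / m
  out
}

#' Extract AP features for every sweep of a cohort
#'
#' Applies artifact trimming and computes peak, amplitude, half-width, area
#' above the cutoff, and the per-fiber normalized peak and area for every
#' (fiber, stimulation) in a long table of sweeps.
#'
#' @param sweeps data frame with columns `muscle_id`, `fiber_id`, `stim_index`,
#'   `time_ms`, `voltage_mV` (as written by [write_cohort()]).
#' @param metadata per-stimulation table with columns `fiber_id`, `stim_index`,
#'   `vrest_mV`, `stim_duration_ms`; an optional `artifact_ms` column
#'   overrides the artifact-window length (the long-pulse mode has a 5 ms
#'   command but only a brief onset artifact).
#' @param cutoff voltage cutoff for the AP integral (mV).
#' @param guard_ms artifact guard passed to [trim_artifact()].
#' @return data frame with one row per stimulation: `muscle_id`, `fiber_id`,
#'   `stim_index`, `vrest_mV`, `peak_mV`, `amplitude_mV`, `half_width_ms`,
#'   `area_mVms`, `norm_peak`, `norm_area`.
#' @export
extract_ap_features <- function(sweeps, metadata, cutoff = -30, guard_ms = 0.1) {
  require_columns(sweeps, c("fiber_id", "stim_index", "time_ms", "voltage_mV"), "sweeps")
  require_columns(metadata, c("fiber_id", "stim_index", "vrest_mV", "stim_duration_ms"), "metadata")
  meta_key <- paste(metadata$fiber_id, metadata$stim_index)
  groups <- split(seq_len(nrow(sweeps)), paste(sweeps$fiber_id, sweeps$stim_index))
  rows <- lapply(names(groups), function(key) {
    idx <- groups[[key]]
    mi <- match(key, meta_key)
    if (is.na(mi)) stop_input("no metadata row for sweep '%s'", key)
    md <- metadata[mi, ]
    art <- if ("artifact_ms" %in% names(md)) md$artifact_ms else md$stim_duration_ms
    sw <- ap_sweep(
      time_ms = sweeps$time_ms[idx], voltage_mV = sweeps$voltage_mV[idx],
      vrest = md$vrest_mV,
      artifact_window = c(0, art),
      stim_duration_ms = md$stim_duration_ms,
      fiber_id = md$fiber_id, stim_index = md$stim_index
    )
    sw <- trim_artifact(sw, guard_ms = guard_ms)
    data.frame(
      muscle_id = if ("muscle_id" %in% names(md)) md$muscle_id else NA_character_,
      fiber_id = md$fiber_id, stim_index = md$stim_index,
      vrest_mV = md$vrest_mV,
      peak_mV = ap_peak(sw), amplitude_mV = ap_amplitude(sw),
      half_width_ms = ap_half_width(sw),
      area_mVms = area_above(sw, cutoff = cutoff),
      stringsAsFactors = FALSE
    )
  })
  feats <- do.call(rbind, rows)
  feats <- feats[order(feats$fiber_id, feats$stim_index), ]
  feats$norm_peak <- NA_real_
  feats$norm_area <- NA_real_
  for (fid in unique(feats$fiber_id)) {
    sel <- feats$fiber_id == fid
    feats$norm_peak[sel] <- normalize_peaks(feats$peak_mV[sel], cutoff = cutoff)
    feats$norm_area[sel] <- normalize_areas(feats$area_mVms[sel])
  }
  rownames(feats) <- NULL
  feats
}
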