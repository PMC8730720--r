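#' Compute dF/F from raw fluorescence frames
#'
#' The background `F0` of each ROI is the mean fluorescence over the
#' background frames (the signal between stimuli), and the dF/F series is
#' `(F - F0) / F0`. Because the ratio is taken per ROI, multiplicative
#' illumination gradients along the fiber cancel exactly.
#'
#' @param fluorescence numeric matrix, frames x ROIs (arbitrary units).
#' @param background_frames integer indices of the frames used as background.
#' @return list with `dff` (frames x ROIs matrix) and `F0` (per-ROI vector).
#' @export
compute_dff <- function(fluorescence, background_frames) {
  fluorescence <- as.matrix(fluorescence)
  if (length(background_frames) < 1L) stop_input("background_frames must not be empty")
  if (any(background_frames < 1L) || any(background_frames > nrow(fluorescence))) {
    stop_input("background_frames out of range (1..%d)", nrow(fluorescence))
  }
  F0 <- colMeans(fluorescence[background_frames, , drop = FALSE])
  bad <- which(!is.finite(F0) | F0 <= 0)
  if (length(bad) > 0L) {
    stop_input("non-positive background F0 for ROI(s): %s", paste(bad, collapse = ", "))
  }
  dff <- sweep(sweep(fluorescence, 2L, F0, "-"), 2L, F0, "/")
  list(dff = dff, F0 = F0)
}

#' Peak of a dF/F series
#'
#' Maximum of the series inside the search window. With a 30 frames/s capture
#' and slow indicator kinetics (time to peak near 44 ms) the best frame
#' slightly underestimates the continuous peak.
#'
#' @param series numeric dF/F series for one ROI.
#' @param window frame indices to search (default: all frames).
#' @return the peak dF/F (fraction).
#' @export
dff_peak <- function(series, window = seq_along(series)) {
  if (length(window) < 1L) stop_input("empty peak search window")
  if (any(window < 1L) || any(window > length(series))) {
    stop_input("peak search window out of range (1..%d)", length(series))
  }
  max(series[window])
}

#' Normalize a run of dF/F peaks to the -70 mV reference
#'
#' The reference stimulation is the one whose resting potential is closest to
#' `ref_mV` (within `tol`); every dF/F peak of the run is divided by the
#' reference value, so the reference stimulation normalizes to 1.
#'
#' @param dff_peaks per-stimulation dF/F peaks of one ROI.
#' @param vrest_mV resting potential of each stimulation (mV).
#' @param ref_mV reference resting potential (default -70 mV).
#' @param tol admissible distance from `ref_mV` (default 2 mV).
#' @return list with `norm` (normalized values) and `ref_index` (index of the
#'   reference stimulation).
#' @export
normalize_to_ref70 <- function(dff_peaks, vrest_mV, ref_mV = -70, tol = 2) {
  if (length(dff_peaks) != length(vrest_mV)) {
    stop_input("dff_peaks and vrest_mV must have the same length")
  }
  d <- abs(vrest_mV - ref_mV)
  i <- which.min(d)
  if (length(i) == 0L || !is.finite(d[i]) || d[i] > tol) {
    stop_input("no stimulation within %.1f mV of %.1f mV (resting potentials span [%.1f, %.1f])",
               tol, ref_mV, min(vrest_mV, na.rm = TRUE), max(vrest_mV, na.rm = TRUE))
  }
  ref <- dff_peaks[i]
  if (!is.finite(ref) || ref <= 0) {
    stop_input("reference dF/F at %.1f mV is not positive (%.3g)", vrest_mV[i], ref)
  }
  list(norm = dff_peaks / ref, ref_index = i)
}

#' Normalize a run of dF/F peaks to the run maximum
#'
#' @param dff_peaks per-stimulation dF/F peaks of one ROI.
#' @return `dff_peaks / max(dff_peaks)`; all zeros (with a warning) when the
#'   run maximum is not positive.
#' @export
normalize_to_runmax <- function(dff_peaks) {
  ok <- is.finite(dff_peaks)
  if (!any(ok) || max(dff_peaks[ok]) <= 0) {
    warning("run maximum of dF/F is not positive; normalized values are all 0")
    out <- rep(0, length(dff_peaks))
    out[!ok] <- NA_real_
    return(out)
  }
  dff_peaks / max(dff_peaks[ok])
}

#' Extract dF/F features for every stimulation and ROI of a cohort
#'
#' Reconstructs per-stimulation frame blocks from the long fluorescence table,
#' computes the background from the signal between stimuli (the last
#' `background_n` frames of the preceding block; the first stimulation uses
#' its own pre-response frame at t = 0), and returns the per-ROI dF/F peak
#' together with both normalization conventions.
#'
#' @param calcium data frame with columns `fiber_id`, `stim_index`,
#'   `roi_index`, `frame_index`, `fluorescence_au` (as written by
#'   [write_cohort()]).
#' @param metadata per-stimulation table with `fiber_id`, `stim_index`,
#'   `vrest_mV`.
#' @param background_n number of trailing frames of the preceding block used
#'   as background (default 10).
#' @param ref_mV,ref_tol reference resting potential and tolerance for
#'   [normalize_to_ref70()].
#' @return data frame with one row per (fiber, stimulation, ROI):
#'   `muscle_id`, `fiber_id`, `stim_index`, `roi_index`, `dff_peak`,
#'   `norm_ref70`, `norm_runmax`, `ref_stim_index`, `background_F0`.
#' @export
extract_calcium_features <- function(calcium, metadata, background_n = 10L,
                                     ref_mV = -70, ref_tol = 2) {
  require_columns(calcium, c("fiber_id", "stim_index", "roi_index",
                             "frame_index", "fluorescence_au"), "calcium")
  require_columns(metadata, c("fiber_id", "stim_index", "vrest_mV"), "metadata")

  out <- list()
  for (fid in unique(calcium$fiber_id)) {
    cal <- calcium[calcium$fiber_id == fid, ]
    md <- metadata[metadata$fiber_id == fid, ]
    md <- md[order(md$stim_index), ]
    stims <- md$stim_index
    rois <- sort(unique(cal$roi_index))
    # frames x ROIs matrix per stimulation
    blocks <- lapply(stims, function(s) {
      b <- cal[cal$stim_index == s, ]
      b <- b[order(b$roi_index, b$frame_index), ]
      matrix(b$fluorescence_au, ncol = length(rois),
             dimnames = list(NULL, rois))
    })
    n_frames <- nrow(blocks[[1L]])
    peaks <- matrix(NA_real_, nrow = length(stims), ncol = length(rois))
    f0s <- matrix(NA_real_, nrow = length(stims), ncol = length(rois))
    for (j in seq_along(stims)) {
      if (j == 1L) {
        bg_mat <- blocks[[1L]][1L, , drop = FALSE] # t = 0 pre-response frame
      } else {
        prev <- blocks[[j - 1L]]
        bg_rows <- seq.int(max(1L, nrow(prev) - background_n + 1L), nrow(prev))
        bg_mat <- prev[bg_rows, , drop = FALSE]
      }
      F0 <- colMeans(bg_mat)
      bad <- which(!is.finite(F0) | F0 <= 0)
      if (length(bad) > 0L) {
        stop_input("fiber %s stim %s: non-positive background F0 for ROI(s) %s",
                   fid, stims[j], paste(rois[bad], collapse = ", "))
      }
      dff <- sweep(sweep(blocks[[j]], 2L, F0, "-"), 2L, F0, "/")
      peaks[j, ] <- apply(dff, 2L, max)
      f0s[j, ] <- F0
    }
    ref_idx <- normalize_to_ref70(peaks[, 1L], md$vrest_mV,
                                  ref_mV = ref_mV, tol = ref_tol)$ref_index
    for (r in seq_along(rois)) {
      ref <- peaks[ref_idx, r]
      norm70 <- if (is.finite(ref) && ref > 0) peaks[, r] / ref else rep(NA_real_, length(stims))
      normmax <- suppressWarnings(normalize_to_runmax(peaks[, r]))
      out[[length(out) + 1L]] <- data.frame(
        muscle_id = if ("muscle_id" %in% names(md)) md$muscle_id else NA_character_,
        fiber_id = fid, stim_index = stims, roi_index = rois[r],
        dff_peak = peaks[, r], norm_ref70 = norm70, norm_runmax = normmax,
        ref_stim_index = stims[ref_idx], background_F0 = f0s[, r],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$fiber_id, res$stim_index, res$roi_index), ]
  rownames(res) <- NULL
  res
}
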