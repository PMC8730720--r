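#' Classify ECC success from far-ROI normalized dF/F
#'
#' A stimulation's ECC is `success` when the normalized dF/F at the ROI of
#' the recording electrode is at least `success_min` (default 0.75 of its
#' value at the -70 mV reference), `fail` when it is at most `fail_max`
#' (default 0.25), and `indeterminate` in between. Both thresholds are
#' inclusive toward the definite classes. Negative values (noise) are clipped
#' to 0 for classification only.
#'
#' @param norm_dff_far normalized far-ROI dF/F, vectorized.
#' @param success_min,fail_max classification thresholds.
#' @return factor with levels `success`, `indeterminate`, `fail`.
#' @export
classify_ecc <- function(norm_dff_far, success_min = 0.75, fail_max = 0.25) {
  if (any(!is.finite(norm_dff_far))) {
    stop_input("norm_dff_far contains non-finite values (missing reference normalization?)")
  }
  x <- pmax(norm_dff_far, 0)
  lab <- ifelse(x >= success_min, "success",
         ifelse(x <= fail_max, "fail", "indeterminate"))
  factor(lab, levels = c("success", "indeterminate", "fail"))
}

#' Locate the conduction transition of one fiber's run
#'
#' The transition is defined by the last stimulation labelled `success` and
#' the first stimulation labelled `fail` after it; `indeterminate`
#' stimulations in between are skipped and never counted as either class.
#' A `fail` that recovers before the last success is logged as an anomaly
#' but does not move the transition.
#'
#' @param run data frame for one fiber, ordered by `stim_index`, with columns
#'   `stim_index`, `label` (from [classify_ecc()]), `vrest_mV`, and optionally
#'   `peak_mV`, `norm_area`, `dff_far`, `dff_near`.
#' @return a one-row data frame of class `ecc_transition`:
#'   `last_success_index`, `first_fail_index`, `vrest_last_success`,
#'   `vrest_first_fail`, `d_vrest`, plus the AP peak, normalized integral and
#'   near/far dF/F at the two transition stimulations where available.
#' @export
find_transition <- function(run) {
  require_columns(run, c("stim_index", "label", "vrest_mV"), "run")
  run <- run[order(run$stim_index), ]
  lab <- as.character(run$label)
  succ <- which(lab == "success")
  if (length(succ) == 0L) {
    stop_input("no stimulation labelled 'success' in the run; transition not found")
  }
  last_success <- succ[length(succ)]
  fail_after <- which(lab == "fail" & seq_along(lab) > last_success)
  if (length(fail_after) == 0L) {
    stop_input("no 'fail' after the last 'success'; transition not found (run ends %s)",
               lab[length(lab)])
  }
  first_fail <- fail_after[1L]
  relapse <- which(lab == "fail" & seq_along(lab) < last_success)
  if (length(relapse) > 0L) {
    message(sprintf("fiber %s: %d fail label(s) before the last success (anomaly, ignored)",
                    run$fiber_id[1L] %||% "?", length(relapse)))
  }
  col_or_na <- function(col, i) if (col %in% names(run)) run[[col]][i] else NA_real_
  structure(data.frame(
    fiber_id = if ("fiber_id" %in% names(run)) run$fiber_id[1L] else NA_character_,
    muscle_id = if ("muscle_id" %in% names(run)) run$muscle_id[1L] else NA_character_,
    last_success_index = run$stim_index[last_success],
    first_fail_index = run$stim_index[first_fail],
    vrest_last_success = run$vrest_mV[last_success],
    vrest_first_fail = run$vrest_mV[first_fail],
    d_vrest = run$vrest_mV[first_fail] - run$vrest_mV[last_success],
    peak_last_success = col_or_na("peak_mV", last_success),
    peak_first_fail = col_or_na("peak_mV", first_fail),
    norm_integral_last_success = col_or_na("norm_area", last_success),
    norm_integral_first_fail = col_or_na("norm_area", first_fail),
    dff_far_last_success = col_or_na("dff_far", last_success),
    dff_far_first_fail = col_or_na("dff_far", first_fail),
    dff_near_at_fail = col_or_na("dff_near", first_fail),
    stringsAsFactors = FALSE
  ), class = c("ecc_transition", "data.frame"))
}

#' Near/far dF/F gradient along the fiber
#'
#' Summarizes the spatial profile of normalized dF/F for one stimulation:
#' the values at the ROIs nearest the stimulating and recording electrodes,
#' and the position at which the profile first drops below 0.5 (linearly
#' interpolated; `NA` when it never does).
#'
#' @param dff_by_roi normalized dF/F per ROI.
#' @param roi_positions_mm ROI positions (mm), ascending.
#' @return list with `near`, `far`, and `half_cross_mm`.
#' @export
near_far_gradient <- function(dff_by_roi, roi_positions_mm) {
  if (length(dff_by_roi) < 2L) stop_input("need at least 2 ROIs for a gradient")
  if (length(dff_by_roi) != length(roi_positions_mm)) {
    stop_input("dff_by_roi and roi_positions_mm must have the same length")
  }
  ord <- order(roi_positions_mm)
  x <- roi_positions_mm[ord]
  y <- dff_by_roi[ord]
  below <- which(y < 0.5)
  cross <- NA_real_
  if (length(below) > 0L) {
    i <- below[1L]
    if (i == 1L) {
      cross <- x[1L]
    } else {
      cross <- x[i - 1L] + (0.5 - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
    }
  }
  list(near = y[1L], far = y[length(y)], half_cross_mm = cross)
}

#' Classify every stimulation of a cohort and extract transitions
#'
#' Labels each stimulation by the normalized dF/F of the ROI at the recording
#' electrode and locates each fiber's conduction transition. Fibers whose runs
#' never reach a definite `fail` after a `success` (or never succeed) are
#' excluded from the transition table and reported in the `skipped` attribute.
#'
#' @param dff dF/F feature table from [extract_calcium_features()].
#' @param metadata per-stimulation metadata table.
#' @param features optional AP feature table from [extract_ap_features()]
#'   (adds AP peak and normalized integral to the transition metrics).
#' @param success_min,fail_max classification thresholds.
#' @return list with `classification` (one row per stimulation: `muscle_id`,
#'   `fiber_id`, `stim_index`, `vrest_mV`, `norm_dff_far`, `label`),
#'   `transitions` (one `ecc_transition` row per fiber), and `skipped`
#'   (fiber ids without a definite transition).
#' @export
classify_cohort <- function(dff, metadata, features = NULL,
                            success_min = 0.75, fail_max = 0.25) {
  require_columns(dff, c("fiber_id", "stim_index", "roi_index", "norm_ref70"), "dff")
  require_columns(metadata, c("fiber_id", "stim_index", "vrest_mV"), "metadata")
  far_roi <- max(dff$roi_index)
  near_roi <- min(dff$roi_index)
  cls_l <- list(); tr_l <- list(); skipped <- character(0)
  for (fid in unique(dff$fiber_id)) {
    far <- dff[dff$fiber_id == fid & dff$roi_index == far_roi, ]
    near <- dff[dff$fiber_id == fid & dff$roi_index == near_roi, ]
    md <- metadata[metadata$fiber_id == fid, c("muscle_id", "fiber_id", "stim_index", "vrest_mV")]
    run <- merge(md, far[, c("stim_index", "norm_ref70")], by = "stim_index")
    names(run)[names(run) == "norm_ref70"] <- "norm_dff_far"
    run <- run[order(run$stim_index), ]
    run$label <- classify_ecc(run$norm_dff_far, success_min, fail_max)
    cls_l[[fid]] <- run[, c("muscle_id", "fiber_id", "stim_index", "vrest_mV",
                            "norm_dff_far", "label")]
    trun <- run
    trun$dff_far <- trun$norm_dff_far
    trun$dff_near <- near$norm_ref70[match(trun$stim_index, near$stim_index)]
    if (!is.null(features)) {
      fi <- features[features$fiber_id == fid, c("stim_index", "peak_mV", "norm_area")]
      trun <- merge(trun, fi, by = "stim_index", all.x = TRUE)
      trun <- trun[order(trun$stim_index), ]
    }
    tr <- tryCatch(find_transition(trun), error = function(e) {
      skipped <<- c(skipped, fid)
      message(sprintf("fiber %s excluded from transition aggregates: %s",
                      fid, conditionMessage(e)))
      NULL
    })
    if (!is.null(tr)) tr_l[[fid]] <- tr
  }
  list(
    classification = do.call(rbind, c(cls_l, list(make.row.names = FALSE))),
    transitions = if (length(tr_l) > 0L) do.call(rbind, c(tr_l, list(make.row.names = FALSE))),
    skipped = skipped
  )
}
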