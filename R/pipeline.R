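#' Fit the three Boltzmann relationships for every fiber
#'
#' Per fiber: (1) AP peak against resting potential (`peak_vs_vrest` preset),
#' (2) reference-normalized dF/F against resting potential (`dff_vs_vrest`
#' preset), restricted to stimulations depolarized beyond the reference
#' (`vrest >= ref_mV`), and (3) reference-normalized dF/F against AP peak
#' (`dff_vs_peak` preset), over the whole run.
#'
#' @param features AP feature table from [extract_ap_features()].
#' @param dff dF/F feature table from [extract_calcium_features()].
#' @param roi_index ROI whose dF/F is fitted (default: the ROI nearest the
#'   stimulating electrode).
#' @param ref_mV resting potential of the dF/F reference (default -70).
#' @return data frame of class `ecc_fits` with one row per fiber and
#'   relationship (`LV`, `HV`, `V50`, `k`, `rss`, `n_points`, `converged`,
#'   `half_max_output`, `span_10_90`); the full `boltzmann_fit` objects are
#'   attached as attribute `"fits"`.
#' @export
fit_cohort <- function(features, dff, roi_index = NULL, ref_mV = -70) {
  require_columns(features, c("fiber_id", "stim_index", "vrest_mV", "peak_mV"), "features")
  require_columns(dff, c("fiber_id", "stim_index", "roi_index", "norm_ref70"), "dff")
  if (is.null(roi_index)) roi_index <- min(dff$roi_index)
  d <- dff[dff$roi_index == roi_index, ]
  fits <- list()
  rows <- list()
  for (fid in unique(features$fiber_id)) {
    f <- features[features$fiber_id == fid, ]
    f <- f[order(f$stim_index), ]
    dfib <- d[d$fiber_id == fid, ]
    y70 <- dfib$norm_ref70[match(f$stim_index, dfib$stim_index)]
    sets <- list(
      peak_vs_vrest = list(x = f$vrest_mV, y = f$peak_mV),
      dff_vs_vrest = list(x = f$vrest_mV[f$vrest_mV >= ref_mV],
                          y = y70[f$vrest_mV >= ref_mV]),
      dff_vs_peak = list(x = f$peak_mV, y = y70)
    )
    for (rel in names(sets)) {
      fit <- tryCatch(
        fit_boltzmann(sets[[rel]]$x, sets[[rel]]$y, config = boltzmann_preset(rel)),
        error = function(e) {
          warning(sprintf("fiber %s, %s: %s", fid, rel, conditionMessage(e)))
          NULL
        })
      if (is.null(fit)) next
      fits[[paste(fid, rel, sep = ".")]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        muscle_id = if ("muscle_id" %in% names(f)) f$muscle_id[1L] else NA_character_,
        fiber_id = fid, relationship = rel,
        LV = fit$params[["LV"]], HV = fit$params[["HV"]],
        V50 = fit$params[["V50"]], k = fit$params[["k"]],
        rss = fit$rss, n_points = fit$n_points, converged = fit$converged,
        half_max_output = fit$half_max_output, span_10_90 = fit$span_10_90,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "fits") <- fits
  class(res) <- c("ecc_fits", "data.frame")
  res
}

.stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[eccfail] ", fmt), ...))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates generate -> AP features -> dF/F -> Boltzmann fits ->
#' classification -> report as a file-based, reproducible pipeline. Each
#' stage reads only the plain-text artifacts of the previous stages (never
#' `truth.json`), writes its output into `out_dir`, and is skipped when its
#' output already exists unless `force = TRUE`. A manifest with the seed, a
#' configuration hash and per-file checksums is written at the end.
#'
#' Artifacts: `sweeps.csv`, `calcium.csv`, `metadata.csv`, `truth.json`,
#' `config.yaml`, `features.csv`, `dff.csv`, `fits.json`,
#' `classification.csv`, `transitions.csv` (far mode only), `summary.json`,
#' `manifest.json`.
#'
#' @param out_dir output directory.
#' @param config an [cohort_config()] describing the cohort.
#' @param seed optional override of `config$seed`.
#' @param cutoff AP integral voltage cutoff (mV).
#' @param ref_mV,ref_tol dF/F reference resting potential and tolerance.
#' @param success_min,fail_max ECC classification thresholds.
#' @param force rerun all stages even when outputs exist.
#' @param quiet suppress stage messages.
#' @return the manifest, invisibly.
#' @export
run_ecc_pipeline <- function(out_dir, config = cohort_config(), seed = NULL,
                             cutoff = -30, ref_mV = -70, ref_tol = 2,
                             success_min = 0.75, fail_max = 0.25,
                             force = FALSE, quiet = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_cohort_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  # a stage reruns when forced, when its output is missing, or when any of
  # its inputs is newer than its output
  fresh <- function(f, deps = character(0)) {
    if (force || !file.exists(path(f))) return(TRUE)
    length(deps) > 0L &&
      any(file.mtime(path(deps)) > file.mtime(path(f)), na.rm = TRUE)
  }

  # stage: generate
  if (fresh("sweeps.csv")) {
    .stage_log(quiet, "generate: cohort seed %d (%s mode)", config$seed,
               config$protocol$mode)
    write_cohort(make_cohort(config), out_dir, overwrite = TRUE)
  } else .stage_log(quiet, "generate: outputs exist, skipped")

  metadata <- utils::read.csv(path("metadata.csv"), stringsAsFactors = FALSE)

  # stage: AP features
  if (fresh("features.csv", c("sweeps.csv", "metadata.csv"))) {
    .stage_log(quiet, "extract-ap: cutoff %.0f mV", cutoff)
    sweeps <- utils::read.csv(path("sweeps.csv"), stringsAsFactors = FALSE)
    feats <- extract_ap_features(sweeps, metadata, cutoff = cutoff)
    utils::write.csv(feats, path("features.csv"), row.names = FALSE)
  } else .stage_log(quiet, "extract-ap: outputs exist, skipped")
  feats <- utils::read.csv(path("features.csv"), stringsAsFactors = FALSE)

  # stage: dF/F
  if (fresh("dff.csv", c("calcium.csv", "metadata.csv"))) {
    .stage_log(quiet, "extract-ca: reference %.0f mV (tol %.1f)", ref_mV, ref_tol)
    calcium <- utils::read.csv(path("calcium.csv"), stringsAsFactors = FALSE)
    dff <- extract_calcium_features(calcium, metadata, ref_mV = ref_mV,
                                    ref_tol = ref_tol)
    utils::write.csv(dff, path("dff.csv"), row.names = FALSE)
  } else .stage_log(quiet, "extract-ca: outputs exist, skipped")
  dff <- utils::read.csv(path("dff.csv"), stringsAsFactors = FALSE)

  # stage: Boltzmann fits
  if (fresh("fits.json", c("features.csv", "dff.csv"))) {
    .stage_log(quiet, "fit: three constrained Boltzmann relationships per fiber")
    fits <- fit_cohort(feats, dff, ref_mV = ref_mV)
    fit_objs <- attr(fits, "fits")
    payload <- lapply(fit_objs, function(ft) list(
      params = as.list(ft$params), fixed = as.list(ft$fixed),
      lower = as.list(ft$lower), upper = as.list(ft$upper),
      rss = ft$rss, n_points = ft$n_points, converged = ft$converged,
      half_max_output = ft$half_max_output, span_10_90 = ft$span_10_90,
      relationship = ft$config))
    jsonlite::write_json(list(seed = config$seed, fits = payload),
                         path("fits.json"), digits = NA, auto_unbox = TRUE)
    utils::write.csv(as.data.frame(fits), path("fits.csv"), row.names = FALSE)
  } else .stage_log(quiet, "fit: outputs exist, skipped")
  fits_df <- utils::read.csv(path("fits.csv"), stringsAsFactors = FALSE)

  # stage: classification (needs a spatial ROI profile)
  has_profile <- length(unique(dff$roi_index)) > 1L
  if (has_profile && fresh("classification.csv", c("dff.csv", "features.csv", "metadata.csv"))) {
    .stage_log(quiet, "classify: thresholds %.2f / %.2f", success_min, fail_max)
    cls <- classify_cohort(dff, metadata, features = feats,
                           success_min = success_min, fail_max = fail_max)
    utils::write.csv(cls$classification, path("classification.csv"), row.names = FALSE)
    if (!is.null(cls$transitions)) {
      utils::write.csv(as.data.frame(cls$transitions), path("transitions.csv"),
                       row.names = FALSE)
    }
  } else if (has_profile) {
    .stage_log(quiet, "classify: outputs exist, skipped")
  }

  # stage: report
  if (fresh("summary.json", c("features.csv", "dff.csv", "fits.csv"))) {
    .stage_log(quiet, "report: cohort summary")
    summary <- .cohort_summary(config, feats, dff, fits_df,
                               if (has_profile && file.exists(path("transitions.csv")))
                                 utils::read.csv(path("transitions.csv"), stringsAsFactors = FALSE))
    jsonlite::write_json(summary, path("summary.json"), digits = NA, auto_unbox = TRUE)
    .write_report_md(path("report.md"), summary)
  } else .stage_log(quiet, "report: outputs exist, skipped")

  files <- c("sweeps.csv", "calcium.csv", "metadata.csv", "truth.json",
             "config.yaml", "features.csv", "dff.csv", "fits.json", "fits.csv",
             "classification.csv", "transitions.csv", "summary.json", "report.md")
  files <- files[file.exists(path(files))]
  manifest <- list(
    tool = "eccfail", version = as.character(utils::packageVersion("eccfail")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(path("config.yaml"))),
    files = as.list(stats::setNames(unname(tools::md5sum(path(files))), files))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  .stage_log(quiet, "done: %d artifacts in %s", length(files) + 1L, out_dir)
  invisible(manifest)
}

# Cohort-level summary tables for summary.json / report.md.
.cohort_summary <- function(config, feats, dff, fits_df, transitions = NULL) {
  out <- list(seed = config$seed, mode = config$protocol$mode,
              n_muscles = length(unique(feats$muscle_id)),
              n_fibers = length(unique(feats$fiber_id)),
              n_stimulations = nrow(feats))
  fit_means <- lapply(split(fits_df[fits_df$converged, ], fits_df$relationship[fits_df$converged]),
    function(g) list(
      n_fibers = nrow(g),
      V50 = list(mean = mean(g$V50), sd = stats::sd(g$V50)),
      k = list(mean = mean(g$k), sd = stats::sd(g$k)),
      half_max_output = list(mean = mean(g$half_max_output),
                             sd = stats::sd(g$half_max_output)),
      span_10_90 = list(mean = mean(g$span_10_90), sd = stats::sd(g$span_10_90))))
  out$boltzmann <- fit_means

  roi0 <- min(dff$roi_index)
  d0 <- dff[dff$roi_index == roi0, ]
  first <- d0[!is.na(d0$norm_runmax), ]
  first <- first[order(first$fiber_id, first$stim_index), ]
  first <- first[!duplicated(first$fiber_id), ]
  out$potentiation <- list(
    first_stim_norm_runmax = list(mean = mean(first$norm_runmax),
                                  sd = stats::sd(first$norm_runmax),
                                  n = nrow(first)))

  r2 <- tryCatch(correlate_cohort(feats, dff), error = function(e) NULL)
  if (!is.null(r2)) {
    out$correlations <- list(
      r2_area = list(mean = mean(r2$r2_area), sd = stats::sd(r2$r2_area)),
      r2_peak = list(mean = mean(r2$r2_peak), sd = stats::sd(r2$r2_peak)),
      n_fibers = nrow(r2))
  }

  if (!is.null(transitions) && nrow(transitions) > 0L) {
    agg <- aggregate_cohort(transitions,
                            c("d_vrest", "peak_last_success", "peak_first_fail",
                              "dff_far_last_success", "dff_far_first_fail",
                              "dff_near_at_fail"), level = "muscle")
    out$transition <- stats::setNames(
      lapply(seq_len(nrow(agg)), function(i) list(mean = agg$mean[i], sd = agg$sd[i],
                                                  n_muscles = agg$n_groups[i])),
      agg$quantity)
  }
  out
}

.write_report_md <- function(path, s) {
  lines <- c(
    "# ECC failure analysis report", "",
    sprintf("Seed %d, %s-electrode mode: %d muscles, %d fibers, %d stimulations.",
            s$seed, s$mode, s$n_muscles, s$n_fibers, s$n_stimulations), "",
    "## Boltzmann fits (cohort mean +/- SD over fibers)", "")
  for (rel in names(s$boltzmann)) {
    b <- s$boltzmann[[rel]]
    lines <- c(lines, sprintf(
      "- %s (n = %d): V50 = %.1f +/- %.1f mV, k = %.2f +/- %.2f mV, half-max output = %.2f +/- %.2f",
      rel, b$n_fibers, b$V50$mean, b$V50$sd, b$k$mean, b$k$sd,
      b$half_max_output$mean, b$half_max_output$sd))
  }
  p <- s$potentiation$first_stim_norm_runmax
  lines <- c(lines, "",
             sprintf("First-stimulation run-max-normalized dF/F: %.2f +/- %.2f (n = %d fibers).",
                     p$mean, p$sd, p$n))
  if (!is.null(s$correlations)) {
    lines <- c(lines, "", sprintf(
      "Per-fiber R^2 of normalized dF/F: vs AP area %.2f +/- %.2f, vs AP peak %.2f +/- %.2f (n = %d).",
      s$correlations$r2_area$mean, s$correlations$r2_area$sd,
      s$correlations$r2_peak$mean, s$correlations$r2_peak$sd,
      s$correlations$n_fibers))
  }
  if (!is.null(s$transition)) {
    tv <- s$transition$d_vrest
    lines <- c(lines, "", sprintf(
      "Conduction transition: resting-potential gap %.2f +/- %.2f mV (muscle means, n = %d).",
      tv$mean, tv$sd, tv$n_muscles))
  }
  writeLines(lines, path)
}
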