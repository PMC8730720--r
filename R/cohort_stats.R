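#' Squared Pearson correlation
#'
#' R-squared of the ordinary least-squares line, computed as the squared
#' Pearson correlation of `x` and `y`.
#'
#' @param x,y numeric vectors of equal length (>= 3 points, both with
#'   positive variance).
#' @return R-squared in \[0, 1\].
#' @export
linear_r2 <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_input("linear_r2 needs at least 3 finite points, got %d", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_input("linear_r2 undefined: zero variance in %s",
               if (stats::sd(x) == 0) "x" else "y")
  }
  unname(stats::cor(x, y)^2)
}

#' Paired Student's t-test
#'
#' Two-sided paired t statistic on the within-pair differences `a - b`.
#'
#' @param a,b paired measurements of equal length (n >= 2).
#' @return list with `t`, `p` (two-sided), `df`, and `n`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop_input("paired_t needs sequences of equal length")
  keep <- is.finite(a) & is.finite(b)
  d <- (a - b)[keep]
  n <- length(d)
  if (n < 2L) stop_input("paired_t needs at least 2 complete pairs, got %d", n)
  s <- stats::sd(d)
  if (s == 0) stop_input("paired_t undefined: all paired differences are equal")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1, n = n)
}

#' R-squared of normalized data against the identity line
#'
#' Fraction of the variance of `y` explained by the model `y = x`:
#' `1 - sum((y - x)^2) / sum((y - mean(y))^2)`. This is the comparison drawn
#' when run-max-normalized dF/F is plotted against the normalized AP area or
#' peak with the line of identity as the reference; unlike the squared
#' Pearson correlation it penalizes systematic departures from that line.
#' Can be negative when the identity line fits worse than the mean.
#'
#' @param x,y normalized quantities of equal length (>= 3 finite pairs).
#' @return identity-line R-squared (at most 1).
#' @export
identity_r2 <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_input("identity_r2 needs at least 3 finite points, got %d", length(x))
  ss <- sum((y - mean(y))^2)
  if (ss == 0) stop_input("identity_r2 undefined: zero variance in y")
  1 - sum((y - x)^2) / ss
}

#' Per-fiber correlation of dF/F with AP peak and AP area
#'
#' For each fiber, the run-max-normalized dF/F is compared against the
#' normalized AP peak and the normalized AP area over all stimulations of the
#' run (including the potentiation phase), giving the two per-fiber
#' R-squared values whose cohort means summarize which AP property better
#' predicts the Ca2+ transient. The default comparison is against the
#' identity line ([identity_r2()]), matching how the normalized relationships
#' are plotted; `method = "ols"` uses the squared Pearson correlation
#' ([linear_r2()]) instead.
#'
#' @param features AP feature table from [extract_ap_features()].
#' @param dff dF/F feature table from [extract_calcium_features()].
#' @param roi_index ROI used for the dF/F (default: the ROI nearest the
#'   stimulating electrode present in `dff`).
#' @param dff_norm which normalization of the dF/F to correlate:
#'   `"runmax"` (default) or `"ref70"`.
#' @param method `"identity"` (default) or `"ols"`.
#' @return data frame of class `ecc_correlations` with one row per fiber:
#'   `muscle_id`, `fiber_id`, `r2_peak`, `r2_area`, `n_points`.
#' @export
correlate_cohort <- function(features, dff, roi_index = NULL,
                             dff_norm = c("runmax", "ref70"),
                             method = c("identity", "ols")) {
  dff_norm <- match.arg(dff_norm)
  method <- match.arg(method)
  r2fun <- if (method == "identity") identity_r2 else linear_r2
  require_columns(features, c("fiber_id", "stim_index", "norm_peak", "norm_area"), "features")
  col <- if (dff_norm == "runmax") "norm_runmax" else "norm_ref70"
  require_columns(dff, c("fiber_id", "stim_index", "roi_index", col), "dff")
  if (is.null(roi_index)) roi_index <- min(dff$roi_index)
  d <- dff[dff$roi_index == roi_index, ]
  rows <- lapply(unique(features$fiber_id), function(fid) {
    f <- features[features$fiber_id == fid, ]
    dfib <- d[d$fiber_id == fid, ]
    y <- dfib[[col]][match(f$stim_index, dfib$stim_index)]
    keep <- is.finite(y) & is.finite(f$norm_peak) & is.finite(f$norm_area)
    if (sum(keep) < 3L) return(NULL)
    data.frame(
      muscle_id = if ("muscle_id" %in% names(f)) f$muscle_id[1L] else NA_character_,
      fiber_id = fid,
      r2_peak = r2fun(f$norm_peak[keep], y[keep]),
      r2_area = r2fun(f$norm_area[keep], y[keep]),
      n_points = sum(keep), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("ecc_correlations", "data.frame")
  res
}

#' Aggregate fiber-level quantities to cohort summaries
#'
#' At `"muscle"` level each muscle contributes the unweighted mean of its
#' fibers, and the cohort mean and SD are taken across muscles; at `"fiber"`
#' level they are taken directly across fibers. All results are reported as
#' mean +/- SD.
#'
#' @param fiber_table data frame with one row per fiber (must contain
#'   `muscle_id` for muscle-level aggregation).
#' @param value_cols names of the numeric columns to aggregate.
#' @param level `"fiber"` or `"muscle"`.
#' @return data frame with one row per quantity: `quantity`, `level`, `mean`,
#'   `sd`, `n_groups`, `label` (formatted "mean +/- SD").
#' @export
aggregate_cohort <- function(fiber_table, value_cols,
                             level = c("fiber", "muscle")) {
  level <- match.arg(level)
  require_columns(fiber_table, value_cols, "fiber_table")
  rows <- lapply(value_cols, function(col) {
    v <- fiber_table[[col]]
    if (level == "muscle") {
      require_columns(fiber_table, "muscle_id", "fiber_table")
      grp <- split(v, fiber_table$muscle_id)
      grp <- grp[vapply(grp, function(g) any(is.finite(g)), logical(1))]
      if (length(grp) == 0L) {
        warning(sprintf("no finite values for '%s'; group skipped", col))
        return(NULL)
      }
      v <- vapply(grp, function(g) mean(g[is.finite(g)]), numeric(1))
    } else {
      v <- v[is.finite(v)]
      if (length(v) == 0L) {
        warning(sprintf("no finite values for '%s'; group skipped", col))
        return(NULL)
      }
    }
    data.frame(quantity = col, level = level, mean = mean(v),
               sd = stats::sd(v), n_groups = length(v),
               label = sprintf("%.3g +/- %.3g", mean(v), stats::sd(v)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
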