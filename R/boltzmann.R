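#' Two-asymptote Boltzmann sigmoid
#'
#' Evaluates `Out = LV + (HV - LV) / (1 + exp((V50 - V) / k))`: a sigmoid with
#' limiting value `LV` as `V` becomes very negative and `HV` as `V` becomes
#' very positive, half-way point at `V = V50`, and slope factor `k` (mV).
#' This single equation describes all three voltage relationships analysed by
#' the package: AP peak vs resting potential, normalized dF/F vs resting
#' potential, and normalized dF/F vs AP peak.
#'
#' @param V voltage (mV), vectorized.
#' @param LV limiting value at very negative `V`.
#' @param HV limiting value at very positive `V`.
#' @param V50 voltage of the half-maximal transition (mV).
#' @param k slope factor (mV), must be positive.
#' @return numeric vector of the dependent variable.
#' @examples
#' boltzmann(-58.2, LV = 30, HV = -40, V50 = -58.2, k = 1.8) # midpoint: -5
#' @export
boltzmann <- function(V, LV, HV, V50, k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop_input("slope factor 'k' must be positive and finite (got %s)",
               paste(format(k), collapse = ", "))
  }
  LV + (HV - LV) / (1 + exp((V50 - V) / k))
}

.bz_par_names <- c("LV", "HV", "V50", "k")

#' Constrained fit configurations for the Boltzmann relationships
#'
#' Returns the parameter constraints used for each of the three fitted
#' relationships:
#' \describe{
#'   \item{`peak_vs_vrest`}{AP peak against resting potential; `HV` (the
#'     minimal AP peak at depolarized resting potentials) bounded to
#'     \[-50, -30\] mV, all other parameters free.}
#'   \item{`dff_vs_vrest`}{normalized dF/F against resting potential; `LV`
#'     fixed to 1 (the value at the -70 mV reference) and `HV` bounded to
#'     \[0, 0.1\].}
#'   \item{`dff_vs_peak`}{normalized dF/F against AP peak; `HV` fixed to 1 and
#'     `LV` fixed to 0.}
#' }
#'
#' @param name one of `"peak_vs_vrest"`, `"dff_vs_vrest"`, `"dff_vs_peak"`.
#' @return a list with elements `name`, `fixed` (named numeric vector of fixed
#'   parameters), `lower` and `upper` (named bounds for the free parameters).
#' @export
boltzmann_preset <- function(name = c("peak_vs_vrest", "dff_vs_vrest", "dff_vs_peak")) {
  name <- match.arg(name)
  cfg <- switch(name,
    peak_vs_vrest = list(
      fixed = c(),
      lower = c(LV = -Inf, HV = -50, V50 = -Inf, k = 0.05),
      upper = c(LV = Inf, HV = -30, V50 = Inf, k = 50)
    ),
    dff_vs_vrest = list(
      fixed = c(LV = 1),
      lower = c(HV = 0, V50 = -Inf, k = 0.02),
      upper = c(HV = 0.1, V50 = Inf, k = 50)
    ),
    dff_vs_peak = list(
      fixed = c(LV = 0, HV = 1),
      lower = c(V50 = -Inf, k = 0.05),
      upper = c(V50 = Inf, k = 100)
    )
  )
  cfg$name <- name
  cfg
}

# Validate a fit configuration (either a preset or a user-supplied list).
.bz_check_config <- function(config) {
  if (!is.list(config) || is.null(config$lower) || is.null(config$upper)) {
    stop_input("'config' must be a list with 'lower' and 'upper' bounds (see boltzmann_preset())")
  }
  fixed <- config$fixed %||% c()
  if (length(fixed) > 0L && is.null(names(fixed))) {
    stop_input("'config$fixed' must be a named numeric vector")
  }
  bad <- setdiff(c(names(fixed), names(config$lower), names(config$upper)), .bz_par_names)
  if (length(bad) > 0L) {
    stop_input("unknown Boltzmann parameter(s) in config: %s", paste(bad, collapse = ", "))
  }
  free <- setdiff(.bz_par_names, names(fixed))
  lower <- structure(rep(-Inf, length(free)), names = free)
  upper <- structure(rep(Inf, length(free)), names = free)
  lower[intersect(names(config$lower), free)] <- config$lower[intersect(names(config$lower), free)]
  upper[intersect(names(config$upper), free)] <- config$upper[intersect(names(config$upper), free)]
  if ("k" %in% free && lower[["k"]] <= 0) lower[["k"]] <- 1e-3
  list(name = config$name %||% "custom", fixed = fixed, free = free,
       lower = lower, upper = upper)
}

# Data-driven starting values for the free parameters.
.bz_init <- function(x, y, cfg) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(xs)
  n_edge <- max(2L, n %/% 4L)
  lv0 <- mean(ys[seq_len(n_edge)])
  hv0 <- mean(ys[seq.int(n - n_edge + 1L, n)])
  if ("LV" %in% names(cfg$fixed)) lv0 <- cfg$fixed[["LV"]]
  if ("HV" %in% names(cfg$fixed)) hv0 <- cfg$fixed[["HV"]]

  # midpoint of the steepest finite-difference slope
  dx <- diff(xs)
  ok <- dx > 0
  slope <- rep(0, length(dx))
  slope[ok] <- diff(ys)[ok] / dx[ok]
  v50_0 <- if (any(ok)) (xs[which.max(abs(slope))] + xs[which.max(abs(slope)) + 1L]) / 2 else stats::median(xs)

  # k from the x-span between the 25% and 75% transition levels
  yr <- hv0 - lv0
  k0 <- diff(range(xs)) / 10
  if (abs(yr) > .Machine$double.eps) {
    frac <- (ys - lv0) / yr
    x25 <- suppressWarnings(xs[which(frac >= 0.25)[1L]])
    x75 <- suppressWarnings(xs[which(frac >= 0.75)[1L]])
    if (length(x25) == 1L && length(x75) == 1L && is.finite(x25) && is.finite(x75) && x75 != x25) {
      k0 <- abs(x75 - x25) / log(9)
    }
  }
  k0 <- max(k0, 1e-2)
  start <- c(LV = lv0, HV = hv0, V50 = v50_0, k = k0)[cfg$free]
  pmin(pmax(start, cfg$lower + 1e-9), cfg$upper - 1e-9)
}

#' Fit the Boltzmann equation by bound-constrained least squares
#'
#' Ordinary least squares over the free parameters of the Boltzmann sigmoid,
#' honouring fixed parameters exactly and projecting the remaining ones into
#' their box constraints (Levenberg-Marquardt via \pkg{minpack.lm}). The fit is
#' restarted from a deterministic set of jittered initializations and the best
#' residual sum of squares is kept.
#'
#' @param x independent voltage variable (mV).
#' @param y dependent variable (AP peak in mV, or normalized dF/F).
#' @param config a fit configuration, normally one of [boltzmann_preset()].
#' @param init optional named vector of starting values for free parameters.
#' @param n_starts number of additional jittered restarts (default 5).
#' @param max_eval maximum function evaluations per start.
#' @return an object of class `boltzmann_fit`: a list with `params` (all four
#'   parameters), `fixed`, `lower`, `upper`, `rss`, `n_points`, `converged`,
#'   `config` (the preset name), `fitted` values, and derived quantities
#'   `half_max_output` and `span_10_90`.
#' @seealso [half_max_output()], [span_10_90()], [boltzmann_preset()]
#' @export
fit_boltzmann <- function(x, y, config = boltzmann_preset("peak_vs_vrest"),
                          init = NULL, n_starts = 5L, max_eval = 1000L) {
  cfg <- .bz_check_config(config)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < length(cfg$free)) {
    stop_input("fewer data points (%d) than free parameters (%d)", n, length(cfg$free))
  }
  if (n < 4L) stop_input("Boltzmann fit needs at least 4 points, got %d", n)

  flat <- stats::sd(y) < .Machine$double.eps^0.5 * (abs(mean(y)) + 1)

  start0 <- .bz_init(x, y, cfg)
  if (!is.null(init)) {
    init <- init[intersect(names(init), cfg$free)]
    start0[names(init)] <- pmin(pmax(init, cfg$lower[names(init)] + 1e-9),
                                cfg$upper[names(init)] - 1e-9)
  }
  k0 <- if ("k" %in% cfg$free) start0[["k"]] else cfg$fixed[["k"]] %||% 1

  residual <- function(p) {
    full <- c(p, cfg$fixed)
    y - boltzmann(x, full[["LV"]], full[["HV"]], full[["V50"]], full[["k"]])
  }

  # deterministic jitter table: (V50 shift in units of k0, k multiplier)
  jitter <- list(c(0, 1), c(-1, 0.5), c(1, 0.5), c(-0.5, 2), c(0.5, 2), c(0, 4))
  jitter <- jitter[seq_len(min(length(jitter), n_starts + 1L))]

  best <- NULL
  for (j in jitter) {
    start <- start0
    if ("V50" %in% cfg$free) start[["V50"]] <- start0[["V50"]] + j[1L] * k0
    if ("k" %in% cfg$free) start[["k"]] <- start0[["k"]] * j[2L]
    start <- pmin(pmax(start, cfg$lower + 1e-9), cfg$upper - 1e-9)
    ans <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = cfg$lower, upper = cfg$upper,
                         fn = residual,
                         control = minpack.lm::nls.lm.control(
                           maxiter = min(max_eval, 1000L), maxfev = max_eval,
                           ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(ans)) next
    rss <- sum(residual(ans$par)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = ans$par, rss = rss, info = ans$info)
    }
  }
  if (is.null(best)) {
    stop_input("Boltzmann fit failed to converge from any start (n = %d, preset = %s)",
               n, cfg$name)
  }

  params <- c(best$par, cfg$fixed)[.bz_par_names]
  names(params) <- .bz_par_names
  # runaway fits (midpoint far outside the data, or slope pinned at its
  # ceiling) carry no information about the transition: flag, don't report
  xr <- range(x)
  runaway <- params[["V50"]] < xr[1L] - diff(xr) || params[["V50"]] > xr[2L] + diff(xr) ||
    ("k" %in% cfg$free && params[["k"]] > cfg$upper[["k"]] - 1e-6)
  fit <- structure(list(
    params = params,
    fixed = cfg$fixed,
    lower = cfg$lower,
    upper = cfg$upper,
    config = cfg$name,
    rss = best$rss,
    n_points = n,
    converged = (best$info %in% 1:4) && !flat && !runaway,
    fitted = boltzmann(x, params[["LV"]], params[["HV"]], params[["V50"]], params[["k"]]),
    x = x, y = y
  ), class = "boltzmann_fit")
  fit$half_max_output <- half_max_output(fit)
  fit$span_10_90 <- span_10_90(fit)
  if (flat) warning("response has no variance; fit flagged as not converged")
  fit
}

#' Output at the half-maximal transition
#'
#' For a fitted Boltzmann relationship the dependent variable at `V = V50` is
#' `(LV + HV) / 2`; for the AP-peak relationship this is the half-maximal AP
#' peak.
#'
#' @param fit a `boltzmann_fit` object.
#' @return numeric scalar, in the units of the dependent variable.
#' @export
half_max_output <- function(fit) {
  p <- if (inherits(fit, "boltzmann_fit")) fit$params else fit
  unname((p[["LV"]] + p[["HV"]]) / 2)
}

#' Voltage span of the 10--90% transition
#'
#' Distance in `V` over which the Boltzmann output moves from 90% to 10% of
#' the `LV`-to-`HV` transition: `k * ln(81)`.
#'
#' @param fit a `boltzmann_fit` object, or a numeric slope factor `k`.
#' @return span in mV.
#' @export
span_10_90 <- function(fit) {
  k <- if (inherits(fit, "boltzmann_fit")) fit$params[["k"]] else fit
  if (any(k <= 0)) stop_input("slope factor 'k' must be positive")
  unname(k * log(81))
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit (%s), n = %d, %s\n", x$config, x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  p <- x$params
  fixed <- names(x$fixed)
  lab <- vapply(.bz_par_names, function(nm) {
    sprintf("%s = %.4g%s", nm, p[[nm]], if (nm %in% fixed) " (fixed)" else "")
  }, character(1))
  cat(" ", paste(lab, collapse = ", "), "\n")
  cat(sprintf("  rss = %.4g, half-max output = %.4g, 10-90 span = %.4g mV\n",
              x$rss, x$half_max_output, x$span_10_90))
  invisible(x)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) object$x else newdata
  p <- object$params
  boltzmann(V, p[["LV"]], p[["HV"]], p[["V50"]], p[["k"]])
}
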