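# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded sub-streams (e.g. per-fiber streams of the cohort generator)
#' never perturb the global random sequence.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

# Time spent at or above `level` by the piecewise-linear trace (t, v),
# with linearly interpolated crossings.
time_above <- function(t, v, level) {
  n <- length(v)
  if (n < 2L) return(0)
  a <- v[-n] - level
  b <- v[-1L] - level
  dt <- diff(t)
  frac <- ifelse(a != b, a / (a - b), 0.5) # crossing offset from the left node
  dur <- ifelse(a >= 0 & b >= 0, dt,
         ifelse(a < 0 & b < 0, 0,
         ifelse(a >= 0, frac * dt, (1 - frac) * dt)))
  sum(dur)
}

# Trapezoidal integral of max(v - level, 0) dt with interpolated sub-sample
# crossings; exact for piecewise-linear traces.
integral_above <- function(t, v, level) {
  n <- length(v)
  if (n < 2L) return(0)
  a <- v[-n] - level
  b <- v[-1L] - level
  dt <- diff(t)
  both_pos <- a >= 0 & b >= 0
  both_neg <- a <= 0 & b <= 0
  area <- numeric(n - 1L)
  area[both_pos] <- (a[both_pos] + b[both_pos]) / 2 * dt[both_pos]
  cross <- !(both_pos | both_neg)
  if (any(cross)) {
    ac <- a[cross]
    bc <- b[cross]
    dtc <- dt[cross]
    frac <- ac / (ac - bc)
    rising <- ac < 0 # positive part sits right of the crossing
    pos_len <- ifelse(rising, (1 - frac) * dtc, frac * dtc)
    pos_val <- ifelse(rising, bc, ac)
    area[cross] <- pos_val * pos_len / 2
  }
  sum(area)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_input("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}
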