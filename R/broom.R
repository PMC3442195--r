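# broom-style accessors for fitted diagnostic objects

#' Tidy a two-regime breakpoint fit
#'
#' @param x A `regime_split` object.
#' @param ... Unused.
#' @return One row per regime with the log-log slope estimate and its
#'   standard error.
#' @export
tidy.regime_split <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = c("early_slope", "late_slope"),
    estimate = c(x$early_slope, x$late_slope),
    std.error = c(s["x1", "Std. Error"], s["x2", "Std. Error"])
  )
}

#' @rdname tidy.regime_split
#' @export
glance.regime_split <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble(
    t_split = x$t_split,
    early_slope = x$early_slope,
    late_slope = x$late_slope,
    sigma = s$sigma,
    r.squared = s$r.squared,
    nobs = nrow(x$series)
  )
}

#' Tidy an N-scaling summary
#'
#' @param x An `n_scaling` object.
#' @param ... Unused.
#' @return `tidy()`: the per-count mean-field table; `glance()`: the
#'   regression slope/intercept with standard errors.
#' @export
tidy.n_scaling <- function(x, ...) x$table

#' @rdname tidy.n_scaling
#' @export
glance.n_scaling <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    slope = s["n", "Estimate"],
    slope.se = s["n", "Std. Error"],
    intercept = s["(Intercept)", "Estimate"],
    intercept.se = s["(Intercept)", "Std. Error"],
    t = x$t,
    nobs = nrow(x$table)
  )
}

#' Tidy and summarise a simulation run
#'
#' @param x A `ctc_run`.
#' @param ... Unused.
#' @return `tidy()`: the peak-vs-time series as a plain tibble; `glance()`:
#'   one row with run-level facts (mode, source count, latest-time wall and
#'   top-slice peaks).
#' @export
tidy.ctc_run <- function(x, ...) as_tibble(x$peaks)

#' @rdname tidy.ctc_run
#' @export
glance.ctc_run <- function(x, ...) {
  pk <- as_tibble(x$peaks)
  last_t <- max(pk$t)
  last <- pk[pk$t == last_t, ]
  tibble(
    mode = x$flow$mode,
    u = x$flow$u,
    n_sources = nrow(x$sources),
    n_times = length(x$config$times),
    t_last = last_t,
    peak_wall = last$peak[which.min(last$offset)],
    peak_top = last$peak[which.max(last$offset)]
  )
}
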