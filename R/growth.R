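## Colony-area growth: doubling times from log-linear fits, and the
## decomposition of the degradation-and-dilution rate into growth
## dilution plus active degradation.

#' Colony-area doubling time
#'
#' Least-squares fit of `ln(area)` against time over a window (by default
#' the last hour of induction, 150-210 min); the growth rate is the
#' slope `r` and the doubling time `ln(2)/r`, with a confidence interval
#' propagated from the slope's standard error. A non-positive slope is
#' flagged as non-growing (infinite doubling time).
#'
#' @param record data frame with columns `time_min` and `area` (one
#'   colony).
#' @param window time window `c(from, to)`, min.
#' @param level confidence level (default 90%).
#' @return List with `doubling_time` (min), `ci`, `rate` (1/min),
#'   `rate_se`, `n`, `non_growing`.
#' @export
area_doubling_time <- function(record, window = c(150, 210),
                               level = 0.90) {
  stopifnot(all(c("time_min", "area") %in% names(record)))
  sel <- in_window(record$time_min, window)
  tt <- record$time_min[sel]; aa <- record$area[sel]
  if (length(tt) < 3) stop("need at least 3 points in the window")
  if (any(aa <= 0)) stop("areas must be positive")
  fit <- stats::lm(log(aa) ~ tt)
  r <- unname(stats::coef(fit)[2])
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  tcrit <- stats::qt(1 - (1 - level) / 2, df = length(tt) - 2)
  r_ci <- r + c(-1, 1) * tcrit * se
  # slopes below numerical resolution count as non-growing
  tiny <- 1e-12
  to_dt <- function(rate) if (rate > tiny) log(2) / rate else Inf
  ci <- c(to_dt(r_ci[2]), to_dt(r_ci[1]))  # larger rate -> shorter time
  list(doubling_time = to_dt(r), ci = ci, rate = r, rate_se = se,
       n = length(tt), non_growing = r <= tiny)
}

#' Decompose turnover into growth dilution plus degradation
#'
#' The degradation-and-dilution rate `d` is modeled as growth rate plus a
#' constant active-degradation rate: a linear fit with slope fixed to
#' one, whose intercept is `mean(d - growth)` over the included systems.
#' Systems far below the line (residual more negative than two SDs of
#' the included residuals) are flagged as turning off anomalously
#' slowly.
#'
#' @param d_values named vector of per-system rates `d`, 1/min.
#' @param growth_rates named vector of per-system growth rates, 1/min
#'   (same names).
#' @param exclude system names excluded from the fit (but still
#'   reported).
#' @return List with `intercept` (the active-degradation rate, 1/min),
#'   `residuals` (named, all systems), `flagged_below`, `included`.
#' @export
degradation_growth_decomposition <- function(d_values, growth_rates,
                                             exclude = character()) {
  if (is.null(names(d_values)) || is.null(names(growth_rates)))
    stop("d_values and growth_rates must be named by system")
  common <- intersect(names(d_values), names(growth_rates))
  included <- setdiff(common, exclude)
  if (length(included) < 2) stop("need at least 2 included systems")
  intercept <- mean(d_values[included] - growth_rates[included])
  residuals <- d_values[common] - growth_rates[common] - intercept
  s <- stats::sd(residuals[included])
  flagged <- names(residuals)[residuals < -2 * s - 1e-15]
  list(intercept = intercept, residuals = residuals,
       flagged_below = flagged, included = included)
}

#' Half-life from a first-order rate
#'
#' `ln(2) / rate`; e.g. an active-degradation rate of 0.0072 per minute
#' corresponds to a reporter half-life of 96.3 min.
#'
#' @param rate first-order rate, 1/min (> 0).
#' @return Half-life in minutes.
#' @export
half_life_from_rate <- function(rate) {
  if (any(rate <= 0)) stop("rate must be > 0")
  log(2) / rate
}
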