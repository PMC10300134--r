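## Staged estimation of the kinetic parameters from a fluorescence trace:
## basal plateau -> quadratic onset fit (i, t_on) -> quadratic turn-off
## fit (t_off) -> exponential decay fit (d) -> back-computation of b.

#' Optimizer settings of the staged fit
#'
#' Bound-constrained simplex search (Nelder-Mead on a quadratic transform
#' of the bounded parameters, the `fminsearchbnd` idiom) with relative
#' convergence tolerance on parameters and objective and an evaluation
#' budget.
#'
#' @param reltol relative convergence tolerance.
#' @param maxit maximum function evaluations.
#' @return A list of control settings.
#' @export
fit_control <- function(reltol = 1e-8, maxit = 5000) {
  list(reltol = reltol, maxit = maxit)
}

## Nelder-Mead with lower bounds via the substitution p = lb + x^2
## (dimensions with lb = -Inf are left untransformed).
bounded_nm <- function(par, fn, lower = rep(-Inf, length(par)),
                      control = fit_control()) {
  bounded <- is.finite(lower)
  par <- pmax(par, lower + 1e-12)
  to_x <- function(p) ifelse(bounded, sqrt(pmax(p - lower, 0)), p)
  to_p <- function(x) ifelse(bounded, lower + x^2, x)
  res <- stats::optim(to_x(par), function(x) fn(to_p(x)),
                      method = "Nelder-Mead",
                      control = list(reltol = control$reltol,
                                     maxit = control$maxit))
  p <- to_p(res$par)
  snap <- bounded & (p - lower < 1e-9)
  p[snap] <- lower[snap]
  list(par = p, value = res$value,
       converged = res$convergence == 0L, evals = res$counts[["function"]])
}

#' Basal (pre-induction) fluorescence plateau
#'
#' Mean fluorescence over the basal window (possibly a single timepoint,
#' as for optogenetic systems imaged only from induction onset). Under
#' the model this estimates the composite plateau `f b / (d (d + f))`.
#'
#' @param times,fluorescence trace vectors (min, maxGAL1).
#' @param window numeric `c(from, to)`, min.
#' @return The plateau estimate, maxGAL1.
#' @export
estimate_basal <- function(times, fluorescence, window = c(-60, 0)) {
  sel <- in_window(times, window)
  if (!any(sel)) stop("basal window contains no timepoints")
  mean(fluorescence[sel])
}

#' Fit the quadratic onset (induction speed and activation lag)
#'
#' Least-squares fit of the one-sided quadratic
#' `basal + (i f / 2) (t - t_on)^2 for t > t_on` over the rise window,
#' with `i >= 0` and `t_on >= 0` (the quadratic is the second-order
#' expansion of the exact onset solution; it is zero before the lag
#' because the promoter is a step). The maturation rate `f` is fixed.
#'
#' @param times,fluorescence trace vectors.
#' @param f_fixed maturation rate, 1/min.
#' @param window rise window `c(from, to)`, min.
#' @param basal_plateau the pre-induction plateau, maxGAL1.
#' @param control a [fit_control()].
#' @return List with `i`, `t_on`, `residual_ss`, `converged`,
#'   `t_on_defined` (FALSE for an essentially flat trace).
#' @export
fit_rise <- function(times, fluorescence, f_fixed, window = c(-50, 50),
                     basal_plateau, control = fit_control()) {
  if (f_fixed <= 0) stop("f_fixed must be > 0")
  sel <- in_window(times, window)
  tt <- times[sel]; yy <- fluorescence[sel]
  if (length(tt) < 3) stop("need at least 3 points in the rise window")
  dy <- yy - basal_plateau
  ## the model is linear in i given t_on: profile i over a lag grid,
  ## then polish both with the bounded simplex
  prof_i <- function(t_on) {
    z <- (f_fixed / 2) * pmax(tt - t_on, 0)^2
    zz <- sum(z * z)
    if (zz == 0) return(0)
    max(0, sum(z * dy) / zz)
  }
  grid <- seq(max(0, window[1]), window[2], by = 1)
  sse <- vapply(grid, function(t_on) {
    i <- prof_i(t_on)
    sum((dy - i * (f_fixed / 2) * pmax(tt - t_on, 0)^2)^2)
  }, numeric(1))
  t_on0 <- grid[which.min(sse)]
  i0 <- max(prof_i(t_on0), 1e-12)
  obj <- function(p) {
    r <- dy - (p[1] * f_fixed / 2) * pmax(tt - p[2], 0)^2
    sum(r * r)
  }
  res <- bounded_nm(c(i0, t_on0), obj, lower = c(0, 0), control = control)
  flat <- res$par[1] * f_fixed / 2 *
    pmax(max(tt) - res$par[2], 0)^2 <
    .Machine$double.eps^0.5 * max(abs(yy), 1e-12)
  list(i = res$par[1], t_on = res$par[2], residual_ss = res$value,
       converged = res$converged, t_on_defined = !flat)
}

#' Fit the quadratic turn-off (deactivation lag)
#'
#' Least-squares fit of
#' `induced_plateau - (i f / 2) (t - t_end - t_off)^2 for t > t_end + t_off`
#' over the fall window, with the curvature amplitude and `t_off >= 0`
#' both free. Returns the deactivation lag; a trace that stays flat
#' through the window drives the lag to the window edge and is flagged.
#'
#' @param times,fluorescence trace vectors.
#' @param f_fixed maturation rate, 1/min.
#' @param window fall window `c(from, to)`, min.
#' @param induced_plateau fluorescence level at the end of induction.
#' @param t_end induction signal removal, min.
#' @param control a [fit_control()].
#' @return List with `t_off`, `i_fall`, `residual_ss`, `converged`,
#'   `t_off_defined`, `at_window_edge`.
#' @export
fit_fall <- function(times, fluorescence, f_fixed, window = c(210, 270),
                     induced_plateau, t_end = 210,
                     control = fit_control()) {
  if (f_fixed <= 0) stop("f_fixed must be > 0")
  sel <- in_window(times, window)
  tt <- times[sel]; yy <- fluorescence[sel]
  if (length(tt) < 3) stop("need at least 3 points in the fall window")
  dy <- induced_plateau - yy
  prof_i <- function(t_off) {
    z <- (f_fixed / 2) * pmax(tt - t_end - t_off, 0)^2
    zz <- sum(z * z)
    if (zz == 0) return(0)
    max(0, sum(z * dy) / zz)
  }
  grid <- seq(0, window[2] - t_end, by = 1)
  sse <- vapply(grid, function(t_off) {
    i <- prof_i(t_off)
    sum((dy - i * (f_fixed / 2) * pmax(tt - t_end - t_off, 0)^2)^2)
  }, numeric(1))
  t_off0 <- grid[which.min(sse)]
  i0 <- max(prof_i(t_off0), 1e-12)
  obj <- function(p) {
    r <- yy - induced_plateau +
      (p[1] * f_fixed / 2) * pmax(tt - t_end - p[2], 0)^2
    sum(r * r)
  }
  res <- bounded_nm(c(i0, t_off0), obj, lower = c(0, 0),
                    control = control)
  span <- window[2] - t_end
  drop_at_end <- res$par[1] * f_fixed / 2 *
    pmax(window[2] - t_end - res$par[2], 0)^2
  defined <- drop_at_end >= .Machine$double.eps^0.5 *
    max(abs(induced_plateau), 1e-12)
  at_edge <- !defined || res$par[2] >= span - 1e-6
  list(t_off = res$par[2], i_fall = res$par[1], residual_ss = res$value,
       converged = res$converged, t_off_defined = defined,
       at_window_edge = at_edge)
}

#' Fit the exponential decay (degradation-and-dilution rate)
#'
#' Nonlinear least-squares fit of `F0 * exp(-d (t - t0)) + floor` over the
#' decay window (starting about four maturation half-times after
#' shutoff, where the maturation transient is negligible). The floor is
#' fixed to the basal plateau; `d` is unconstrained, so a rising trace
#' yields a negative rate, the downstream exclusion signal.
#'
#' @param times,fluorescence trace vectors.
#' @param window decay window `c(from, to)`, min.
#' @param floor asymptotic fluorescence level, maxGAL1.
#' @param control a [fit_control()].
#' @return List with `d`, `F0`, `residual_ss`, `converged`.
#' @export
fit_decay <- function(times, fluorescence, window = c(270, 390),
                      floor = 0, control = fit_control()) {
  sel <- in_window(times, window)
  tt <- times[sel]; yy <- fluorescence[sel]
  if (length(tt) < 3) stop("need at least 3 points in the decay window")
  t0 <- tt[1]
  above <- yy - floor
  ## a trace flat at the floor carries no decay information: report a
  ## zero rate rather than letting the degenerate fit pick an arbitrary d
  if (all(abs(above) <= .Machine$double.eps^0.5 * max(abs(yy), 1)))
    return(list(d = 0, F0 = 0, residual_ss = 0, converged = TRUE))
  ## profile F0 over a rate grid (model linear in F0 given d), then polish
  prof_F0 <- function(d) {
    z <- exp(-d * (tt - t0))
    sum(z * above) / sum(z * z)
  }
  grid <- seq(-0.1, 0.2, by = 0.002)
  sse <- vapply(grid, function(d) {
    sum((above - prof_F0(d) * exp(-d * (tt - t0)))^2)
  }, numeric(1))
  d0 <- grid[which.min(sse)]
  F00 <- prof_F0(d0)
  obj <- function(p) {
    r <- above - p[1] * exp(-p[2] * (tt - t0))
    sum(r * r)
  }
  res <- bounded_nm(c(F00, d0), obj, control = control)
  list(d = res$par[2], F0 = res$par[1], residual_ss = res$value,
       converged = res$converged)
}

#' Back-compute the basal synthesis rate
#'
#' Inverts the basal plateau `f b / (d (d + f))` using the separately
#' fitted degradation-and-dilution rate: `b = plateau * d * (d + f) / f`.
#' When `d <= 0` no inversion exists and `NA` is returned with a warning
#' (for systems whose `d` is close to zero the result would not represent
#' leakiness well in any case).
#'
#' @param basal_plateau the fitted plateau, maxGAL1.
#' @param d degradation-and-dilution rate, 1/min.
#' @param f maturation rate, 1/min.
#' @return `b` in maxGAL1/min, or `NA` when `d <= 0`.
#' @export
recover_b <- function(basal_plateau, d, f) {
  if (f <= 0) stop("f must be > 0")
  if (is.na(d) || d <= 0) {
    warning("d <= 0: basal rate b is undefined")
    return(NA_real_)
  }
  basal_plateau * d * (d + f) / f
}

## Exact-form stage fits: same staging, but the rise and fall windows are
## fitted with the exact closed-form solutions (using the decay-stage d)
## instead of their quadratic truncations. Free of truncation bias up to
## the small error inherited from d.
fit_rise_exact <- function(times, fluorescence, f, d, window,
                           basal_plateau) {
  sel <- in_window(times, window)
  tt <- times[sel]; yy <- fluorescence[sel]
  dy <- yy - basal_plateau
  zfun <- function(t_on) {
    tau <- pmax(tt - t_on, 0)
    on <- tt > t_on
    z <- numeric(length(tt))
    z[on] <- f / (d * (f + d)) - exp(-d * tau[on]) / d +
      exp(-(f + d) * tau[on]) / (f + d)
    z
  }
  prof_i <- function(t_on) {
    z <- zfun(t_on); zz <- sum(z * z)
    if (zz == 0) return(0)
    max(0, sum(z * dy) / zz)
  }
  sse <- function(t_on) {
    z <- zfun(t_on)
    sum((dy - prof_i(t_on) * z)^2)
  }
  lo <- max(0, window[1]); hi <- window[2]
  grid <- seq(lo, hi, by = 1)
  t_on0 <- grid[which.min(vapply(grid, sse, numeric(1)))]
  opt <- stats::optimize(sse, c(max(lo, t_on0 - 1.5),
                                min(hi, t_on0 + 1.5)), tol = 1e-8)
  t_on <- opt$minimum
  list(i = prof_i(t_on), t_on = t_on, residual_ss = opt$objective,
       converged = TRUE, t_on_defined = prof_i(t_on) > 0)
}

## joint fit of (t_off, d) over the fall + decay span with the exact
## ON-then-OFF closed forms; b, i, t_on are held at their current stage
## estimates
fit_falldecay_exact <- function(times, fluorescence, b, i, f, d_init,
                                fall_window, decay_window, t_end,
                                t_start = 0, t_on = 0,
                                control = fit_control()) {
  sel <- in_window(times, c(fall_window[1], decay_window[2]))
  tt <- times[sel]; yy <- fluorescence[sel]
  curve <- function(t_off, d) {
    p <- new_fit_params(b = b, i = i, f = f, d = d, t_on = t_on,
                        t_off = t_off)
    s0 <- t_end + t_off
    out <- numeric(length(tt))
    pre <- tt < s0
    if (any(pre)) out[pre] <- closed_form_on(p, tt[pre], t_start)
    if (any(!pre)) out[!pre] <- closed_form_off(p, tt[!pre], t_end,
                                                t_start)
    out
  }
  obj <- function(q) sum((yy - curve(q[1], q[2]))^2)
  hi <- fall_window[2] - t_end
  grid <- seq(0, hi, by = 1)
  t_off0 <- grid[which.min(vapply(grid, function(s) obj(c(s, d_init)),
                                  numeric(1)))]
  res <- bounded_nm(c(t_off0, d_init), obj,
                    lower = c(0, DEGENERATE_RATE_TOL), control = control)
  list(t_off = res$par[1], d = res$par[2], i_fall = i,
       residual_ss = res$value, converged = res$converged,
       t_off_defined = TRUE,
       at_window_edge = res$par[1] >= hi - 1e-6)
}

new_fit_params <- function(b, i, f, d, t_on, t_off) {
  structure(list(b = b, i = i, f = f, d = d, t_on = t_on, t_off = t_off),
            class = "kinetic_params")
}

#' Fit the kinetic model to an induction time course
#'
#' The package's central fitting routine. Runs the staged procedure on a
#' single-cell trace or (default for multi-cell input) on the pointwise
#' population-average trace: basal plateau, quadratic onset fit for `i`
#' and `t_on`, quadratic turn-off fit for `t_off`, exponential decay fit
#' for `d`, and back-computation of `b`. For chemically induced systems
#' the media transport delay (`protocol$media_delay_s`) is subtracted
#' from both fitted lags; optogenetic systems switch instantaneously and
#' keep the raw lags.
#'
#' @param data a data frame with columns `time_min` and `fluorescence`
#'   (optionally `cell_id`), or a `"synthetic_population"`.
#' @param f fixed maturation rate, 1/min (default: a 20-min maturation
#'   half-time).
#' @param windows a [fit_windows()].
#' @param protocol an [induction_protocol()].
#' @param chemically_induced apply the media-delay correction?
#' @param average with multi-cell input, fit the population-average trace
#'   (`TRUE`) or every cell separately (`FALSE`, returning an
#'   `"induction_fit_set"`).
#' @param induced_plateau optional separately measured steady-state level
#'   (e.g. from an overnight induction); default is the fluorescence at
#'   the last induction timepoint.
#' @param form `"taylor"` (default) fits the rise and fall windows with
#'   the second-order Taylor truncations, the procedure the benchmark
#'   defines; `"exact"` fits them with the exact closed-form solutions
#'   (using the decay-stage `d`), which removes the substantial
#'   truncation bias of the quadratic fits at the cost of departing from
#'   the reference procedure.
#' @param control a [fit_control()].
#' @return An object of class `"induction_fit"` (or
#'   `"induction_fit_set"`), with methods `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot` and `simulate`.
#' @examples
#' pop <- generate_population(population_config(n_cells = 20, seed = 42))
#' fit <- fit_induction(pop)
#' coef(fit)
#' @export
fit_induction <- function(data, f = log(2) / 20, windows = fit_windows(),
                          protocol = induction_protocol(),
                          chemically_induced = TRUE, average = TRUE,
                          induced_plateau = NULL,
                          form = c("taylor", "exact"),
                          control = fit_control()) {
  form <- match.arg(form)
  if (inherits(data, "synthetic_population")) data <- data$traces
  stopifnot(is.data.frame(data),
            all(c("time_min", "fluorescence") %in% names(data)))
  if (!average && !("cell_id" %in% names(data))) data$cell_id <- "cell"
  ids <- if ("cell_id" %in% names(data)) unique(data$cell_id) else "cell"
  if (!average) {
    fits <- lapply(ids, function(id) {
      fit_induction(data[data$cell_id == id, , drop = FALSE], f = f,
                    windows = windows, protocol = protocol,
                    chemically_induced = chemically_induced,
                    induced_plateau = induced_plateau, form = form,
                    control = control)
    })
    names(fits) <- ids
    return(structure(list(fits = fits, traces = data),
                     class = "induction_fit_set"))
  }
  if (length(ids) > 1) {
    agg <- stats::aggregate(fluorescence ~ time_min, data = data,
                            FUN = mean)
    tt <- agg$time_min; yy <- agg$fluorescence
    scope <- "population"
  } else {
    o <- order(data$time_min)
    tt <- data$time_min[o]; yy <- data$fluorescence[o]
    scope <- "cell"
  }
  if (any(diff(tt) <= 0)) stop("duplicated timepoints within a cell")

  basal <- estimate_basal(tt, yy, windows$basal)
  if (is.null(induced_plateau)) {
    idx <- which.min(abs(tt - protocol$t_end))
    induced_plateau <- yy[idx]
  }
  decay <- fit_decay(tt, yy, window = windows$decay, floor = basal,
                     control = control)
  b <- if (decay$d > 0) basal * decay$d * (decay$d + f) / f else NA_real_
  if (form == "exact" && decay$d <= 0) {
    warning("fitted d <= 0: exact closed forms unavailable, using taylor")
    form <- "taylor"
  }
  if (form == "exact") {
    d_cur <- decay$d
    for (pass in 1:2) {
      b_cur <- basal * d_cur * (d_cur + f) / f
      rise <- fit_rise_exact(tt, yy, f = f, d = d_cur,
                             window = windows$rise, basal_plateau = basal)
      fall <- fit_falldecay_exact(tt, yy, b = b_cur, i = rise$i, f = f,
                                  d_init = d_cur,
                                  fall_window = windows$fall,
                                  decay_window = windows$decay,
                                  t_end = protocol$t_end,
                                  t_start = protocol$t_start,
                                  t_on = rise$t_on, control = control)
      d_cur <- fall$d
    }
    decay$d <- d_cur
    b <- basal * d_cur * (d_cur + f) / f
  } else {
    rise <- fit_rise(tt, yy, f_fixed = f, window = windows$rise,
                     basal_plateau = basal, control = control)
    fall <- fit_fall(tt, yy, f_fixed = f, window = windows$fall,
                     induced_plateau = induced_plateau,
                     t_end = protocol$t_end, control = control)
  }
  t_on <- rise$t_on; t_off <- fall$t_off
  delay_min <- if (chemically_induced) protocol$media_delay_s / 60 else 0
  t_on <- max(0, t_on - delay_min)
  t_off <- max(0, t_off - delay_min)
  structure(list(
    params = new_fit_params(b = b, i = rise$i, f = f, d = decay$d,
                            t_on = t_on, t_off = t_off),
    basal_plateau = basal, induced_plateau = induced_plateau,
    stages = list(rise = rise, fall = fall, decay = decay),
    windows = windows, protocol = protocol,
    chemically_induced = chemically_induced,
    media_delay_applied_min = delay_min,
    form = form, scope = scope, n_cells = length(ids),
    times = tt, fluorescence = yy,
    converged = rise$converged && fall$converged && decay$converged),
    class = "induction_fit")
}

#' Fit one cell's trace
#'
#' Thin wrapper around [fit_induction()] for a single-cell trace.
#' @inheritParams fit_induction
#' @param ... passed to [fit_induction()].
#' @export
fit_cell <- function(data, ...) {
  if ("cell_id" %in% names(data) && length(unique(data$cell_id)) > 1)
    stop("fit_cell expects a single cell; use fit_induction()")
  fit_induction(data, average = TRUE, ...)
}

#' Fit the population-average time course
#'
#' Averages the fluorescence pointwise over all cells present at each
#' timepoint, then runs the staged fit on the mean trace (the procedure
#' used for the lag estimates, which are too noisy cell by cell).
#'
#' @inheritParams fit_induction
#' @param ... passed to [fit_induction()].
#' @export
fit_population_average <- function(data, ...) {
  if (inherits(data, "synthetic_population")) data <- data$traces
  if (length(unique(data$cell_id)) < 2)
    stop("need at least 2 cells to average")
  fit_induction(data, average = TRUE, ...)
}

#' Apply the pathological-cell exclusion rules
#'
#' Excludes cells whose fitted degradation-and-dilution rate is negative
#' (fluorescence rising after shutoff) or whose fluorescence at the start
#' of induction (t = 0 h) strictly exceeds the level one hour after
#' shutoff (t = 4.5 h); both levels are read at the nearest sampled
#' timepoint. A constant trace is kept (strict inequality).
#'
#' @param fit_set an `"induction_fit_set"` from
#'   `fit_induction(average = FALSE)`.
#' @return List with `kept` and `excluded` (both `"induction_fit_set"`),
#'   and a data frame `reasons` with one row per cell.
#' @export
exclude_cells <- function(fit_set) {
  stopifnot(inherits(fit_set, "induction_fit_set"))
  fits <- fit_set$fits
  pr <- fits[[1]]$protocol
  t_check <- pr$t_end + 60
  rows <- lapply(names(fits), function(id) {
    ft <- fits[[id]]
    d_neg <- is.finite(ft$params$d) && ft$params$d < 0
    f0 <- ft$fluorescence[which.min(abs(ft$times - pr$t_start))]
    f45 <- ft$fluorescence[which.min(abs(ft$times - t_check))]
    pre_high <- f0 > f45
    reason <- if (d_neg && pre_high) "negative_d;start_above_4.5h"
      else if (d_neg) "negative_d"
      else if (pre_high) "start_above_4.5h"
      else NA_character_
    data.frame(cell_id = id, excluded = d_neg || pre_high,
               reason = reason, d = ft$params$d, f_t0 = f0,
               f_t4.5h = f45, stringsAsFactors = FALSE)
  })
  reasons <- do.call(rbind, rows)
  keep_ids <- reasons$cell_id[!reasons$excluded]
  excl_ids <- reasons$cell_id[reasons$excluded]
  subset_set <- function(ids) {
    structure(list(fits = fits[ids],
                   traces = fit_set$traces[
                     fit_set$traces$cell_id %in% ids, , drop = FALSE]),
              class = "induction_fit_set")
  }
  list(kept = subset_set(keep_ids), excluded = subset_set(excl_ids),
       reasons = reasons)
}

## ---- methods ----

#' @export
print.induction_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Staged kinetic fit (%s%s)\n", x$scope,
              if (x$scope == "population")
                sprintf(" of %d cells", x$n_cells) else ""))
  print(x$params)
  cat(sprintf("  basal plateau %.4g, induced plateau %.4g maxGAL1\n",
              x$basal_plateau, x$induced_plateau))
  if (x$media_delay_applied_min > 0)
    cat(sprintf("  media delay of %.2f min subtracted from both lags\n",
                x$media_delay_applied_min))
  if (!x$converged) cat("  WARNING: at least one stage did not converge\n")
  if (!x$stages$fall$t_off_defined || x$stages$fall$at_window_edge)
    cat("  NOTE: t_off at/undefined within the fall window\n")
  invisible(x)
}

#' @export
coef.induction_fit <- function(object, ...) {
  unlist(object$params)
}

#' @export
summary.induction_fit <- function(object, ...) {
  out <- list(fit = object,
              residual_ss = c(rise = object$stages$rise$residual_ss,
                              fall = object$stages$fall$residual_ss,
                              decay = object$stages$decay$residual_ss),
              flags = c(converged = object$converged,
                        t_on_defined = object$stages$rise$t_on_defined,
                        t_off_defined = object$stages$fall$t_off_defined,
                        t_off_at_edge = object$stages$fall$at_window_edge,
                        d_negative = is.finite(object$params$d) &&
                          object$params$d < 0))
  class(out) <- "summary.induction_fit"
  out
}

#' @export
print.summary.induction_fit <- function(x, ...) {
  print(x$fit)
  cat("  stage residual sums of squares:\n")
  print(signif(x$residual_ss, 4))
  cat("  flags:\n")
  print(x$flags)
  invisible(x)
}

#' Model curve from a staged fit
#'
#' `type = "model"` evaluates the full kinetic model (numerical solution
#' from the basal steady state) at the fitted parameters; it requires a
#' positive fitted `d`. `type = "stages"` returns the piecewise fitted
#' curves actually used in estimation (plateau, one-sided quadratics,
#' exponential decay) over their windows.
#'
#' @param object an `"induction_fit"`.
#' @param times evaluation times, min (default: the fitted trace's grid).
#' @param type `"model"` or `"stages"`.
#' @param ... unused.
#' @return For `"model"`, a numeric vector; for `"stages"`, a data frame
#'   `time_min`, `fitted`, `stage`.
#' @export
predict.induction_fit <- function(object, times = object$times,
                                  type = c("model", "stages"), ...) {
  type <- match.arg(type)
  p <- object$params
  if (type == "model") {
    if (!is.finite(p$d) || p$d <= 0)
      stop("fitted d <= 0: no model steady state; use type = \"stages\"")
    return(integrate_model(p, object$protocol, times, rtol = 1e-9))
  }
  w <- object$windows
  pr <- object$protocol
  seg <- function(win, fn, stage) {
    tt <- times[in_window(times, win)]
    if (!length(tt)) return(NULL)
    data.frame(time_min = tt, fitted = fn(tt), stage = stage,
               stringsAsFactors = FALSE)
  }
  rise <- object$stages$rise; fall <- object$stages$fall
  decay <- object$stages$decay
  out <- rbind(
    seg(w$basal, function(tt) rep(object$basal_plateau, length(tt)),
        "basal"),
    seg(w$rise, function(tt) object$basal_plateau +
          (rise$i * p$f / 2) * pmax(tt - rise$t_on, 0)^2, "rise"),
    seg(w$fall, function(tt) object$induced_plateau -
          (fall$i_fall * p$f / 2) *
            pmax(tt - pr$t_end - fall$t_off, 0)^2, "fall"),
    seg(w$decay, function(tt) object$basal_plateau +
          decay$F0 * exp(-decay$d * (tt - w$decay[1])), "decay"))
  rownames(out) <- NULL
  out
}

#' @export
fitted.induction_fit <- function(object, ...) {
  predict(object, type = "stages", ...)
}

#' @export
residuals.induction_fit <- function(object, ...) {
  st <- predict(object, type = "stages")
  obs <- object$fluorescence[match(st$time_min, object$times)]
  st$residual <- obs - st$fitted
  st$fitted <- NULL
  st
}

#' @export
plot.induction_fit <- function(x, ...,
                               xlab = "time (min)",
                               ylab = "fluorescence (maxGAL1)") {
  graphics::plot(x$times, x$fluorescence, pch = 16, cex = 0.6,
                 col = "grey40", xlab = xlab, ylab = ylab, ...)
  st <- predict(x, times = seq(min(x$times), max(x$times), by = 1),
                type = "stages")
  for (sg in unique(st$stage)) {
    sel <- st$stage == sg
    graphics::lines(st$time_min[sel], st$fitted[sel], col = "firebrick",
                    lwd = 2)
  }
  graphics::abline(v = c(x$protocol$t_start, x$protocol$t_end),
                   lty = 3, col = "grey60")
  invisible(x)
}

#' Simulate traces from a fitted model
#'
#' Generates a synthetic population whose central parameters are the
#' fitted ones (requires a positive fitted `d`).
#'
#' @param object an `"induction_fit"`.
#' @param nsim number of cells to simulate.
#' @param seed integer seed.
#' @param ... passed to [population_config()].
#' @return A `"synthetic_population"`.
#' @export
simulate.induction_fit <- function(object, nsim = 1, seed = 1L, ...) {
  p <- object$params
  if (!is.finite(p$d) || p$d <= 0) stop("cannot simulate with fitted d <= 0")
  if (is.na(p$b)) p$b <- 0
  generate_population(population_config(
    n_cells = nsim, central_params = p, protocol = object$protocol,
    seed = seed, ...))
}

#' @export
print.induction_fit_set <- function(x, ...) {
  cat(sprintf("Per-cell staged fits: %d cells\n", length(x$fits)))
  d <- vapply(x$fits, function(f) f$params$d, numeric(1))
  cat(sprintf("  fitted d: median %.4g 1/min, %d negative\n",
              stats::median(d), sum(d < 0)))
  invisible(x)
}

#' @export
coef.induction_fit_set <- function(object, ...) {
  t(vapply(object$fits, function(f) unlist(f$params), numeric(6)))
}
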