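## Two-compartment kinetic model of an inducible transcriptional system.
##
## U  unfolded (dark) protein:  dU/dt = b + i*S(t) - (f + d)*U
## F  mature fluorophore:       dF/dt = f*U - d*F
## S  promoter step input:      S(t) = 1  iff  t_start + t_on <= t < t_end + t_off
##
## Rates are per minute, amounts in maxGAL1 units. The closed forms below
## are the exact solutions of this linear system from the basal steady
## state; the Runge-Kutta integrator is the independent numerical oracle.

DEGENERATE_RATE_TOL <- 1e-8

#' Is the promoter active at time t?
#'
#' The step input of the model: 1 when `t_start + t_on <= t < t_end +
#' t_off`, else 0.
#'
#' @param t time, min (vectorized).
#' @param params a [kinetic_params()].
#' @param protocol an [induction_protocol()].
#' @return 0/1 numeric vector.
#' @export
step_input <- function(t, params, protocol = induction_protocol()) {
  as.numeric(t >= protocol$t_start + params$t_on &
               t < protocol$t_end + params$t_off)
}

#' Right-hand side of the kinetic model
#'
#' Time derivative of the state `(U, F)`: `dU/dt = b + i*S(t) - (f+d)*U`,
#' `dF/dt = f*U - d*F`, with the promoter step `S(t)` taken from the
#' protocol and lags.
#'
#' @param state numeric length-2 vector `c(U, F)`.
#' @param t time, min.
#' @param params a [kinetic_params()].
#' @param protocol an [induction_protocol()].
#' @return Numeric length-2 vector `c(dU, dF)`.
#' @export
model_rhs <- function(state, t, params, protocol = induction_protocol()) {
  s <- step_input(t, params, protocol)
  U <- state[[1]]; F <- state[[2]]
  c(params$b + params$i * s - (params$f + params$d) * U,
    params$f * U - params$d * F)
}

check_rates <- function(params) {
  if (abs(params$d) < DEGENERATE_RATE_TOL ||
      abs(params$f) < DEGENERATE_RATE_TOL ||
      abs(params$f + params$d) < DEGENERATE_RATE_TOL)
    stop("degenerate rates (d, f or f+d ~ 0): use integrate_model() instead")
}

#' Steady-state fluorescence
#'
#' Basal steady state `f*b / (d*(f+d))`; induced steady state
#' `f*(i+b) / (d*(f+d))`. Requires `d > 0` (otherwise no steady state
#' exists).
#'
#' @param params a [kinetic_params()].
#' @param induced logical; induced or basal plateau.
#' @return Fluorescence, maxGAL1.
#' @export
steady_state <- function(params, induced = FALSE) {
  if (params$d <= 0) stop("no steady state for d <= 0")
  rate <- if (induced) params$b + params$i else params$b
  params$f * rate / (params$d * (params$f + params$d))
}

#' Exact fluorescence during induction
#'
#' Closed-form solution for the mature-fluorophore level while the
#' promoter is on, starting from the basal steady state at the activation
#' time `t_start + t_on`:
#' `F_ON(t) = f(i+b)/(d(f+d)) - (i/d) e^{-d tau} + (i/(f+d)) e^{-(f+d) tau}`
#' with `tau = t - t_start - t_on`. Continuous at onset
#' (`F_ON(t_on) = f b/(d(f+d))`) and approaching the induced steady state
#' as `t` grows.
#'
#' @param params a [kinetic_params()].
#' @param t time, min (vectorized); must satisfy `t >= t_start + t_on`.
#' @param t_start induction signal onset, min.
#' @return Fluorescence, maxGAL1.
#' @export
closed_form_on <- function(params, t, t_start = 0) {
  check_rates(params)
  tau <- t - t_start - params$t_on
  if (any(tau < -1e-9)) stop("closed_form_on requires t >= t_start + t_on")
  with(params,
       f * (i + b) / (d * (f + d)) - (i / d) * exp(-d * tau) +
         (i / (f + d)) * exp(-(f + d) * tau))
}

#' Exact fluorescence after induction ends
#'
#' Closed-form relaxation back toward the basal steady state after the
#' promoter switches off at `t_end + t_off`. By default the state at
#' switch-off is taken from the exact on-phase solution for an induction
#' of finite duration `t_end + t_off - t_start - t_on`; with
#' `from_steady_state = TRUE` the induced plateau is assumed instead, and
#' the relaxation reduces to
#' `F_OFF(t) = f b/(d(f+d)) + (i/d) e^{-d sigma} - (i/(f+d)) e^{-(f+d) sigma}`
#' with `sigma = t - t_end - t_off`. Either way the solution decays to the
#' basal plateau `f b/(d(f+d))` and is continuous with [closed_form_on()]
#' at the switch-off time.
#'
#' @param params a [kinetic_params()].
#' @param t time, min (vectorized); must satisfy `t >= t_end + t_off`.
#' @param t_end induction signal removal, min.
#' @param t_start induction signal onset, min (sets the on-duration).
#' @param from_steady_state assume the induced plateau was reached.
#' @return Fluorescence, maxGAL1.
#' @export
closed_form_off <- function(params, t, t_end = 210, t_start = 0,
                            from_steady_state = FALSE) {
  check_rates(params)
  sigma <- t - t_end - params$t_off
  if (any(sigma < -1e-9)) stop("closed_form_off requires t >= t_end + t_off")
  f <- params$f; d <- params$d; b <- params$b; i <- params$i
  F_b <- f * b / (d * (f + d))
  if (from_steady_state) {
    A <- i / d
    C <- -i / (f + d)
  } else {
    tau2 <- t_end + params$t_off - t_start - params$t_on
    if (tau2 < 0) stop("switch-off precedes switch-on")
    U_dev <- (i / (f + d)) * (1 - exp(-(f + d) * tau2))  # U2 - b/(f+d)
    F2 <- closed_form_on(params, t_end + params$t_off, t_start)
    C <- -U_dev
    A <- F2 - F_b - C
  }
  F_b + A * exp(-d * sigma) + C * exp(-(f + d) * sigma)
}

#' Quadratic (second-order Taylor) onset approximation
#'
#' First two nonvanishing Taylor terms of the exact onset solution:
#' `(f/d) b/(d+f) + (i f / 2) (t - t_on)^2`. The linear term vanishes
#' because the fluorescence rise is purely second order at onset; the
#' truncation error grows as the cube of the time since onset.
#'
#' @param params a [kinetic_params()].
#' @param t time, min (vectorized), `t >= t_start + t_on`.
#' @param t_start induction signal onset, min.
#' @return Fluorescence, maxGAL1.
#' @export
taylor_on <- function(params, t, t_start = 0) {
  check_rates(params)
  tau <- t - t_start - params$t_on
  if (any(tau < -1e-9)) stop("taylor_on requires t >= t_start + t_on")
  with(params, (f / d) * b / (d + f) + (i * f / 2) * tau^2)
}

#' Quadratic (second-order Taylor) turn-off approximation
#'
#' First two Taylor terms of the relaxation from the induced plateau:
#' `(f/d)(b+i)/(d+f) - (i f / 2) (t - t_end - t_off)^2`.
#'
#' @param params a [kinetic_params()].
#' @param t time, min (vectorized), `t >= t_end + t_off`.
#' @param t_end induction signal removal, min.
#' @return Fluorescence, maxGAL1.
#' @export
taylor_off <- function(params, t, t_end = 210) {
  check_rates(params)
  sigma <- t - t_end - params$t_off
  if (any(sigma < -1e-9)) stop("taylor_off requires t >= t_end + t_off")
  with(params, (f / d) * (b + i) / (d + f) - (i * f / 2) * sigma^2)
}

## Cash-Karp embedded Runge-Kutta 4(5) step for the 2-state model with a
## piecewise-constant input held fixed inside each segment.
rk45_segment <- function(U, F, t0, t1, b_eff, fd, f, d, rtol, atol) {
  if (t1 <= t0) return(c(U, F))
  a2 <- 1 / 5; a3 <- 3 / 10; a4 <- 3 / 5; a5 <- 1; a6 <- 7 / 8
  b21 <- 1 / 5
  b31 <- 3 / 40; b32 <- 9 / 40
  b41 <- 3 / 10; b42 <- -9 / 10; b43 <- 6 / 5
  b51 <- -11 / 54; b52 <- 5 / 2; b53 <- -70 / 27; b54 <- 35 / 27
  b61 <- 1631 / 55296; b62 <- 175 / 512; b63 <- 575 / 13824
  b64 <- 44275 / 110592; b65 <- 253 / 4096
  c1 <- 37 / 378; c3 <- 250 / 621; c4 <- 125 / 594; c6 <- 512 / 1771
  d1 <- 2825 / 27648; d3 <- 18575 / 48384; d4 <- 13525 / 55296
  d5 <- 277 / 14336; d6 <- 1 / 4
  deriv <- function(u, f_) c(b_eff - fd * u, f * u - d * f_)
  t <- t0
  h <- min(t1 - t0, 5)
  y <- c(U, F)
  while (t < t1 - 1e-12) {
    h <- min(h, t1 - t)
    k1 <- deriv(y[1], y[2])
    y2 <- y + h * b21 * k1;                     k2 <- deriv(y2[1], y2[2])
    y3 <- y + h * (b31 * k1 + b32 * k2);        k3 <- deriv(y3[1], y3[2])
    y4 <- y + h * (b41 * k1 + b42 * k2 + b43 * k3)
    k4 <- deriv(y4[1], y4[2])
    y5 <- y + h * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4)
    k5 <- deriv(y5[1], y5[2])
    y6 <- y + h * (b61 * k1 + b62 * k2 + b63 * k3 + b64 * k4 + b65 * k5)
    k6 <- deriv(y6[1], y6[2])
    y_hi <- y + h * (c1 * k1 + c3 * k3 + c4 * k4 + c6 * k6)
    y_lo <- y + h * (d1 * k1 + d3 * k3 + d4 * k4 + d5 * k5 + d6 * k6)
    sc <- atol + rtol * pmax(abs(y), abs(y_hi))
    err <- max(abs(y_hi - y_lo) / sc)
    if (!is.finite(err)) err <- 2
    if (err <= 1) {
      t <- t + h
      y <- y_hi
      h <- h * min(5, max(0.2, 0.9 * if (err > 0) err^(-0.2) else 5))
    } else {
      h <- h * max(0.2, 0.9 * err^(-0.2))
    }
  }
  y
}

#' Numerically integrate the kinetic model
#'
#' Integrates the two-compartment model from the pre-induction steady
#' state `(U, F) = (b/(f+d), f b/(d (f+d)))` with an adaptive embedded
#' Runge-Kutta 4(5) scheme, splitting the integration at the
#' discontinuities of the promoter step (`t_start + t_on` and
#' `t_end + t_off`). Serves as the independent numerical oracle for the
#' closed-form solutions and as the trace engine of the synthetic-data
#' generator.
#'
#' @param params a [kinetic_params()].
#' @param protocol an [induction_protocol()].
#' @param times strictly increasing sampling times, min, within
#'   `[observe_from, observe_to]`.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return Numeric vector of noiseless fluorescence values at `times`.
#' @export
integrate_model <- function(params, protocol = induction_protocol(),
                            times = protocol_times(protocol),
                            rtol = 1e-9, atol = 1e-12) {
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (times[1] < protocol$observe_from - 1e-9 ||
      times[length(times)] > protocol$observe_to + 1e-9)
    stop("'times' must lie within the protocol observation window")
  if (params$d <= 0 && params$b > 0)
    warning("d <= 0 with basal input: no pre-induction steady state; using U=F=0")
  fd <- params$f + params$d
  if (params$d > 0) {
    U0 <- params$b / fd
    F0 <- params$f * params$b / (params$d * fd)
  } else {
    U0 <- 0; F0 <- 0
  }
  t_up <- protocol$t_start + params$t_on
  t_dn <- protocol$t_end + params$t_off
  t_init <- min(times[1], protocol$t_start)
  knots <- sort(unique(c(t_init, times, t_up, t_dn)))
  knots <- knots[knots >= t_init & knots <= times[length(times)]]
  out <- numeric(length(times))
  U <- U0; F <- F0
  for (k in seq_len(length(knots) - 1L)) {
    t0 <- knots[k]; t1 <- knots[k + 1L]
    tm <- (t0 + t1) / 2
    b_eff <- params$b + params$i * as.numeric(tm >= t_up && tm < t_dn)
    y <- rk45_segment(U, F, t0, t1, b_eff, fd, params$f, params$d,
                      rtol, atol)
    U <- y[1]; F <- y[2]
    hit <- which(abs(times - t1) < 1e-9)
    if (length(hit)) out[hit] <- F
  }
  if (any(abs(times - knots[1]) < 1e-9)) out[abs(times - knots[1]) < 1e-9] <- F0
  out
}

#' Log-log slope of the fluorescence rise
#'
#' Least-squares slope of `log(F - baseline)` against `log(t)` over a time
#' window; a value near 2 indicates the quadratic rise the second-order
#' model predicts at onset.
#'
#' @param times,fluorescence trace vectors (min, maxGAL1).
#' @param window numeric `c(from, to)` window, min; times must be
#'   positive inside it.
#' @param baseline plateau to subtract before taking logs, maxGAL1.
#' @return The fitted slope (dimensionless).
#' @export
loglog_rise_slope <- function(times, fluorescence, window = c(20, 70),
                              baseline = 0) {
  sel <- in_window(times, window)
  tt <- times[sel]; ff <- fluorescence[sel] - baseline
  if (length(tt) < 2) stop("need at least 2 points in the window")
  if (any(tt <= 0)) stop("window must contain only positive times")
  if (any(ff <= 0)) stop("non-positive fluorescence after baseline subtraction")
  unname(stats::coef(stats::lm(log(ff) ~ log(tt)))[2])
}
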