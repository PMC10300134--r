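#' Kinetic parameters of an inducible transcriptional system
#'
#' Bundles the six parameters of the two-compartment expression model:
#' basal synthesis rate `b`, induced synthesis-rate increment `i` (both in
#' maxGAL1 per minute), fluorophore maturation rate `f` and
#' degradation-and-dilution rate `d` (per minute), and the activation and
#' deactivation lags `t_on`, `t_off` (minutes) of the promoter's step
#' response.
#'
#' `f` must be strictly positive; `i`, `t_on` and `t_off` are non-negative
#' (the fitting bounds). `b` must be non-negative for simulation input.
#' `d` may be non-positive only when the object carries a raw fit outcome
#' (a negative fitted `d` is an exclusion signal downstream); pass
#' `allow_nonpositive_d = TRUE` for that case.
#'
#' @param b basal synthesis rate, maxGAL1/min.
#' @param i induced synthesis-rate increment, maxGAL1/min.
#' @param f maturation rate, 1/min.
#' @param d degradation-and-dilution rate, 1/min.
#' @param t_on activation lag after inducer addition, min.
#' @param t_off deactivation lag after inducer removal, min.
#' @param allow_nonpositive_d permit `d <= 0` (raw fit outcomes only).
#' @return An object of class `"kinetic_params"` (a named list).
#' @examples
#' kinetic_params(b = 1e-4, i = 0.001, f = 0.035, d = 0.017,
#'                t_on = 10, t_off = 5)
#' @export
kinetic_params <- function(b = 0, i = 0, f = log(2) / 20, d = 0.017,
                           t_on = 0, t_off = 0,
                           allow_nonpositive_d = FALSE) {
  for (nm in c("b", "i", "f", "d", "t_on", "t_off")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a finite numeric scalar", nm))
  }
  if (f <= 0) stop("maturation rate 'f' must be > 0")
  if (i < 0) stop("induction increment 'i' must be >= 0")
  if (b < 0) stop("basal rate 'b' must be >= 0")
  if (t_on < 0 || t_off < 0) stop("lags 't_on'/'t_off' must be >= 0")
  if (d <= 0 && !allow_nonpositive_d)
    stop("'d' must be > 0 (set allow_nonpositive_d = TRUE for raw fits)")
  structure(list(b = b, i = i, f = f, d = d, t_on = t_on, t_off = t_off),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters of an inducible system\n")
  cat(sprintf("  b     = %-10.4g maxGAL1/min (basal synthesis)\n", x$b))
  cat(sprintf("  i     = %-10.4g maxGAL1/min (induction speed)\n", x$i))
  cat(sprintf("  f     = %-10.4g 1/min       (maturation)\n", x$f))
  cat(sprintf("  d     = %-10.4g 1/min       (degradation-and-dilution)\n",
              x$d))
  cat(sprintf("  t_on  = %-10.4g min         (activation lag)\n", x$t_on))
  cat(sprintf("  t_off = %-10.4g min         (deactivation lag)\n", x$t_off))
  invisible(x)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(kinetic_params(b = x$b, i = x$i, f = x$f, d = x$d,
                          t_on = x$t_on, t_off = x$t_off,
                          allow_nonpositive_d = TRUE))
  }
  stop("cannot interpret 'params' as kinetic parameters")
}

#' Induction protocol of a time-lapse experiment
#'
#' Describes the experimental design around which the model's step input is
#' built: induction signal on at `t_start` (canonically 0 min) and off at
#' `t_end` (canonically 210 min, i.e. 3.5 h), with observation from
#' `observe_from` (canonically -60 min, at least 1 h pre-induction) to
#' `observe_to` (canonically 390 min, 3 h post-induction) and images every
#' `sampling_interval` minutes (canonically 10). `media_delay_s` is the
#' transport lag of the medium to the microfluidic chamber in seconds
#' (canonically 170 s), subtracted from the fitted lags for chemically
#' induced systems. `pre_induction_sampled = FALSE` reproduces optogenetic
#' runs in which fluorescence was not measured before induction.
#'
#' @param t_start,t_end induction window, min.
#' @param observe_from,observe_to observation window, min.
#' @param sampling_interval imaging interval, min.
#' @param media_delay_s media transport lag, seconds.
#' @param pre_induction_sampled are pre-induction timepoints imaged?
#' @return An object of class `"induction_protocol"`.
#' @export
induction_protocol <- function(t_start = 0, t_end = 210,
                               observe_from = -60, observe_to = 390,
                               sampling_interval = 10,
                               media_delay_s = 170,
                               pre_induction_sampled = TRUE) {
  if (!(observe_from <= t_start && t_start < t_end && t_end <= observe_to))
    stop("need observe_from <= t_start < t_end <= observe_to")
  if (sampling_interval <= 0) stop("sampling_interval must be > 0")
  structure(list(t_start = t_start, t_end = t_end,
                 observe_from = observe_from, observe_to = observe_to,
                 sampling_interval = sampling_interval,
                 media_delay_s = media_delay_s,
                 pre_induction_sampled = pre_induction_sampled),
            class = "induction_protocol")
}

#' @export
print.induction_protocol <- function(x, ...) {
  cat(sprintf(
    "Induction protocol: signal on [%g, %g) min, observed [%g, %g] min every %g min\n",
    x$t_start, x$t_end, x$observe_from, x$observe_to, x$sampling_interval))
  cat(sprintf("  media delay %g s; pre-induction sampled: %s\n",
              x$media_delay_s, x$pre_induction_sampled))
  invisible(x)
}

#' Sampling grid of a protocol
#'
#' Timepoints at which the experiment images cells: `observe_from` to
#' `observe_to` in steps of `sampling_interval`, restricted to
#' `[t_start, observe_to]` when pre-induction fluorescence is not measured.
#'
#' @param protocol an [induction_protocol()].
#' @return Numeric vector of times in minutes.
#' @export
protocol_times <- function(protocol) {
  tt <- seq(protocol$observe_from, protocol$observe_to,
            by = protocol$sampling_interval)
  if (!protocol$pre_induction_sampled) tt <- tt[tt >= protocol$t_start]
  tt
}

#' Fitting windows of the staged estimation
#'
#' The four time windows (minutes, induction onset at 0) used by the staged
#' fit: `basal` for the pre-induction plateau, `rise` for the quadratic
#' onset fit, `fall` for the quadratic turn-off fit, and `decay` for the
#' exponential decay fit. Defaults follow the canonical chemical-induction
#' design; systems with nonmonotonic activation or late onset use
#' overrides (e.g. `rise = c(-50, 30)`, or `basal = c(0, 0)` together with
#' `rise = c(0, 60)` for optogenetic systems with no pre-induction
#' samples).
#'
#' @param basal,rise,fall,decay numeric length-2 windows `c(from, to)` in
#'   minutes; `basal` may collapse to a single timepoint `c(0, 0)`.
#' @return An object of class `"fit_windows"`.
#' @export
fit_windows <- function(basal = c(-60, 0), rise = c(-50, 50),
                        fall = c(210, 270), decay = c(270, 390)) {
  w <- list(basal = basal, rise = rise, fall = fall, decay = decay)
  for (nm in names(w)) {
    v <- w[[nm]]
    if (!is.numeric(v) || length(v) != 2L || v[1] > v[2])
      stop(sprintf("window '%s' must be numeric c(from, to) with from <= to", nm))
  }
  structure(w, class = "fit_windows")
}

in_window <- function(times, window) {
  times >= window[1] & times <= window[2]
}
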