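## Population-level statistics: maxGAL1 normalization, bootstrap lag
## confidence intervals, noise scaling, violin/bimodality summaries,
## event alignment and the one-tailed z test.

#' Normalize fluorescence to maxGAL1 units
#'
#' Divides background-subtracted fluorescence by the reference level of
#' the GAL1-promoter reporter: 1 maxGAL1 is the mean of the GAL1pr
#' stationary-state distribution, outliers included.
#'
#' @param x a trace data frame (column `fluorescence`) or numeric vector.
#' @param gal1_steady_state the reference level, arbitrary units (> 0).
#' @return `x` with fluorescence expressed in maxGAL1.
#' @export
normalize_to_maxgal1 <- function(x, gal1_steady_state) {
  if (!is.numeric(gal1_steady_state) || length(gal1_steady_state) != 1 ||
      gal1_steady_state <= 0)
    stop("gal1_steady_state must be a positive scalar")
  if (is.data.frame(x)) {
    x$fluorescence <- x$fluorescence / gal1_steady_state
    x
  } else {
    x / gal1_steady_state
  }
}

#' Reference level from a GAL1pr population
#'
#' The mean fluorescence of the reference population at its stationary
#' timepoint (nearest sampled time), computed over all cells with no
#' outlier removal — the definition of 1 maxGAL1.
#'
#' @param traces long trace data frame.
#' @param at_time stationary timepoint, min.
#' @return The reference level (same units as the traces).
#' @export
maxgal1_reference <- function(traces, at_time = 210) {
  tt <- unique(traces$time_min)
  t_ref <- tt[which.min(abs(tt - at_time))]
  mean(traces$fluorescence[traces$time_min == t_ref])
}

#' Cross-batch calibration factor
#'
#' Multiplicative factor mapping batch B's fluorescence units onto batch
#' A's maxGAL1 scale through a shared reference construct measured in
#' both (e.g. the leaky tetO promoter's basal level).
#'
#' @param batch_a_ref,batch_b_ref the shared reference's level in each
#'   batch's units (> 0).
#' @return Scalar factor: multiply batch B values by it.
#' @export
cross_calibrate <- function(batch_a_ref, batch_b_ref) {
  if (batch_a_ref <= 0 || batch_b_ref <= 0)
    stop("references must be positive")
  batch_a_ref / batch_b_ref
}

#' Bootstrap confidence intervals for the activation/deactivation lags
#'
#' Resamples `sample_size` single-cell time courses with replacement,
#' averages them pointwise, fits the lag stages on the average trace, and
#' repeats `n_resamples` times; the 95% interval spans the 2.5th to
#' 97.5th percentiles of the resampled lag estimates. Resamples whose fit
#' fails are dropped (and counted).
#'
#' @param traces long trace data frame (or `"synthetic_population"`).
#' @param f fixed maturation rate, 1/min.
#' @param windows a [fit_windows()].
#' @param protocol an [induction_protocol()].
#' @param chemically_induced apply the media-delay correction.
#' @param n_resamples number of bootstrap resamples.
#' @param sample_size cells drawn per resample (with replacement).
#' @param seed integer seed; results are deterministic given it.
#' @param lags which lags to bootstrap: subset of `c("on", "off")`.
#' @param level confidence level.
#' @param control a [fit_control()].
#' @return List with `t_on_ci`, `t_off_ci` (each `c(lower, upper)` or
#'   NULL), the resampled estimates, and `n_failed`.
#' @export
bootstrap_lag_ci <- function(traces, f = log(2) / 20,
                             windows = fit_windows(),
                             protocol = induction_protocol(),
                             chemically_induced = TRUE,
                             n_resamples = 1000, sample_size = 100,
                             seed = 1L, lags = c("on", "off"),
                             level = 0.95, control = fit_control()) {
  if (inherits(traces, "synthetic_population")) traces <- traces$traces
  lags <- match.arg(lags, c("on", "off"), several.ok = TRUE)
  ids <- unique(traces$cell_id)
  if (length(ids) < sample_size)
    stop("need at least 'sample_size' cells (resampling with replacement)")
  tt <- sort(unique(traces$time_min))
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(tt),
                dimnames = list(ids, NULL))
  mat[cbind(match(traces$cell_id, ids), match(traces$time_min, tt))] <-
    traces$fluorescence
  if (anyNA(mat)) stop("cells must share a common time grid")
  delay_min <- if (chemically_induced) protocol$media_delay_s / 60 else 0
  sel_basal <- in_window(tt, windows$basal)
  t_end_idx <- which.min(abs(tt - protocol$t_end))

  with_seed(seed, {
    t_on_s <- t_off_s <- rep(NA_real_, n_resamples)
    n_failed <- 0L
    for (r in seq_len(n_resamples)) {
      idx <- sample.int(length(ids), sample_size, replace = TRUE)
      avg <- colMeans(mat[idx, , drop = FALSE])
      ok <- TRUE
      basal <- mean(avg[sel_basal])
      if ("on" %in% lags) {
        rs <- try(fit_rise(tt, avg, f_fixed = f, window = windows$rise,
                           basal_plateau = basal, control = control),
                  silent = TRUE)
        if (inherits(rs, "try-error") || !rs$converged) ok <- FALSE
        else t_on_s[r] <- max(0, rs$t_on - delay_min)
      }
      if ("off" %in% lags) {
        fl <- try(fit_fall(tt, avg, f_fixed = f, window = windows$fall,
                           induced_plateau = avg[t_end_idx],
                           t_end = protocol$t_end, control = control),
                  silent = TRUE)
        if (inherits(fl, "try-error") || !fl$converged) ok <- FALSE
        else t_off_s[r] <- max(0, fl$t_off - delay_min)
      }
      if (!ok) {
        n_failed <- n_failed + 1L
        t_on_s[r] <- t_off_s[r] <- NA_real_
      }
    }
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NULL)
      unname(stats::quantile(x, probs))
    }
    list(t_on_ci = if ("on" %in% lags) ci(t_on_s) else NULL,
         t_off_ci = if ("off" %in% lags) ci(t_off_s) else NULL,
         t_on_samples = if ("on" %in% lags) t_on_s else NULL,
         t_off_samples = if ("off" %in% lags) t_off_s else NULL,
         n_failed = n_failed)
  })
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; the per-population
#' noise measure, evaluated at the last induction timepoint in the
#' benchmark.
#'
#' @param values numeric vector with positive mean.
#' @return SD/mean.
#' @export
compute_cv <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive")
  stats::sd(values) / m
}

#' Noise-versus-mean scaling regression
#'
#' Ordinary least squares of `log10(CV)` on `log10(mean)` across systems,
#' after dropping the configured exclusions; reports slope, intercept,
#' R-squared and the slope's confidence interval.
#'
#' @param points data frame with columns `system`, `mean`, `cv`.
#' @param exclude character vector of system labels to exclude.
#' @param level confidence level for the slope CI.
#' @return List with `slope`, `intercept`, `r_squared`, `slope_ci`,
#'   `n_used`, `excluded`.
#' @export
noise_scaling_regression <- function(points, exclude = character(),
                                     level = 0.95) {
  stopifnot(all(c("system", "mean", "cv") %in% names(points)))
  keep <- !(points$system %in% exclude)
  pts <- points[keep & points$mean > 0 & points$cv > 0, , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 points after exclusion")
  fit <- stats::lm(log10(cv) ~ log10(mean), data = pts)
  ci <- suppressWarnings(stats::confint(fit, "log10(mean)",
                                        level = level))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       slope_ci = unname(ci[1, ]),
       n_used = nrow(pts),
       excluded = points$system[!keep])
}

## biased (population) central moments, kurtosis non-excess — required
## for the 5/9 uniform/exponential reference value
sample_moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  list(skewness = mean((x - m)^3) / m2^1.5,
       kurtosis = mean((x - m)^4) / m2^2)
}

#' Bimodality coefficient
#'
#' `(skewness^2 + 1) / kurtosis` with plain (biased) sample moments and
#' non-excess kurtosis. Equals 1/3 for the normal distribution and 5/9
#' for the uniform and exponential distributions; values above 5/9 are
#' treated as bimodal.
#'
#' @param values numeric vector (n >= 4).
#' @return The coefficient (dimensionless).
#' @export
bimodality_coefficient <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  mo <- sample_moments(values)
  (mo$skewness^2 + 1) / mo$kurtosis
}

#' Otsu threshold of a 1-D sample
#'
#' Histograms the values into `n_bins` equal-width bins and returns the
#' bin edge that maximizes the between-class variance of the split
#' (ties broken toward the lower threshold).
#'
#' @param values numeric vector, non-constant.
#' @param n_bins number of histogram bins.
#' @return The threshold (same units as `values`).
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  rng <- range(values)
  if (diff(rng) == 0) stop("values are constant: no threshold exists")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  n <- length(values)
  w0 <- cumsum(counts)[-n_bins] / n
  mu0 <- cumsum(counts * centers)[-n_bins] / n
  mu_t <- sum(counts * centers) / n
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma_b)  # first maximum = lower threshold on ties
  breaks[k + 1]
}

#' Violin-plot summary with adaptive bandwidth
#'
#' The distribution summary behind the benchmark's violin plots:
#' values more than two standard deviations from the mean are set aside
#' as outlier dots; the bimodality coefficient of the remainder decides
#' whether the kernel bandwidth is the unimodal `0.8 * sd / n^(1/5)` or,
#' for bimodal samples (coefficient > 5/9), the smaller of the two
#' subpopulation bandwidths after an Otsu split. If a split side has
#' fewer than 2 points the unimodal bandwidth is used and flagged.
#'
#' @param values numeric vector, n >= 5.
#' @param n_bins Otsu histogram bins.
#' @return An object of class `"violin_summary"`.
#' @export
violin_summary <- function(values, n_bins = 256) {
  if (length(values) < 5) stop("need at least 5 values")
  m <- mean(values); s <- stats::sd(values)
  out_mask <- abs(values - m) > 2 * s
  kept <- values[!out_mask]
  bw_unimodal <- function(x) 0.8 * stats::sd(x) / length(x)^(1 / 5)
  bc <- bimodality_coefficient(kept)
  bimodal <- bc > 5 / 9
  split <- NA_real_
  sub_bw <- NULL
  fallback <- FALSE
  if (bimodal) {
    split <- otsu_threshold(kept, n_bins)
    lo <- kept[kept <= split]; hi <- kept[kept > split]
    if (length(lo) < 2 || length(hi) < 2) {
      fallback <- TRUE
      bw <- bw_unimodal(kept)
    } else {
      sub_bw <- c(lower = bw_unimodal(lo), upper = bw_unimodal(hi))
      bw <- min(sub_bw)
    }
  } else {
    bw <- bw_unimodal(kept)
  }
  structure(list(kept = kept, outliers = values[out_mask],
                 bimodality_coefficient = bc, bimodal = bimodal,
                 split_threshold = split, bandwidth = bw,
                 subpop_bandwidths = sub_bw,
                 unimodal_fallback = fallback),
            class = "violin_summary")
}

#' @export
print.violin_summary <- function(x, ...) {
  cat(sprintf(
    "Violin summary: n = %d kept, %d outliers (>2 SD)\n",
    length(x$kept), length(x$outliers)))
  cat(sprintf("  bimodality coefficient %.4f (threshold 5/9 = %.4f): %s\n",
              x$bimodality_coefficient, 5 / 9,
              if (x$bimodal) "bimodal" else "unimodal"))
  if (x$bimodal && !x$unimodal_fallback)
    cat(sprintf("  Otsu split at %.4g; bandwidths %.4g / %.4g\n",
                x$split_threshold, x$subpop_bandwidths[1],
                x$subpop_bandwidths[2]))
  cat(sprintf("  kernel bandwidth %.4g\n", x$bandwidth))
  invisible(x)
}

#' Align single-cell trajectories on a per-cell event
#'
#' Shifts each cell's time axis so that its event (e.g. budding) is at
#' time 0, and summarizes mean and SD at every aligned timepoint where at
#' least two cells overlap.
#'
#' @param traces long trace data frame.
#' @param event_times named numeric vector (names = cell ids) or data
#'   frame with columns `cell_id`, `event_time_min`.
#' @return List with `traces` (plus column `time_aligned`) and `summary`
#'   (`time_aligned`, `n`, `mean`, `sd`).
#' @export
align_by_event <- function(traces, event_times) {
  if (is.data.frame(event_times))
    event_times <- stats::setNames(event_times$event_time_min,
                                   event_times$cell_id)
  ids <- unique(traces$cell_id)
  missing <- setdiff(ids, names(event_times))
  if (length(missing))
    stop("missing event time for cell(s): ",
         paste(missing, collapse = ", "))
  traces$time_aligned <- traces$time_min -
    unname(event_times[traces$cell_id])
  key <- round(traces$time_aligned, 6)
  agg <- stats::aggregate(traces$fluorescence, by = list(time = key),
                          FUN = function(v) c(n = length(v),
                                              mean = mean(v),
                                              sd = stats::sd(v)))
  summ <- data.frame(time_aligned = agg$time,
                     n = agg$x[, "n"], mean = agg$x[, "mean"],
                     sd = agg$x[, "sd"])
  summ <- summ[summ$n >= 2, , drop = FALSE]
  rownames(summ) <- NULL
  list(traces = traces, summary = summ)
}

#' One-tailed z test for a difference of means
#'
#' Standard z statistic on the difference of sample means with the
#' samples' own standard deviations:
#' `z = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)`.
#'
#' @param sample_a,sample_b numeric vectors (n >= 2 each).
#' @param alternative `"greater"` tests mean(a) > mean(b).
#' @return One-tailed p value.
#' @export
one_tailed_z_test <- function(sample_a, sample_b,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("need n >= 2 in both samples")
  se <- sqrt(stats::var(sample_a) / length(sample_a) +
               stats::var(sample_b) / length(sample_b))
  dm <- mean(sample_a) - mean(sample_b)
  if (se == 0) return(if (dm == 0) 0.5 else if (dm > 0) 0 else 1)
  z <- dm / se
  if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
  else stats::pnorm(z)
}
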