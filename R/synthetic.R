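## Seeded synthetic induction experiments: single-cell fluorescence traces
## with cell-to-cell parameter variability, autofluorescence offsets and
## measurement noise; colony-area growth series; 1-D expression samples.

#' Configuration of a synthetic cell population
#'
#' Describes a simulated induction experiment. Each cell draws its rates
#' (`b`, `i`, `d`) lognormally around the central parameters with the
#' given coefficients of variation (parameterized so the population mean
#' equals the central value) and its lags (`t_on`, `t_off`) from a normal
#' distribution truncated at zero with standard deviation `lag_sd`. The
#' maturation rate `f` is common to all cells (it is a property of the
#' fluorophore). Traces are the noiseless model solution plus a
#' cell-constant autofluorescence offset plus i.i.d. Gaussian measurement
#' noise per timepoint.
#'
#' `noise_sd = NULL` defaults to 5% of the central induced steady state,
#' the package's stand-in for typical segmentation noise.
#'
#' @param n_cells number of cells.
#' @param central_params central [kinetic_params()].
#' @param cv_params named CVs for the lognormal rate variability
#'   (entries `b`, `i`, `d`).
#' @param lag_sd standard deviation of the truncated-normal lag
#'   variability, min.
#' @param noise_sd additive measurement noise SD, maxGAL1 (or NULL).
#' @param autofluorescence_mean,autofluorescence_sd cell-constant offset
#'   distribution, maxGAL1.
#' @param protocol an [induction_protocol()].
#' @param outlier_fraction fraction of cells replaced by pathological
#'   traces (see [inject_outlier_cells()]).
#' @param seed integer seed; the whole experiment is deterministic given
#'   it.
#' @param sim_rtol relative tolerance passed to [integrate_model()].
#' @return An object of class `"population_config"`.
#' @export
population_config <- function(n_cells = 200,
                              central_params = kinetic_params(
                                b = 1e-4, i = 0.001, f = 0.035, d = 0.017,
                                t_on = 10, t_off = 5),
                              cv_params = c(b = 0.2, i = 0.2, d = 0.2),
                              lag_sd = 2,
                              noise_sd = NULL,
                              autofluorescence_mean = 0,
                              autofluorescence_sd = 0,
                              protocol = induction_protocol(),
                              outlier_fraction = 0,
                              seed = 1L,
                              sim_rtol = 1e-7) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  central_params <- as_kinetic_params(central_params)
  if (is.null(noise_sd))
    noise_sd <- 0.05 * steady_state(central_params, induced = TRUE)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cv <- c(b = 0, i = 0, d = 0)
  cv[names(cv_params)] <- cv_params
  structure(list(n_cells = as.integer(n_cells),
                 central_params = central_params,
                 cv_params = cv, lag_sd = lag_sd, noise_sd = noise_sd,
                 autofluorescence_mean = autofluorescence_mean,
                 autofluorescence_sd = autofluorescence_sd,
                 protocol = protocol,
                 outlier_fraction = outlier_fraction,
                 seed = as.integer(seed), sim_rtol = sim_rtol),
            class = "population_config")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

rlnorm_mean <- function(n, mean, cv) {
  if (mean == 0 || cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < 0)) out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Generate a synthetic single-cell induction experiment
#'
#' Draws per-cell kinetic parameters around the configured central values,
#' integrates the model for every cell on the protocol's sampling grid,
#' and adds the cell-constant autofluorescence offset and per-timepoint
#' Gaussian measurement noise. Ground-truth parameters are returned
#' alongside the traces so recovery can be scored.
#'
#' @param config a [population_config()].
#' @param system label written into the trace table.
#' @return An object of class `"synthetic_population"`: a list with
#'   `traces` (long data frame: `cell_id`, `time_min`, `fluorescence`,
#'   `system`, `background_subtracted`), `truth` (per-cell parameters,
#'   offsets and outlier tags) and `config`.
#' @export
generate_population <- function(config = population_config(),
                                system = "synthetic") {
  stopifnot(inherits(config, "population_config"))
  with_seed(config$seed, {
    n <- config$n_cells
    cp <- config$central_params
    cv <- config$cv_params
    truth <- data.frame(
      cell_id = sprintf("cell_%03d", seq_len(n)),
      b = rlnorm_mean(n, cp$b, cv[["b"]]),
      i = rlnorm_mean(n, cp$i, cv[["i"]]),
      f = rep(cp$f, n),
      d = rlnorm_mean(n, cp$d, cv[["d"]]),
      t_on = rnorm_trunc0(n, cp$t_on, config$lag_sd),
      t_off = rnorm_trunc0(n, cp$t_off, config$lag_sd),
      autofluorescence = stats::rnorm(n, config$autofluorescence_mean,
                                      config$autofluorescence_sd),
      outlier = FALSE, outlier_type = NA_character_,
      stringsAsFactors = FALSE)
    if (any(truth$d <= 0) && config$outlier_fraction == 0)
      stop("drew d <= 0; reduce cv_params['d']")
    times <- protocol_times(config$protocol)
    m <- length(times)
    traces <- vector("list", n)
    for (k in seq_len(n)) {
      pk <- kinetic_params(b = truth$b[k], i = truth$i[k], f = truth$f[k],
                           d = truth$d[k], t_on = truth$t_on[k],
                           t_off = truth$t_off[k])
      ff <- integrate_model(pk, config$protocol, times,
                            rtol = config$sim_rtol) +
        truth$autofluorescence[k] +
        stats::rnorm(m, 0, config$noise_sd)
      traces[[k]] <- data.frame(cell_id = truth$cell_id[k],
                                time_min = times, fluorescence = ff,
                                system = system,
                                background_subtracted = TRUE,
                                stringsAsFactors = FALSE)
    }
    pop <- structure(list(traces = do.call(rbind, traces), truth = truth,
                          config = config),
                     class = "synthetic_population")
    if (config$outlier_fraction > 0)
      pop <- inject_outlier_cells(pop, config$outlier_fraction,
                                  seed = config$seed + 1L)
    pop
  })
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf(
    "Synthetic induction experiment: %d cells x %d timepoints (seed %d)\n",
    nrow(x$truth), length(unique(x$traces$time_min)), x$config$seed))
  cat(sprintf("  noise SD %.4g maxGAL1, %d tagged outlier cells\n",
              x$config$noise_sd, sum(x$truth$outlier)))
  invisible(x)
}

#' Replace a fraction of cells with pathological traces
#'
#' Emulates the cell classes the exclusion rules target: cells whose
#' fluorescence keeps rising after promoter shutoff (these yield a
#' negative fitted degradation-and-dilution rate) and cells that start the
#' induction brighter than they are one hour after shutoff (a decaying,
#' pre-induced trace). Replaced cells alternate between the two types and
#' are tagged in the ground truth so exclusion logic can be scored.
#'
#' @param population a `"synthetic_population"`.
#' @param fraction fraction of cells to replace, in `[0, 1)`; exactly
#'   `round(fraction * n_cells)` cells are tagged.
#' @param seed integer seed.
#' @return The modified `"synthetic_population"`.
#' @export
inject_outlier_cells <- function(population, fraction, seed = 1L) {
  stopifnot(inherits(population, "synthetic_population"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n_out <- round(fraction * nrow(population$truth))
  if (n_out == 0) return(population)
  with_seed(seed, {
    cfg <- population$config
    pr <- cfg$protocol
    times <- protocol_times(pr)
    pick <- sample(nrow(population$truth), n_out)
    for (j in seq_along(pick)) {
      k <- pick[j]
      id <- population$truth$cell_id[k]
      type <- if (j %% 2L == 1L) "rising_after_shutoff" else "pre_induced"
      cp <- cfg$central_params
      if (type == "rising_after_shutoff") {
        ## promoter never shuts off within the observation window, and
        ## turnover is anomalously slow, so the trace keeps climbing
        ## through the decay window instead of saturating
        pk <- kinetic_params(b = cp$b, i = cp$i, f = cp$f, d = cp$d / 5,
                             t_on = cp$t_on,
                             t_off = pr$observe_to - pr$t_end + 60)
        ff <- integrate_model(pk, pr, times, rtol = cfg$sim_rtol)
      } else {
        ## cell arrives induced and decays through the whole course
        ff <- steady_state(cp, induced = TRUE) *
          exp(-cp$d * (times - times[1]))
      }
      ff <- ff + stats::rnorm(length(times), 0, cfg$noise_sd)
      sel <- population$traces$cell_id == id
      population$traces$fluorescence[sel] <-
        ff[match(population$traces$time_min[sel], times)]
      population$truth$outlier[k] <- TRUE
      population$truth$outlier_type[k] <- type
    }
    population
  })
}

#' Synthetic colony-area growth series
#'
#' Exponential area growth `A(t) = A0 * exp(rate * t)` sampled on the
#' protocol grid with multiplicative lognormal noise of coefficient of
#' variation `noise_cv`.
#'
#' @param rate growth rate, 1/min (> 0).
#' @param t_range sampled time span `c(from, to)`, min.
#' @param by sampling interval, min.
#' @param noise_cv multiplicative noise CV (0 for noiseless).
#' @param seed integer seed.
#' @param area0 area at `t = 0`, pixel^2.
#' @param colony_id label.
#' @return Data frame with columns `colony_id`, `time_min`, `area`.
#' @export
generate_growth_series <- function(rate, t_range = c(-60, 390), by = 10,
                                   noise_cv = 0, seed = 1L,
                                   area0 = 1000, colony_id = "colony_1") {
  if (rate <= 0) stop("rate must be > 0")
  tt <- seq(t_range[1], t_range[2], by = by)
  with_seed(seed, {
    noise <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(length(tt), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(tt))
    data.frame(colony_id = colony_id, time_min = tt,
               area = area0 * exp(rate * tt) * noise,
               stringsAsFactors = FALSE)
  })
}

#' Gaussian-mixture sample
#'
#' Seeded draw from a finite Gaussian mixture; the fixture for the
#' bimodality-coefficient and Otsu-splitting logic.
#'
#' @param n sample size.
#' @param weights mixture weights (must sum to 1).
#' @param means,sds component means and SDs.
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_bimodal_sample <- function(n, weights = c(0.5, 0.5),
                                    means = c(-3, 3), sds = c(1, 1),
                                    seed = 1L) {
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  stopifnot(length(weights) == length(means),
            length(means) == length(sds))
  with_seed(seed, {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    stats::rnorm(n, means[comp], sds[comp])
  })
}

#' Approximate presets for benchmarked inducible systems
#'
#' A small table of inducible transcriptional systems with approximate
#' parameter values assembled from reported text-level characteristics
#' (steady-state level relative to the GAL1 promoter, leakiness, relative
#' lags). Values marked `approximate = TRUE` are order-of-magnitude
#' anchors for simulation, not measured parameter sets; entries whose
#' kinetic rates were chosen by the package to reproduce the quoted
#' steady-state level carry a note saying so.
#'
#' @return Data frame with one row per preset: kinetic parameters, the
#'   steady-state level and leakiness in maxGAL1, and a provenance note.
#' @export
system_presets <- function() {
  f <- 0.035; d <- 0.017
  ss_to_i <- function(ss, b = 0) ss * d * (f + d) / f - b
  leak_to_b <- function(leak) leak * d * (f + d) / f
  rows <- list(
    list("GAL1pr", 0, ss_to_i(1), f, d, 20, 5, 1, 0,
         "steady state 1 maxGAL1 by unit definition; rates synthetic"),
    list("GALL", 0, ss_to_i(0.02), f, d, 10, 10, 0.02, 0,
         "steady state ~0.02 maxGAL1 (weakest of the GAL set); rates synthetic"),
    list("tetOpr", leak_to_b(0.01), ss_to_i(0.1, leak_to_b(0.01)), f, d,
         25, 15, 0.1, 0.01,
         "basal expression ~1% maxGAL1 (leaky doxycycline system); induced level synthetic"),
    list("El222_LIP", 0, ss_to_i(0.1), f, d, 5, 5, 0.1, 0,
         "fast light-induced system; levels synthetic, lags short"),
    list("strongLOV_LIP", leak_to_b(0.0032),
         ss_to_i(0.57, leak_to_b(0.0032)), f, d, 5, 27,
         0.57, 0.0032,
         "5.7x El222 maximal intensity, 3.2x its leakiness, t_off 22 min longer"),
    list("AQTrip_LIP", 0, ss_to_i(0.34), f, d, 5, 15, 0.34, 0,
         "3.4x El222 maximal intensity; other values synthetic"))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(system = r[[1]], b = r[[2]], i = r[[3]], f = r[[4]],
               d = r[[5]], t_on = r[[6]], t_off = r[[7]],
               steady_state_maxgal1 = r[[8]], leakiness_maxgal1 = r[[9]],
               approximate = TRUE, note = r[[10]],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Kinetic parameters of a named preset
#'
#' @param name a system name from [system_presets()].
#' @return A [kinetic_params()] object.
#' @export
preset_params <- function(name) {
  tab <- system_presets()
  row <- tab[tab$system == name, ]
  if (nrow(row) != 1) stop("unknown preset: ", name)
  kinetic_params(b = row$b, i = row$i, f = row$f, d = row$d,
                 t_on = row$t_on, t_off = row$t_off)
}
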