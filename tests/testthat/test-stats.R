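# Population statistics: normalization, calibration, bootstrap lags,
# CV scaling, bimodality/Otsu summaries, alignment, z test.

test_that("maxGAL1 normalization and the reference definition", {
  tt <- seq(-60, 390, 10)
  tr <- data.frame(cell_id = rep(c("a", "b"), each = length(tt)),
                   time_min = rep(tt, 2),
                   fluorescence = rep(c(100, 300), each = length(tt)))
  ref <- maxgal1_reference(tr, at_time = 210)
  expect_equal(ref, 200)  # mean over cells, outliers included
  norm <- normalize_to_maxgal1(tr, ref)
  expect_equal(maxgal1_reference(norm, 210), 1)
  expect_equal(normalize_to_maxgal1(0, 5), 0)
  expect_equal(normalize_to_maxgal1(norm, 1), norm)  # idempotent at ref 1
  expect_error(normalize_to_maxgal1(tr, 0), "positive")
})

test_that("cross-batch calibration recovers gain ratios", {
  expect_equal(cross_calibrate(3.2, 3.2), 1)
  expect_equal(cross_calibrate(1, 2), 0.5)  # batch B at 2x gain
  set.seed(8)
  ref_true <- 50
  g <- 3.7
  a_ref <- mean(ref_true + rnorm(200, 0, 2))
  b_ref <- mean(g * ref_true + rnorm(200, 0, 2 * g))
  expect_equal(cross_calibrate(a_ref, b_ref), 1 / g, tolerance = 0.02)
  expect_error(cross_calibrate(-1, 2), "positive")
})

test_that("bootstrap lag intervals: determinism, ordering, degeneracy", {
  # identical zero-noise cells: every resample average is the same trace
  cfg <- population_config(n_cells = 12, cv_params = c(b = 0, i = 0, d = 0),
                           lag_sd = 0, noise_sd = 0, seed = 2)
  pop <- generate_population(cfg)
  ci <- bootstrap_lag_ci(pop, f = 0.035, chemically_induced = FALSE,
                         n_resamples = 50, sample_size = 12, seed = 4)
  expect_equal(diff(ci$t_on_ci), 0, tolerance = 1e-8)
  expect_equal(diff(ci$t_off_ci), 0, tolerance = 1e-8)

  noisy <- generate_population(population_config(n_cells = 30, seed = 9))
  c1 <- bootstrap_lag_ci(noisy, f = 0.035, chemically_induced = FALSE,
                         n_resamples = 60, sample_size = 30, seed = 7)
  c2 <- bootstrap_lag_ci(noisy, f = 0.035, chemically_induced = FALSE,
                         n_resamples = 60, sample_size = 30, seed = 7)
  expect_identical(c1, c2)
  expect_lte(c1$t_on_ci[1], c1$t_on_ci[2])
  expect_lte(c1$t_off_ci[1], c1$t_off_ci[2])
  expect_error(bootstrap_lag_ci(noisy, sample_size = 1000), "sample_size")
})

test_that("bootstrap intervals cover the procedure's estimand", {
  # noise-only world: the estimand is the staged fit of the noiseless
  # central trace (the procedure is biased for the generative lag; the
  # bootstrap can only promise coverage of its own estimand)
  est <- fit_induction(ref_trace(), f = 0.035,
                       chemically_induced = FALSE)$params$t_on
  hits <- 0L
  for (rep in 1:15) {
    pop <- generate_population(population_config(
      n_cells = 60, cv_params = c(b = 0, i = 0, d = 0), lag_sd = 0,
      seed = 300 + rep))
    ci <- bootstrap_lag_ci(pop, f = 0.035, chemically_induced = FALSE,
                           n_resamples = 200, sample_size = 60,
                           seed = rep, lags = "on")
    if (ci$t_on_ci[1] <= est && est <= ci$t_on_ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 12)
})

test_that("coefficient of variation", {
  expect_equal(compute_cv(rep(2, 10)), 0)
  expect_equal(compute_cv(c(1, 2, 3)), sd(c(1, 2, 3)) / 2)
  set.seed(10)
  x <- rlnorm(1e4, 0, 0.25)
  expect_equal(compute_cv(x), sqrt(exp(0.25^2) - 1), tolerance = 0.05)
  expect_error(compute_cv(c(-2, 1)), "positive")
})

test_that("noise scaling regression on constructed power laws", {
  m <- 10^seq(-2, 0, length.out = 8)
  pts <- data.frame(system = paste0("s", 1:8), mean = m,
                    cv = 0.3 * m^(-0.5))
  r <- noise_scaling_regression(pts)
  expect_equal(r$slope, -0.5, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  # exclusions are honored point by point
  r2 <- noise_scaling_regression(pts, exclude = c("s1", "s5"))
  expect_equal(r2$n_used, 6)
  expect_setequal(r2$excluded, c("s1", "s5"))
  expect_error(noise_scaling_regression(pts[1:2, ]), "3 points")
})

test_that("bimodality coefficient hits its reference values", {
  # normal: skewness 0, kurtosis 3 -> 1/3
  set.seed(3)
  expect_equal(bimodality_coefficient(rnorm(1e5)), 1 / 3,
               tolerance = 0.02)
  # affine invariance on random samples
  set.seed(4)
  for (k in 1:5) {
    x <- rgamma(200, shape = runif(1, 0.5, 5))
    expect_equal(bimodality_coefficient(3.7 * x - 11),
                 bimodality_coefficient(x), tolerance = 1e-12)
  }
})

test_that("violin summaries: outliers, bandwidth law, bimodal splitting", {
  set.seed(6)
  x <- rnorm(400)
  vs <- violin_summary(x)
  expect_false(vs$bimodal)
  expect_true(all(abs(vs$outliers - mean(x)) > 2 * sd(x)))
  expect_equal(vs$bandwidth,
               0.8 * sd(vs$kept) / length(vs$kept)^(1 / 5))
  # bandwidth homogeneity: scale equivariance and the n^(-1/5) law
  vs_scaled <- violin_summary(5 * x)
  expect_equal(vs_scaled$bandwidth, 5 * vs$bandwidth, tolerance = 1e-10)
  bw <- function(v) 0.8 * sd(v) / length(v)^(1 / 5)
  # (small slack: the n-1 sample SD differs slightly between n and 32n)
  expect_equal(bw(rep(x, 32)) / bw(x), 32^(-1 / 5), tolerance = 0.01)

  # symmetric well-separated mixture: classified bimodal, split between
  # the modes, bandwidth the smaller of the two sides
  y <- generate_bimodal_sample(5000, seed = 12)
  vb <- violin_summary(y)
  expect_true(vb$bimodal)
  expect_lt(abs(vb$split_threshold), 1.5)
  expect_equal(vb$bandwidth, min(vb$subpop_bandwidths))
  expect_error(violin_summary(1:3), "at least 5")
})

test_that("Otsu threshold equals the brute-force between-class scan", {
  expect_gt(otsu_threshold(c(0, 0, 0, 1, 1, 1)), 0)
  expect_lt(otsu_threshold(c(0, 0, 0, 1, 1, 1)), 1)
  brute <- function(x, nb = 256) {
    rng <- range(x)
    breaks <- seq(rng[1], rng[2], length.out = nb + 1)
    bin <- findInterval(x, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    best <- -Inf; thr <- NA
    for (k in 1:(nb - 1)) {
      lo <- bin <= k
      if (!any(lo) || all(lo)) next
      centers <- (breaks[-1] + breaks[-(nb + 1)]) / 2
      w0 <- mean(lo)
      sb <- w0 * (1 - w0) * (mean(centers[bin[lo]]) -
                               mean(centers[bin[!lo]]))^2
      if (sb > best + 1e-15) { best <- sb; thr <- breaks[k + 1] }
    }
    thr
  }
  set.seed(13)
  for (n in c(6, 20, 77, 200)) {
    x <- c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 4))
    expect_equal(otsu_threshold(x), brute(x), tolerance = 1e-12)
  }
  # affine equivariance: the histogram maps affinely with the data
  set.seed(14)
  z <- rnorm(100)
  expect_equal(otsu_threshold(2 * z + 3), 2 * otsu_threshold(z) + 3,
               tolerance = 1e-9)
  expect_error(otsu_threshold(rep(1, 10)), "constant")
})

test_that("event alignment overlays trajectories", {
  tt <- seq(0, 100, 10)
  tr <- data.frame(cell_id = rep(c("a", "b"), each = length(tt)),
                   time_min = c(tt, tt + 20),
                   fluorescence = rep(sin(tt / 15), 2))
  # identical traces offset by 20 min with matching events overlay exactly
  al <- align_by_event(tr, c(a = 0, b = 20))
  wide <- split(al$traces, al$traces$cell_id)
  expect_equal(wide$a$time_aligned, wide$b$time_aligned)
  expect_equal(al$summary$sd, rep(0, nrow(al$summary)))
  # all-zero events are the identity
  al0 <- align_by_event(tr, c(a = 0, b = 0))
  expect_equal(al0$traces$time_aligned, tr$time_min)
  expect_error(align_by_event(tr, c(a = 0)), "missing event")

  # periodic traces with phase jitter: aligning restores the oscillation
  set.seed(15)
  period <- 90
  cells <- lapply(1:15, function(k) {
    shift <- runif(1, 0, period)
    data.frame(cell_id = paste0("c", k), time_min = tt <- seq(0, 360, 10),
               fluorescence = sin(2 * pi * (tt - shift) / period))
  })
  trj <- do.call(rbind, cells)
  shifts <- sapply(cells, function(d)
    d$time_min[which.max(d$fluorescence)])
  names(shifts) <- paste0("c", 1:15)
  alj <- align_by_event(trj, shifts)
  unaligned_amp <- diff(range(tapply(trj$fluorescence, trj$time_min,
                                     mean)))
  aligned_amp <- diff(range(alj$summary$mean))
  expect_gt(aligned_amp, unaligned_amp)
})

test_that("one-tailed z test matches its definition and a permutation
           oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(one_tailed_z_test(x, x), 0.5)
  set.seed(16)
  a <- rnorm(50, 10, 0.1)
  b <- rnorm(50, 0, 0.1)
  expect_lt(one_tailed_z_test(a, b), 1e-10)
  expect_gt(one_tailed_z_test(b, a), 1 - 1e-10)

  set.seed(5)
  a2 <- rnorm(100, 0.3); b2 <- rnorm(100, 0)
  pz <- one_tailed_z_test(a2, b2)
  comb <- c(a2, b2); obs <- mean(a2) - mean(b2)
  perm <- replicate(5000, {
    i <- sample(200, 100)
    mean(comb[i]) - mean(comb[-i])
  })
  expect_lt(abs(pz - mean(perm >= obs)), 0.02)
})
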