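# Staged estimation: stage-by-stage self-consistency on traces built
# from the fitting forms themselves, quantified truncation bias on full
# model traces, exclusion rules, population averaging.

test_that("basal plateau estimation", {
  tt <- seq(-60, 390, 10)
  expect_equal(estimate_basal(tt, rep(0.05, length(tt))), 0.05)
  # noiseless synthetic trace: plateau equals f b / (d (d + f))
  tr <- ref_trace()
  p <- ref_params()
  expect_equal(estimate_basal(tr$time_min, tr$fluorescence),
               p$f * p$b / (p$d * (p$d + p$f)), tolerance = 1e-6)
  # single-timepoint window (optogenetic convention)
  expect_equal(estimate_basal(tt, tt * 0 + 2, window = c(0, 0)), 2)
  expect_error(estimate_basal(tt, tt, window = c(1000, 1001)), "window")
})

test_that("rise fit recovers its own generating quadratic exactly", {
  p <- kinetic_params(b = 1e-4, i = 0.002, f = 0.035, d = 0.017,
                      t_on = 15, t_off = 5)
  tr <- taylor_trace(p)
  basal <- steady_state(p, FALSE)
  r <- fit_rise(tr$time_min, tr$fluorescence, f_fixed = 0.035,
                basal_plateau = basal)
  expect_equal(r$i, 0.002, tolerance = 1e-5)
  expect_equal(r$t_on, 15, tolerance = 1e-4)
  expect_true(r$converged)
  # a flat trace yields i ~ 0 with the lag flagged undefined
  flat <- rep(basal, length(tr$time_min))
  rf <- fit_rise(tr$time_min, flat, f_fixed = 0.035,
                 basal_plateau = basal)
  expect_lt(rf$i, 1e-8)
  expect_false(rf$t_on_defined)
})

test_that("rise fit on a full model trace finds the global least-squares
           optimum (which is strongly truncation-biased)", {
  tr <- ref_trace()
  p <- ref_params()
  basal <- steady_state(p, FALSE)
  r <- fit_rise(tr$time_min, tr$fluorescence, f_fixed = p$f,
                basal_plateau = basal)
  # independent oracle: exhaustive profile scan over the lag
  sel <- tr$time_min >= -50 & tr$time_min <= 50
  tt <- tr$time_min[sel]; dy <- tr$fluorescence[sel] - basal
  scan <- sapply(seq(0, 30, 0.05), function(ton) {
    z <- (p$f / 2) * pmax(tt - ton, 0)^2
    i <- max(0, sum(z * dy) / sum(z * z))
    c(ton, i, sum((dy - i * z)^2))
  })
  best <- scan[, which.min(scan[3, ])]
  expect_lte(r$residual_ss, best[3] * (1 + 1e-6))
  expect_equal(r$t_on, best[1], tolerance = 0.05)
  expect_equal(r$i, best[2], tolerance = 0.01)
  # the bias itself: the quadratic's validity (~1/(f+2d) = 14 min) is much
  # shorter than the 40 min of post-onset window, so i comes out ~3x low
  # and the lag ~8 min early
  expect_lt(r$i / p$i, 0.5)
  expect_lt(r$t_on, p$t_on - 5)
})

test_that("fall fit recovers the deactivation lag from its own form", {
  p <- ref_params()
  tr <- taylor_trace(p)
  induced <- steady_state(p, TRUE)
  fl <- fit_fall(tr$time_min, tr$fluorescence, f_fixed = p$f,
                 induced_plateau = induced)
  expect_equal(fl$t_off, 5, tolerance = 1e-3)
  expect_true(fl$t_off_defined)
  expect_false(fl$at_window_edge)
  # trace flat through the fall window: lag pinned at the edge, flagged
  flat <- ifelse(tr$time_min >= 200, induced, tr$fluorescence)
  ff <- fit_fall(tr$time_min, flat, f_fixed = p$f,
                 induced_plateau = induced)
  expect_true(ff$at_window_edge)
  expect_false(ff$t_off_defined)
})

test_that("decay fit extracts the turnover rate and signs rising traces", {
  tt <- seq(270, 390, 10)
  y <- 0.5 * exp(-0.02 * (tt - 270))
  dc <- fit_decay(tt, y, floor = 0)
  expect_equal(dc$d, 0.02, tolerance = 1e-6)
  expect_equal(dc$F0, 0.5, tolerance = 1e-6)
  # rising trace: negative rate (the exclusion signal)
  up <- fit_decay(tt, 0.1 * exp(0.01 * (tt - 270)), floor = 0)
  expect_lt(up$d, 0)
  # full model trace: small residual bias from the maturation transient
  tr <- ref_trace()
  p <- ref_params()
  dm <- fit_decay(tr$time_min, tr$fluorescence,
                  floor = steady_state(p, FALSE))
  expect_lt(abs(dm$d - p$d) / p$d, 0.04)
  expect_error(fit_decay(tt[1:2], y[1:2]), "3 points")
})

test_that("basal rate back-computation inverts the plateau", {
  expect_equal(recover_b(0, 0.02, 0.035), 0)
  b <- 3e-4; d <- 0.02; f <- 0.035
  plateau <- f * b / (d * (d + f))
  expect_equal(recover_b(plateau, d, f), b)
  expect_warning(bb <- recover_b(0.1, -0.01, 0.035), "undefined")
  expect_true(is.na(bb))
})

test_that("end-to-end staged fit: faithful form carries the documented
           bias, exact form recovers the generative truth", {
  tr <- ref_trace()
  p <- ref_params()
  ft <- fit_induction(tr, f = p$f, chemically_induced = FALSE)
  expect_s3_class(ft, "induction_fit")
  expect_true(ft$converged)
  # d and b are nearly unbiased; i and the lags are truncation-biased
  expect_equal(ft$params$d, p$d, tolerance = 0.04)
  expect_equal(ft$params$b, p$b, tolerance = 0.06)
  fe <- fit_induction(tr, f = p$f, chemically_induced = FALSE,
                      form = "exact")
  expect_equal(fe$params$i, p$i, tolerance = 0.02)
  expect_equal(fe$params$t_on, p$t_on, tolerance = 0.02)
  expect_equal(fe$params$t_off, p$t_off, tolerance = 0.1)
  expect_equal(fe$params$d, p$d, tolerance = 0.02)
  expect_equal(fe$params$b, p$b, tolerance = 0.02)
})

test_that("media-delay correction only applies to chemical induction", {
  p <- kinetic_params(b = 1e-4, i = 0.002, f = 0.035, d = 0.017,
                      t_on = 15, t_off = 10)
  tr <- taylor_trace(p)
  chem <- fit_induction(tr, f = p$f, chemically_induced = TRUE)
  opto <- fit_induction(tr, f = p$f, chemically_induced = FALSE)
  expect_equal(opto$params$t_on - chem$params$t_on, 170 / 60,
               tolerance = 1e-3)
  expect_equal(opto$params$t_off - chem$params$t_off, 170 / 60,
               tolerance = 1e-3)
  expect_equal(chem$media_delay_applied_min, 170 / 60)
  expect_equal(opto$media_delay_applied_min, 0)
})

test_that("fitted lags and induction speed respect their zero bounds", {
  set.seed(7)
  tt <- seq(-60, 390, 10)
  for (k in 1:10) {
    y <- 0.01 + stats::rnorm(length(tt), 0, 0.005)  # pure noise
    ft <- fit_induction(data.frame(time_min = tt, fluorescence = y),
                        f = 0.035)
    expect_gte(ft$params$i, 0)
    expect_gte(ft$params$t_on, 0)
    expect_gte(ft$params$t_off, 0)
  }
})

test_that("rise window shifts barely move the lag on self-consistent data", {
  p <- kinetic_params(b = 1e-4, i = 0.002, f = 0.035, d = 0.017,
                      t_on = 15, t_off = 5)
  tr <- taylor_trace(p)
  basal <- steady_state(p, FALSE)
  t_ons <- sapply(list(c(-60, 40), c(-50, 50), c(-40, 60)), function(w)
    fit_rise(tr$time_min, tr$fluorescence, 0.035, w, basal)$t_on)
  expect_lt(max(t_ons) - min(t_ons), 1)
})

test_that("exclusion rules catch pathological cells and only those", {
  cfg <- population_config(n_cells = 40, noise_sd = 0, seed = 21)
  pop <- generate_population(cfg)
  pop <- inject_outlier_cells(pop, 0.2, seed = 22)  # 8 tagged cells
  set <- fit_induction(pop, f = 0.035, chemically_induced = FALSE,
                       average = FALSE)
  ex <- exclude_cells(set)
  tagged <- pop$truth$cell_id[pop$truth$outlier]
  flagged <- ex$reasons$cell_id[ex$reasons$excluded]
  expect_gte(length(intersect(flagged, tagged)), 8 * 0.95)
  expect_equal(setdiff(flagged, tagged), character(0))
  # both rules fire on their respective pathology
  rising <- pop$truth$cell_id[pop$truth$outlier_type %in%
                                "rising_after_shutoff"]
  expect_true(all(grepl("negative_d",
                        ex$reasons$reason[ex$reasons$cell_id %in% rising])))
  pre <- pop$truth$cell_id[pop$truth$outlier_type %in% "pre_induced"]
  expect_true(all(grepl("start_above_4.5h",
                        ex$reasons$reason[ex$reasons$cell_id %in% pre])))
})

test_that("a constant trace sits on the exclusion boundary and is kept", {
  tt <- seq(-60, 390, 10)
  tr <- data.frame(cell_id = "c1", time_min = tt, fluorescence = 0.02)
  set <- fit_induction(tr, f = 0.035, average = FALSE)
  ex <- exclude_cells(set)
  expect_false(ex$reasons$excluded[1])
})

test_that("population averaging equals the single-cell fit for clones and
           shrinks the rise residual for heterogeneous cells", {
  cfg <- population_config(n_cells = 4, cv_params = c(b = 0, i = 0, d = 0),
                           lag_sd = 0, noise_sd = 0, seed = 1)
  pop <- generate_population(cfg)
  one <- pop$traces[pop$traces$cell_id == "cell_001",
                    c("time_min", "fluorescence")]
  f_one <- fit_induction(one, f = 0.035, chemically_induced = FALSE)
  f_avg <- fit_population_average(pop, f = 0.035,
                                  chemically_induced = FALSE)
  expect_equal(coef(f_avg), coef(f_one), tolerance = 1e-8)

  noisy <- generate_population(population_config(n_cells = 60, seed = 14))
  f_pop <- fit_population_average(noisy, f = 0.035,
                                  chemically_induced = FALSE)
  # the estimand of the procedure: its value on the noiseless central trace
  est <- fit_induction(ref_trace(), f = 0.035, chemically_induced = FALSE)
  expect_equal(f_pop$params$t_on, est$params$t_on, tolerance = 2)
  set <- fit_induction(noisy, f = 0.035, chemically_induced = FALSE,
                       average = FALSE)
  med_cell_rss <- stats::median(vapply(set$fits, function(f)
    f$stages$rise$residual_ss, numeric(1)))
  expect_lt(f_pop$stages$rise$residual_ss, med_cell_rss)
})

test_that("induction_fit methods behave", {
  tr <- ref_trace()
  ft <- fit_induction(tr, f = 0.035, chemically_induced = FALSE)
  expect_named(coef(ft), c("b", "i", "f", "d", "t_on", "t_off"))
  expect_output(print(ft), "Staged kinetic fit")
  sm <- summary(ft)
  expect_s3_class(sm, "summary.induction_fit")
  expect_named(sm$residual_ss, c("rise", "fall", "decay"))
  pr_curve <- predict(ft)
  expect_equal(length(pr_curve), nrow(tr))
  st <- predict(ft, type = "stages")
  expect_true(all(c("basal", "rise", "fall", "decay") %in% st$stage))
  rs <- residuals(ft)
  expect_true(all(abs(rs$residual[rs$stage == "basal"]) < 1e-6))
  sim <- simulate(ft, nsim = 2, seed = 3)
  expect_s3_class(sim, "synthetic_population")
  expect_equal(nrow(sim$truth), 2)
})
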