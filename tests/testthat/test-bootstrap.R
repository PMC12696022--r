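test_that("parametric resampling preserves the skeleton and injects pooled noise", {
  obs <- simulate_study(seed = 4)
  tr <- best_treatment()
  r1 <- parametric_resample(obs, tr, seed = 11)
  r2 <- parametric_resample(obs, tr, seed = 11)
  expect_identical(r1$vfa, r2$vfa)  # seeded determinism
  skel <- c("temperature", "day", "replicate")
  expect_equal(as.data.frame(r1[skel]),
               as.data.frame(obs_for_study_treatment(obs)[skel]),
               ignore_attr = TRUE)
  # zero within-cell scatter: resample returns the cell means exactly
  o0 <- obs_for_study_treatment(simulate_study(seed = 4, noise_sd = 0))
  r0 <- parametric_resample(o0, tr, seed = 1)
  expect_equal(r0$vfa, o0$vfa)
  # single replicate everywhere: pooled SD undefined
  o1rep <- o0[o0$replicate == 1, ]
  expect_error(parametric_resample(o1rep, tr, seed = 1),
               class = "vfa_error_domain")
})

test_that("resampled within-cell SD is consistent with the pooled SD", {
  obs <- obs_for_study_treatment(simulate_study(seed = 5))
  sk <- vfasurf:::.resample_skeleton(obs)
  draws <- vapply(1:1000, function(s) {
    parametric_resample(obs, seed = 20000 + s)$vfa
  }, numeric(nrow(obs)))
  # SD across resamples at each row estimates the pooled SD
  sds <- apply(draws, 1, sd)
  expect_lt(abs(mean(sds) - sk$pooled_sd) / sk$pooled_sd, 0.05)
})

test_that("bootstrap optima are seeded, sized B, and degenerate under zero noise", {
  obs <- simulate_study(seed = 6)
  tr <- best_treatment()
  dom <- coarse_domain()
  b1 <- bootstrap_optima(obs, tr, B = 25, seed = 9, domain = dom)
  b2 <- bootstrap_optima(obs, tr, B = 25, seed = 9, domain = dom)
  expect_equal(nrow(b1$optima), 25)
  expect_identical(b1$optima, b2$optima)
  expect_equal(b1$mean_opt_vfa, mean(b1$optima$predicted_vfa))
  expect_equal(b1$sd_opt_vfa, sd(b1$optima$predicted_vfa))
  expect_error(bootstrap_optima(obs, tr, B = 1, seed = 1, domain = dom),
               class = "vfa_error_domain")
  # study-scale replicate count: exactly B = 300 optima stored
  b300 <- bootstrap_optima(obs, tr, B = 300, seed = 9,
                           domain = study_domain(resolution = 1))
  expect_equal(nrow(b300$optima), 300)
  expect_equal(b300$B, 300L)
  # zero-noise data: every bootstrap optimum equals the point estimate
  obs0 <- simulate_study(seed = 6, noise_sd = 0)
  b0 <- bootstrap_optima(obs0, tr, B = 5, seed = 1, domain = dom)
  pt <- b0$point_estimate
  expect_true(all(b0$optima$temperature == pt$temperature))
  expect_true(all(b0$optima$day == pt$day))
  expect_equal(b0$optima$predicted_vfa, rep(pt$predicted_vfa, 5),
               tolerance = 1e-9)
})

test_that("bootstrap SD of the optimum tracks the true sampling SD", {
  # nested Monte-Carlo calibration: one observed dataset bootstrapped at
  # B = 100 versus the spread of optima across 200 fresh datasets from the
  # same truth; also checks the winner's-curse upward bias of a maximum
  tr <- best_treatment()
  tru <- default_truth_surface(tr, seed = 2, noise_sd = 516)
  keys <- data.frame(sludge_type = "PS", organic_load = 14, initial_ph = 10.5)
  # calibrate on the sampled horizon (days 3-12): below day 3 the cubic
  # extrapolates outside the design and the argmax functional is unstable
  dom <- study_domain(resolution = 0.25, day_range = c(3, 12))
  lat <- domain_lattice(dom)
  X <- poly_design_matrix(lat$temperature, lat$day)
  fresh <- vapply(1:200, function(s) {
    cfg <- simulation_config(list(tru), keys, seed = 30000 + s)
    f <- vfa_surface(simulate_observations(cfg))
    max(drop(X %*% coef(f)))
  }, 0)
  true_sd <- sd(fresh)
  cfg0 <- simulation_config(list(tru), keys, seed = 777)
  obs0 <- simulate_observations(cfg0)
  bt <- bootstrap_optima(obs0, tr, B = 100, seed = 888, domain = dom)
  expect_lt(abs(bt$sd_opt_vfa - true_sd) / true_sd, 0.25)
  # selection bias: the mean fitted optimum exceeds the truth's feasible max
  truth_max <- max(drop(X %*% coef(tru)))
  expect_gte(mean(fresh) - truth_max, 0)
})

test_that("the adjusted-df ANOVA reproduces the study's table arithmetic", {
  withr::with_seed(12, {
    groups <- lapply(1:12, function(i) rnorm(40, 5000 + 100 * i, 200))
  })
  res <- anova_optima(groups, df_per_treatment = 28, alpha = 0.05)
  expect_equal(res$df_between, 11)
  expect_equal(res$df_within, 336)   # 12 treatments x 28 df
  expect_equal(res$df_total, 347)
  expect_equal(round(res$f_critical, 3), 1.817)
  expect_equal(res$ss_total, res$ss_between + res$ss_within,
               tolerance = 1e-6)
  expect_equal(res$f_stat, res$ms_between / res$ms_within)
  expect_equal(res$ms_within, mean(vapply(groups, var, 0)))
  expect_error(anova_optima(list(rnorm(10), rnorm(12)), 28),
               class = "vfa_error_domain")  # mismatched B
  expect_error(anova_optima(list(rnorm(10)), 28), class = "vfa_error_domain")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(13, {
    g <- list(a = rnorm(30, 100, 10), b = rnorm(30, 110, 12))
  })
  a <- anova_optima(g, df_per_treatment = 29)
  t <- t_test_top_two(g, df_per_treatment = 29)
  expect_lt(abs(a$f_stat - t$t_stat^2) / a$f_stat, 1e-8)
})

test_that("ANOVA type-I error is calibrated under a common null", {
  rej <- withr::with_seed(14, {
    vapply(1:500, function(i) {
      g <- lapply(1:4, function(j) rnorm(10))
      a <- anova_optima(g, df_per_treatment = 9, alpha = 0.05)
      a$f_stat > a$f_critical
    }, TRUE)
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("the top-two t-test reproduces the printed best-treatment comparison", {
  # frozen oracle: pooled two-sample t on summary stats
  # (7021.46, 181.55) vs (6855.04, 215.38) with 28 df per group -> t = 3.18
  make <- function(n, m, s) m + s * scale(seq_len(n))[, 1] /
    sd(scale(seq_len(n))[, 1])
  g <- list(best = make(29, 7021.46, 181.55),
            second = make(29, 6855.04, 215.38),
            low = make(29, 4000, 200))
  tt <- t_test_top_two(g, df_per_treatment = 28)
  expect_equal(tt$best, "best")
  expect_equal(tt$second, "second")
  expect_equal(tt$t_stat, 3.1815, tolerance = 1e-3)
  expect_true(tt$reject_null)
  expect_equal(tt$df1, 28)
  # identical groups: t = 0, no rejection
  t0 <- t_test_top_two(list(a = make(29, 5000, 100), b = make(29, 5000, 100)),
                       df_per_treatment = 28)
  expect_equal(t0$t_stat, 0, tolerance = 1e-10)
  expect_false(t0$reject_null)
})

test_that("critical values match the study's printed thresholds", {
  expect_equal(round(critical_t(0.05, 27), 3), 2.052)
  expect_equal(round(critical_f(0.05, 11, 336), 3), 1.817)
  expect_lt(critical_t(0.999, 50), 0.002)  # quantile limit as alpha -> 1
  expect_error(critical_t(0, 10), class = "vfa_error_domain")
  expect_error(critical_t(0.05, 0), class = "vfa_error_domain")
  expect_error(critical_f(1.2, 2, 3), class = "vfa_error_domain")
})
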