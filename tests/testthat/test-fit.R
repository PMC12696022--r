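test_that("the monomial design matrix follows the fixed cubic term order", {
  expect_equal(drop(poly_design_matrix(1, 1)), rep(1, 10), ignore_attr = TRUE)
  expect_equal(drop(poly_design_matrix(0, 2)),
               c(1, 0, 2, 0, 0, 4, 0, 0, 0, 8), ignore_attr = TRUE)
  expect_equal(poly_design_matrix(25, 9)[1, 7], c(`t^3` = 25^3))
  expect_equal(colnames(poly_design_matrix(1, 1)),
               c("(Intercept)", "t", "d", "t^2", "t:d", "d^2",
                 "t^3", "t^2:d", "t:d^2", "d^3"))
  expect_equal(ncol(poly_design_matrix(1, 1, degree = 4)), 15)
  expect_equal(ncol(poly_design_matrix(1, 1, degree = 2)), 6)
})

test_that("OLS agrees with a hand-rolled normal-equations oracle", {
  beta_true <- c(500, 30, -20, 4, 2, -6, 0.5, -0.2, 0.3, -0.4)
  withr::with_seed(10, {
    obs <- small_grid_obs(beta_true, noise = 50)
  })
  fit <- vfa_surface(obs)
  orc <- ols_oracle(obs)
  expect_lt(max(abs(coef(fit) - orc$beta)) / max(abs(orc$beta)), 1e-8)
  expect_lt(max(abs(fit$t_values - orc$t)) / max(abs(orc$t)), 1e-8)
  expect_equal(fit$sigma, orc$sigma, tolerance = 1e-8)
  # study-scale coordinates: same comparison, looser (raw normal equations
  # are badly conditioned there; the fit's internal scaling is not)
  obs2 <- simulate_study(seed = 3)
  f2 <- vfa_surface(obs2, best_treatment())
  o2 <- ols_oracle(obs_for_study_treatment(obs2))
  expect_lt(max(abs(coef(f2) - o2$beta)) / max(abs(o2$beta)), 1e-5)
})

test_that("a noiseless cubic is recovered exactly with r^2 = 1", {
  beta_true <- coef(quad_peak_truth())
  obs <- small_grid_obs(beta_true, noise = 0)
  fit <- vfa_surface(obs)
  expect_lt(max(abs(coef(fit) - beta_true)) / max(abs(beta_true)), 1e-10)
  expect_equal(fit$r.squared, 1, tolerance = 1e-9)
})

test_that("the fit has exactly 10 coefficients and prediction is monomial evaluation", {
  obs <- simulate_study(seed = 2)
  fit <- vfa_surface(obs, best_treatment())
  expect_length(coef(fit), 10)
  expect_length(fit$t_values, 10)
  expect_equal(fit$df.residual, fit$n - 10)
  tt <- seq(25, 55, 5); dd <- seq(0, 12, 2)[1:7]
  expect_equal(predict(fit, tt, dd),
               drop(poly_design_matrix(tt, dd) %*% coef(fit)),
               tolerance = 1e-10)
  # degenerate coefficient vectors predict trivially
  z <- truth_surface(rep(0, 10)); expect_equal(predict(z, 40, 6), 0)
  k <- truth_surface(c(5, rep(0, 9))); expect_equal(predict(k, 12, 3), 5)
})

test_that("fits refuse under-determined and rank-deficient data", {
  few <- tiny_obs()
  expect_error(vfa_surface(few), class = "vfa_error_underdetermined")
  # 12 rows but only one temperature level: t^2, t^3 columns collinear
  obs <- data.frame(sludge_type = "PS", organic_load = 14, initial_ph = 10.5,
                    temperature = 35, day = rep(1:6, 2),
                    replicate = rep(1:2, each = 6),
                    vfa = 100 + rep(1:6, 2))
  expect_error(vfa_surface(obs), class = "vfa_error_singular")
})

test_that("residuals are orthogonal to the design and OLS equivariance holds", {
  withr::with_seed(4, {
    obs <- small_grid_obs(coef(quad_peak_truth()), noise = 100)
  })
  fit <- vfa_surface(obs)
  X <- poly_design_matrix(obs$temperature, obs$day)
  scale_ <- max(abs(crossprod(X, obs$vfa)))
  expect_lt(max(abs(crossprod(X, residuals(fit)))), 1e-6 * scale_)
  # shift: only the intercept moves
  obs_s <- transform(obs, vfa = vfa + 250)
  fit_s <- vfa_surface(obs_s)
  d <- coef(fit_s) - coef(fit)
  expect_equal(unname(d[1]), 250, tolerance = 1e-6)
  expect_lt(max(abs(d[-1])), 1e-6 * max(abs(coef(fit))))
  # scale: coefficients and residual SD scale, r^2 and t-values unchanged
  obs_k <- transform(obs, vfa = vfa * 3)
  fit_k <- vfa_surface(obs_k)
  expect_equal(coef(fit_k), 3 * coef(fit), tolerance = 1e-8)
  expect_equal(fit_k$sigma, 3 * fit$sigma, tolerance = 1e-8)
  expect_equal(fit_k$r.squared, fit$r.squared, tolerance = 1e-10)
  expect_equal(fit_k$t_values, fit$t_values, tolerance = 1e-8)
})

test_that("true coefficients fall in their 95% confidence intervals at nominal rate", {
  tr <- best_treatment()
  tru <- default_truth_surface(tr, seed = 2, noise_sd = 516)
  keys <- data.frame(sludge_type = "PS", organic_load = 14, initial_ph = 10.5)
  hits <- 0L; total <- 0L
  for (s in 1:200) {
    cfg <- simulation_config(list(tru), keys, seed = 7000 + s)
    obs <- simulate_observations(cfg)
    ci <- confint(vfa_surface(obs))
    hits <- hits + sum(coef(tru) >= ci[, 1] & coef(tru) <= ci[, 2])
    total <- total + 10L
  }
  expect_lt(abs(hits / total - 0.95), 0.04)
})

test_that("Pareto ranking uses the right threshold and orders by |t|", {
  # n = 37 rows gives residual df 27, the printed 2.052 threshold
  withr::with_seed(5, {
    g <- expand.grid(temperature = c(25, 35, 45, 55), day = c(3, 6, 9, 12))
    g <- g[rep(1:16, length.out = 37), ]
    obs <- data.frame(sludge_type = "PS", organic_load = 14, initial_ph = 10.5,
                      temperature = g$temperature, day = g$day,
                      replicate = ave(g$temperature,
                                      interaction(g$temperature, g$day),
                                      FUN = seq_along),
                      vfa = 4000 + 10 * g$day + rnorm(37, 0, 100))
  })
  fit <- vfa_surface(obs)
  pr <- pareto_tvalues(fit, alpha = 0.05)
  expect_equal(fit$df.residual, 27)
  expect_equal(round(attr(pr, "threshold"), 3), 2.052)
  expect_equal(nrow(pr), 10)
  expect_true(!is.unsorted(rev(pr$abs_t)))
  expect_equal(pr$significant, pr$abs_t > attr(pr, "threshold"))
})

test_that("a dominant generated effect ranks first in the Pareto chart", {
  # strong pure-cubic day effect, large n, small noise
  beta <- c(3000, 0, 0, 0, 0, 0, 0, 0, 0, 40)
  withr::with_seed(6, {
    obs <- small_grid_obs(beta, noise = 20, reps = 6)
  })
  pr <- pareto_tvalues(vfa_surface(obs))
  expect_equal(pr$term[pr$term != "(Intercept)"][1], "d^3")
  expect_true(pr$significant[pr$term == "d^3"])
})

test_that("under a constant truth the significant-term rate matches alpha", {
  keys <- data.frame(sludge_type = "PS", organic_load = 14, initial_ph = 10.5)
  tru <- truth_surface(c(4000, rep(0, 9)), noise_sd = 516)
  counts <- withr::with_seed(99, {
    vapply(1:500, function(s) {
      cfg <- simulation_config(list(tru), keys, seed = s)
      pr <- pareto_tvalues(vfa_surface(simulate_observations(cfg)))
      sum(pr$significant[pr$term != "(Intercept)"])
    }, 0)
  })
  expect_lt(abs(mean(counts) - 9 * 0.05), 3 * sd(counts) / sqrt(500))
})

test_that("degree comparison is monotone and detects genuine cubic structure", {
  # exact quadratic truth, zero noise: all three degrees fit perfectly
  lv5 <- c(0, 1.5, 3, 4.5, 6)  # five levels per axis so a quartic is estimable
  obs <- small_grid_obs(coef(quad_peak_truth()), noise = 0, reps = 2,
                        ts = lv5, ds = lv5)
  cmp0 <- compare_degrees(obs)
  expect_equal(cmp0$r_squared, rep(1, 3), tolerance = 1e-9)
  expect_equal(cmp0$n_terms, c(6, 10, 15))
  # strong cubic truth: the cubic beats the quadratic even after adjustment
  beta3 <- c(3000, 0, 0, 0, 0, 0, 6, -3, 3, -45)
  withr::with_seed(8, {
    obs3 <- small_grid_obs(beta3, noise = 100, reps = 3, ts = lv5, ds = lv5)
  })
  cmp3 <- compare_degrees(obs3)
  expect_gt(cmp3$adj_r_squared[cmp3$degree == 3],
            cmp3$adj_r_squared[cmp3$degree == 2] + 0.05)
  # r^2 never decreases with degree on noisy data (nested least squares)
  withr::with_seed(9, {
    obsn <- small_grid_obs(coef(quad_peak_truth()), noise = 400, reps = 2,
                           ts = lv5, ds = lv5)
  })
  cmpn <- compare_degrees(obsn)
  expect_true(all(diff(cmpn$r_squared) >= -1e-12))
})
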