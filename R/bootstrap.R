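# Parametric bootstrap of the production optimum and between-treatment
# inference: ANOVA with regression-adjusted df, t-test of the two best
# treatments, critical values.

# Per-cell summary of one treatment's observations: cell means, fitted
# values and the pooled within-cell SD ("equal and normal variability in
# each experimental end").
.resample_skeleton <- function(obs, model = NULL) {
  cell <- interaction(obs$temperature, obs$day, drop = TRUE)
  means <- tapply(obs$vfa, cell, mean)
  ns <- tapply(obs$vfa, cell, length)
  vars <- tapply(obs$vfa, cell, stats::var)
  use <- ns >= 2
  if (!any(use))
    stop_vfa("vfa_error_domain",
             "pooled within-cell SD undefined: every cell has < 2 replicates")
  pooled_sd <- sqrt(sum((ns[use] - 1) * vars[use]) / sum(ns[use] - 1))
  centers_cell <- means[as.character(cell)]
  fitted_ctr <- if (!is.null(model)) predict(model, obs$temperature, obs$day)
  list(obs = obs, cell = cell, centers = as.numeric(centers_cell),
       fitted = fitted_ctr, pooled_sd = pooled_sd)
}

#' Parametric resample of one treatment's observations
#'
#' Draws a pseudo-dataset on the same design skeleton as the original
#' observations: each replicate value is replaced by its cell's observed
#' mean (default) or the fitted surface value (`center = "fitted"`) plus
#' Gaussian noise with the treatment's pooled within-cell SD, truncated at
#' zero.  This is the parametric bootstrap of the assumed data-generating
#' process — equal, normal replicate variability around every experimental
#' end point.
#'
#' @param observations An observation table.
#' @param treatment The treatment (optional for single-treatment tables).
#' @param seed Integer seed (the caller's RNG stream is restored).
#' @param center `"cell_means"` (default) or `"fitted"`.
#' @param model A `"vfa_surface"` fit, required when `center = "fitted"`
#'   (fitted internally when omitted).
#' @return A `"vfa_obs"` table with the same rows and new `vfa` values.
#' @export
parametric_resample <- function(observations, treatment = NULL, seed = 1L,
                                center = c("cell_means", "fitted"),
                                model = NULL) {
  center <- match.arg(center)
  obs <- obs_for_treatment(observations, treatment)
  if (center == "fitted" && is.null(model))
    model <- vfa_surface(obs)
  sk <- .resample_skeleton(obs, model)
  ctr <- if (center == "fitted") sk$fitted else sk$centers
  new_vfa <- with_seed(seed, function()
    pmax(0, ctr + stats::rnorm(nrow(obs), 0, sk$pooled_sd)))
  obs$vfa <- new_vfa
  attr(obs, "provenance") <- sprintf("parametric_resample(seed = %d, center = %s)",
                                     seed, center)
  obs
}

#' Parametric resamples from a fitted surface
#'
#' `simulate()` method: returns `nsim` parametric resamples of the fit's
#' own observations, centred on the fitted surface.
#'
#' @param object A `"vfa_surface"` fit.
#' @param nsim Number of pseudo-datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `"vfa_obs"` tables.
#' @export
simulate.vfa_surface <- function(object, nsim = 1, seed = 1L, ...) {
  obs <- object$data
  obs <- data.frame(sludge_type = object$treatment$sludge_type,
                    organic_load = object$treatment$organic_load,
                    initial_ph = object$treatment$initial_ph,
                    temperature = obs$temperature, day = obs$day,
                    replicate = stats::ave(obs$vfa, interaction(obs$temperature, obs$day),
                                           FUN = seq_along),
                    vfa = obs$vfa)
  lapply(seq_len(nsim), function(b)
    parametric_resample(obs, seed = seed + b - 1L, center = "fitted",
                        model = object))
}

#' Bootstrap distribution of the production optimum
#'
#' Runs B independent resample-fit-sweep cycles for one treatment: each
#' cycle draws a parametric resample ([parametric_resample()]), refits the
#' polynomial surface and locates its optimum on the sweep lattice.  The
#' B optima quantify the uncertainty of the optimal point; their mean and SD
#' feed the between-treatment ANOVA and t-test.  A singular refit is retried
#' with fresh noise up to `max_retries` times, then errors.
#'
#' @param observations An observation table.
#' @param treatment The treatment (optional for single-treatment tables).
#' @param B Number of bootstrap replicates (study default 300).
#' @param seed Integer seed; the whole chain is reproducible.
#' @param domain A `"vfa_domain"` for the sweep.
#' @param center Resampling centre, see [parametric_resample()].
#' @param degree Polynomial degree of the refits.
#' @param max_retries Retry budget per replicate for singular refits.
#' @return An object of class `"vfa_boot"`: list with `optima` (B-row
#'   data.frame of `temperature`, `day`, `predicted_vfa`), `B`, `seed`,
#'   `treatment`, `mean_opt_vfa`, `sd_opt_vfa`, `retries`.
#' @examples
#' obs <- simulate_study(seed = 1)
#' bt <- bootstrap_optima(obs, treatment_key("PS", 14, 10.5), B = 20,
#'                        seed = 1, domain = study_domain(resolution = 0.25))
#' bt
#' @export
bootstrap_optima <- function(observations, treatment = NULL, B = 300L,
                             seed = 1L, domain = study_domain(),
                             center = c("cell_means", "fitted"),
                             degree = 3L, max_retries = 5L) {
  center <- match.arg(center)
  if (B < 2)
    stop_vfa("vfa_error_domain", "B must be >= 2")
  obs <- obs_for_treatment(observations, treatment)
  model0 <- vfa_surface(obs, degree = degree)
  sk <- .resample_skeleton(obs, if (center == "fitted") model0)
  ctr <- if (center == "fitted") sk$fitted else sk$centers
  lat <- domain_lattice(domain)
  X <- poly_design_matrix(lat$temperature, lat$day, degree)
  n <- nrow(obs)
  optima <- matrix(NA_real_, B, 3,
                   dimnames = list(NULL, c("temperature", "day", "predicted_vfa")))
  retries <- 0L
  with_seed(seed, function() {
    for (b in seq_len(B)) {
      for (attempt in seq_len(max_retries + 1L)) {
        y <- pmax(0, ctr + stats::rnorm(n, 0, sk$pooled_sd))
        obs_b <- obs
        obs_b$vfa <- y
        fit_b <- tryCatch(vfa_surface(obs_b, degree = degree),
                          vfa_error_singular = function(e) NULL)
        if (!is.null(fit_b)) break
        retries <<- retries + 1L
        if (attempt == max_retries + 1L)
          stop_vfa("vfa_error_singular",
                   sprintf("bootstrap replicate %d: refit singular after %d retries",
                           b, max_retries))
      }
      o <- .sweep_beta(fit_b$coefficients, X, lat)
      optima[b, ] <<- c(o$temperature, o$day, o$predicted_vfa)
    }
  })
  optima <- as.data.frame(optima)
  structure(
    list(treatment = model0$treatment, optima = optima, B = as.integer(B),
         seed = as.integer(seed), center = center,
         mean_opt_vfa = mean(optima$predicted_vfa),
         sd_opt_vfa = stats::sd(optima$predicted_vfa),
         pooled_sd = sk$pooled_sd, retries = retries,
         point_estimate = sweep_optimum(model0, domain)),
    class = "vfa_boot"
  )
}

#' @export
print.vfa_boot <- function(x, ...) {
  cat(sprintf("Bootstrap optima, treatment %s: B = %d (seed %d, %s centring)\n",
              format(x$treatment), x$B, x$seed, x$center))
  cat(sprintf("optimal VFA: mean %.1f, SD %.1f mg COD/L; point estimate %.1f at (%.2f deg C, %.2f d)\n",
              x$mean_opt_vfa, x$sd_opt_vfa, x$point_estimate$predicted_vfa,
              x$point_estimate$temperature, x$point_estimate$day))
  invisible(x)
}

# Extract the per-group bootstrap samples of optimal VFA from a list of
# vfa_boot objects (or plain numeric vectors).
.boot_samples <- function(distributions) {
  if (inherits(distributions, "vfa_boot")) distributions <- list(distributions)
  samples <- lapply(distributions, function(d) {
    if (inherits(d, "vfa_boot")) d$optima$predicted_vfa else as.numeric(d)
  })
  labs <- vapply(seq_along(distributions), function(i) {
    d <- distributions[[i]]
    if (inherits(d, "vfa_boot")) format(d$treatment)
    else if (!is.null(names(distributions)[i]) && nzchar(names(distributions)[i]))
      names(distributions)[i]
    else paste0("group", i)
  }, "")
  names(samples) <- labs
  samples
}

#' One-way ANOVA on bootstrap optima with regression-adjusted df
#'
#' Tests whether the treatments' mean optimal VFA productions differ.  The
#' bootstrap samples do not carry B - 1 genuine degrees of freedom per
#' group — the information available is bounded by the residual df of each
#' treatment's polynomial regression — so the within-group df is set to
#' `k * df_per_treatment` and the sums of squares are scaled as if each
#' group had `df_per_treatment + 1` observations, keeping the mean square
#' within equal to the pooled bootstrap variance.
#'
#' @param distributions List of `"vfa_boot"` objects (or numeric vectors of
#'   per-group samples), all with the same B.
#' @param df_per_treatment Degrees of freedom granted to each group (the
#'   study's tables imply 28).
#' @param alpha Significance level for the critical F (default 0.05).
#' @return An object of class `"vfa_anova"` with the SS/df/MS decomposition,
#'   `f_stat`, `p_value` and `f_critical`.
#' @examples
#' critical_f(0.05, 11, 336)  # 1.817
#' @export
anova_optima <- function(distributions, df_per_treatment, alpha = 0.05) {
  samples <- .boot_samples(distributions)
  k <- length(samples)
  if (k < 2)
    stop_vfa("vfa_error_domain", "need at least 2 groups")
  Bs <- lengths(samples)
  if (length(unique(Bs)) != 1L)
    stop_vfa("vfa_error_domain",
             "groups have unequal numbers of bootstrap replicates; align B first")
  m <- as.integer(df_per_treatment)
  if (m < 1)
    stop_vfa("vfa_error_domain", "df_per_treatment must be >= 1")
  means <- vapply(samples, mean, 0)
  vars <- vapply(samples, stats::var, 0)
  s2p <- mean(vars)
  n_eff <- m + 1L
  grand <- mean(means)
  ss_between <- n_eff * sum((means - grand)^2)
  df_between <- k - 1L
  df_within <- k * m
  ms_within <- s2p
  ss_within <- ms_within * df_within
  ms_between <- ss_between / df_between
  f_stat <- ms_between / ms_within
  structure(
    list(groups = names(samples), group_means = means, group_sds = sqrt(vars),
         ss_between = ss_between, ss_within = ss_within,
         ss_total = ss_between + ss_within,
         df_between = df_between, df_within = df_within,
         df_total = df_between + df_within,
         ms_between = ms_between, ms_within = ms_within,
         f_stat = f_stat,
         p_value = stats::pf(f_stat, df_between, df_within, lower.tail = FALSE),
         f_critical = critical_f(alpha, df_between, df_within),
         alpha = alpha, df_per_treatment = m),
    class = "vfa_anova"
  )
}

#' @export
print.vfa_anova <- function(x, digits = 3, ...) {
  cat("One-way ANOVA of bootstrap optimal VFA (regression-adjusted df)\n")
  tab <- data.frame(
    `Sum of squares` = c(x$ss_between, x$ss_within, x$ss_total),
    df = c(x$df_between, x$df_within, x$df_total),
    `Mean square` = c(x$ms_between, x$ms_within, NA),
    F = c(x$f_stat, NA, NA),
    `P value` = c(x$p_value, NA, NA),
    `Critical F` = c(x$f_critical, NA, NA),
    row.names = c("Between groups", "Within groups", "Total"),
    check.names = FALSE
  )
  print(format(tab, digits = digits, nsmall = 0), ...)
  invisible(x)
}

#' Two-sample t-test of the two best treatments
#'
#' Selects the two treatments with the highest mean bootstrap optimal VFA
#' and tests their difference with a pooled-variance two-sample t-test
#' (equal variance is the bootstrap's own assumption; set
#' `var_equal = FALSE` for Welch).  As in the ANOVA, each group is granted
#' `df_per_treatment` degrees of freedom, i.e. an effective sample size of
#' `df_per_treatment + 1`; the critical value is the two-sided t quantile at
#' `df1 + df2` df, which keeps the exact F = t-squared identity with the
#' two-group ANOVA.
#'
#' @param distributions List of `"vfa_boot"` objects (>= 2) or numeric
#'   vectors.
#' @param df_per_treatment Degrees of freedom per group.
#' @param alpha Two-sided significance level.
#' @param var_equal Pooled variance (default) or Welch.
#' @return An object of class `"vfa_ttest"`: means, SDs, dfs, `t_stat`,
#'   `t_critical`, `reject_null`.
#' @export
t_test_top_two <- function(distributions, df_per_treatment, alpha = 0.05,
                           var_equal = TRUE) {
  samples <- .boot_samples(distributions)
  if (length(samples) < 2)
    stop_vfa("vfa_error_domain", "need at least 2 groups")
  m <- as.integer(df_per_treatment)
  if (m < 1)
    stop_vfa("vfa_error_domain", "df_per_treatment must be >= 1")
  means <- vapply(samples, mean, 0)
  ord <- order(-means)
  top <- ord[1:2]
  m1 <- unname(means[top[1]]); m2 <- unname(means[top[2]])
  s1 <- stats::sd(samples[[top[1]]]); s2 <- stats::sd(samples[[top[2]]])
  n_eff <- m + 1L
  if (var_equal) {
    s2p <- (s1^2 + s2^2) / 2
    se <- sqrt(s2p * 2 / n_eff)
    df_t <- 2L * m
  } else {
    se <- sqrt((s1^2 + s2^2) / n_eff)
    df_t <- (s1^2 + s2^2)^2 / ((s1^4 + s2^4) / m) # Welch-Satterthwaite
  }
  t_stat <- (m1 - m2) / se
  t_crit <- critical_t(alpha, df_t)
  structure(
    list(best = names(samples)[top[1]], second = names(samples)[top[2]],
         mean1 = m1, mean2 = m2, sd1 = s1, sd2 = s2,
         df1 = m, df2 = m, df_t = df_t,
         t_stat = t_stat, t_critical = t_crit,
         reject_null = abs(t_stat) > t_crit,
         alpha = alpha, var_equal = var_equal),
    class = "vfa_ttest"
  )
}

#' @export
print.vfa_ttest <- function(x, ...) {
  cat("Two-sample t-test of the two best treatments\n")
  cat(sprintf("  best:   %s  mean %.2f, SD %.2f (df %d)\n", x$best, x$mean1, x$sd1, x$df1))
  cat(sprintf("  second: %s  mean %.2f, SD %.2f (df %d)\n", x$second, x$mean2, x$sd2, x$df2))
  cat(sprintf("  t = %.3f, critical t = %.3f (alpha %.2f, %s)\n",
              x$t_stat, x$t_critical, x$alpha,
              if (x$var_equal) "pooled variance" else "Welch"))
  cat(if (x$reject_null) "  -> difference is statistically significant\n"
      else "  -> no significant difference\n")
  invisible(x)
}

#' Critical values of the t and F distributions
#'
#' `critical_t()` is the two-sided t threshold: the `1 - alpha/2` quantile
#' with `df` degrees of freedom (2.052 at alpha 0.05, df 27).
#' `critical_f()` is the upper `1 - alpha` F quantile (1.817 at alpha 0.05,
#' df 11 and 336).
#'
#' @param alpha Significance level in (0, 1).
#' @param df,df1,df2 Degrees of freedom (>= 1; `critical_f` accepts
#'   non-integer df).
#' @return The critical value.
#' @examples
#' critical_t(0.05, 27)       # 2.052
#' critical_f(0.05, 11, 336)  # 1.817
#' @export
critical_t <- function(alpha, df) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_vfa("vfa_error_domain", "alpha must be in (0, 1)")
  if (!is.finite(df) || df < 1)
    stop_vfa("vfa_error_domain", "df must be >= 1")
  stats::qt(1 - alpha / 2, df)
}

#' @rdname critical_t
#' @export
critical_f <- function(alpha, df1, df2) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_vfa("vfa_error_domain", "alpha must be in (0, 1)")
  if (!is.finite(df1) || df1 < 1 || !is.finite(df2) || df2 < 1)
    stop_vfa("vfa_error_domain", "df1 and df2 must be >= 1")
  stats::qf(1 - alpha, df1, df2)
}
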