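# Shared fixtures: tiny observation tables built in code.

# Minimal valid observation table: one treatment, arbitrary coordinates.
tiny_obs <- function(t = c(1, 2, 3), d = c(1, 2, 3), vfa = c(10, 20, 30),
                     replicate = rep(1, length(t))) {
  data.frame(sludge_type = "PS", organic_load = 14, initial_ph = 10.5,
             temperature = t, day = d, replicate = replicate, vfa = vfa)
}

# Observations lying exactly on a known polynomial, on a small-coordinate
# grid (t, d in [0, 6]) where raw-monomial normal equations are well
# conditioned.  Optional iid noise via rnorm (caller seeds).
small_grid_obs <- function(beta, noise = 0, reps = 2,
                           ts = c(0, 2, 4, 6), ds = c(0, 2, 4, 6)) {
  g <- expand.grid(temperature = ts, day = ds)
  g <- g[rep(seq_len(nrow(g)), each = reps), ]
  X <- poly_design_matrix(g$temperature, g$day, 3)
  y <- drop(X %*% beta) + rnorm(nrow(g), 0, noise)
  data.frame(sludge_type = "PS", organic_load = 14, initial_ph = 10.5,
             temperature = g$temperature, day = g$day,
             replicate = sequence(rle(paste(g$temperature, g$day))$lengths),
             vfa = pmax(0, y))
}

# Hand-rolled normal-equations OLS oracle on raw monomials.
ols_oracle <- function(obs, degree = 3) {
  X <- poly_design_matrix(obs$temperature, obs$day, degree)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, obs$vfa))
  res <- obs$vfa - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  list(beta = drop(beta), se = se, t = drop(beta) / se, sigma = sqrt(s2))
}

# A positive cubic on the study domain with an interior peak, plus noise sd,
# as a vfa_truth.  Used where tests need a custom (non-default) truth.
quad_peak_truth <- function(t0 = 40, d0 = 6, height = 5000, noise_sd = 0) {
  # height - (t - t0)^2 - (d - d0)^2
  beta <- c(height - t0^2 - d0^2, 2 * t0, 2 * d0, -1, 0, -1, 0, 0, 0, 0)
  truth_surface(beta, noise_sd = noise_sd)
}

best_treatment <- function() treatment_key("PS", 14, 10.5)

# Subset a multi-treatment table to one treatment (plain data.frame).
obs_for_study_treatment <- function(obs, tr = best_treatment()) {
  lab <- sprintf("%s OL%g pH%g", obs$sludge_type, obs$organic_load,
                 obs$initial_ph)
  out <- obs[lab == format(tr), ]
  rownames(out) <- NULL
  out
}

coarse_domain <- function() study_domain(resolution = 0.25)
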