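# Bivariate polynomial response-surface fit by OLS with raw-monomial
# reporting, coefficient t-values, Pareto ranking and degree comparison.

# Number of monomials of a full bivariate polynomial of given total degree.
n_poly_terms <- function(degree) ((degree + 1L) * (degree + 2L)) %/% 2L

# Fixed basis ordering: by total degree, then decreasing power of t.
# Degree 3: 1, t, d, t^2, t*d, d^2, t^3, t^2*d, t*d^2, d^3.
poly_term_powers <- function(degree) {
  out <- do.call(rbind, lapply(0:degree, function(k)
    cbind(pt = k:0, pd = 0:k)))
  as.data.frame(out)
}

poly_term_index <- function(pt, pd) {
  k <- pt + pd
  (k * (k + 1L)) %/% 2L + pd + 1L
}

poly_term_names <- function(degree) {
  pw <- poly_term_powers(degree)
  mapply(function(a, b) {
    ts <- if (a == 0) "" else if (a == 1) "t" else paste0("t^", a)
    ds <- if (b == 0) "" else if (b == 1) "d" else paste0("d^", b)
    lab <- paste(c(ts, ds)[nzchar(c(ts, ds))], collapse = ":")
    if (!nzchar(lab)) "(Intercept)" else lab
  }, pw$pt, pw$pd)
}

#' Raw-monomial design matrix
#'
#' Builds the design matrix of the full bivariate polynomial of the given
#' total degree in temperature `t` and retention day `d`, columns in the
#' fixed order by total degree then decreasing power of `t` — for the cubic:
#' `[1, t, d, t^2, t*d, d^2, t^3, t^2*d, t*d^2, d^3]`.
#'
#' @param temperature,day Coordinate vectors (recycled to common length).
#' @param degree Total polynomial degree (default 3).
#' @return An `n x n_terms` numeric matrix with term-name column labels.
#' @examples
#' poly_design_matrix(0, 2)  # 1 0 2 0 0 4 0 0 0 8
#' @export
poly_design_matrix <- function(temperature, day, degree = 3L) {
  n <- max(length(temperature), length(day))
  if (n == 0L)
    stop_vfa("vfa_error_domain", "points must be non-empty")
  t <- rep_len(as.numeric(temperature), n)
  d <- rep_len(as.numeric(day), n)
  pw <- poly_term_powers(degree)
  X <- mapply(function(a, b) t^a * d^b, pw$pt, pw$pd)
  X <- matrix(X, nrow = n, dimnames = list(NULL, poly_term_names(degree)))
  X
}

# Matrix A mapping raw monomials r(T,D) to scaled monomials s(T,D):
# s = A r with ts = (T - mt)/st, ds = (D - md)/sd.  Row k is the raw-basis
# expansion of scaled term k (binomial expansion), so raw OLS coefficients
# are t(A) %*% scaled coefficients.
monomial_transform <- function(mt, st, md, sd_, degree) {
  pw <- poly_term_powers(degree)
  p <- nrow(pw)
  A <- matrix(0, p, p)
  for (k in seq_len(p)) {
    i <- pw$pt[k]; j <- pw$pd[k]
    for (a in 0:i) for (b in 0:j) {
      A[k, poly_term_index(a, b)] <-
        choose(i, a) * choose(j, b) * (-mt)^(i - a) * (-md)^(j - b) /
        (st^i * sd_^j)
    }
  }
  A
}

#' Fit a polynomial VFA response surface by ordinary least squares
#'
#' Fits the bivariate polynomial (default third degree, 10 coefficients)
#' `vfa = b0 + b1 t + b2 d + b3 t^2 + b4 t d + b5 d^2 + b6 t^3 + b7 t^2 d +
#' b8 t d^2 + b9 d^3` to the replicate-level observations of one treatment.
#' Replicates enter as individual rows with equal weight — they are never
#' averaged — so the coefficient of determination is computed against
#' replicate scatter and cannot reach 1 on noisy data even when the mean
#' response is captured perfectly.
#'
#' Internally the fit centres and scales `t` and `d` before building the
#' monomial basis (raw cubic monomials make the normal equations severely
#' ill-conditioned at temperatures up to 55), then maps the estimates and
#' their covariance back to the raw monomial scale for reporting, so the
#' returned coefficients are directly comparable across treatments.
#' Coefficient t-values use the classical homoscedastic OLS covariance with
#' `n - p` residual degrees of freedom.
#'
#' @param observations An observation table (see [read_observations()],
#'   [simulate_study()]).
#' @param treatment The treatment to fit; may be omitted when the table
#'   holds a single treatment.
#' @param degree Total polynomial degree (default 3).
#' @return An object of class `"vfa_surface"` with components
#'   `coefficients` (raw monomial scale), `se`, `t_values`, `vcov`,
#'   `r.squared`, `adj.r.squared`, `sigma` (residual SD), `df.residual`,
#'   `n`, `degree`, `treatment`, `fitted.values`, `residuals` and the model
#'   frame `data`.  Supports `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `confint`, `fitted`, `residuals`, `plot` and `simulate`.
#' @seealso [pareto_tvalues()], [compare_degrees()], [sweep_optimum()]
#' @examples
#' obs <- simulate_study(seed = 1)
#' fit <- vfa_surface(obs, treatment_key("PS", 14, 10.5))
#' summary(fit)
#' @export
vfa_surface <- function(observations, treatment = NULL, degree = 3L) {
  obs <- obs_for_treatment(observations, treatment)
  tr <- treatment_key(obs$sludge_type[1], obs$organic_load[1], obs$initial_ph[1])
  t <- obs$temperature; d <- obs$day; y <- obs$vfa
  degree <- as.integer(degree)
  p <- n_poly_terms(degree)
  n <- length(y)
  if (n < p + 1L)
    stop_vfa("vfa_error_underdetermined",
             sprintf("need at least %d rows for a degree-%d surface (%d given, residual df must be >= 1)",
                     p + 1L, degree, n))
  mt <- mean(t); st <- stats::sd(t); md <- mean(d); sd_ <- stats::sd(d)
  if (!is.finite(st) || st == 0) st <- 1
  if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
  Xs <- poly_design_matrix((t - mt) / st, (d - md) / sd_, degree)
  qrX <- qr(Xs)
  if (qrX$rank < p) {
    bad <- colnames(Xs)[qrX$pivot[(qrX$rank + 1L):p]]
    stop_vfa("vfa_error_singular",
             paste0("design matrix is rank deficient; offending column(s): ",
                    paste(bad, collapse = ", ")))
  }
  beta_s <- qr.coef(qrX, y)
  fitted <- drop(Xs %*% beta_s)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df <- n - p
  sigma2 <- rss / df
  xtx_inv_s <- chol2inv(chol(crossprod(Xs)))
  A <- monomial_transform(mt, st, md, sd_, degree)
  beta <- drop(crossprod(A, beta_s))
  vc <- sigma2 * crossprod(A, xtx_inv_s %*% A)
  se <- sqrt(pmax(0, diag(vc)))
  nm <- poly_term_names(degree)
  names(beta) <- nm; names(se) <- nm
  dimnames(vc) <- list(nm, nm)
  structure(
    list(coefficients = beta, se = se, t_values = beta / se, vcov = vc,
         r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
         adj.r.squared = if (tss > 0) 1 - (rss / df) / (tss / (n - 1)) else NA_real_,
         sigma = sqrt(sigma2), df.residual = df, n = n, degree = degree,
         treatment = tr, fitted.values = fitted, residuals = res,
         data = data.frame(temperature = t, day = d, vfa = y),
         center = c(t = mt, d = md), scale = c(t = st, d = sd_),
         call = match.call()),
    class = "vfa_surface"
  )
}

#' @export
coef.vfa_surface <- function(object, ...) object$coefficients

#' @export
vcov.vfa_surface <- function(object, ...) object$vcov

#' @export
fitted.vfa_surface <- function(object, ...) object$fitted.values

#' @export
residuals.vfa_surface <- function(object, ...) object$residuals

#' Predict VFA production from a fitted surface
#'
#' Evaluates the fitted polynomial at the supplied coordinates (raw
#' monomial evaluation, exact up to floating arithmetic).
#'
#' @param object A `"vfa_surface"` fit.
#' @param temperature,day Coordinates (vectorized, recycled); alternatively
#'   pass `newdata`.
#' @param newdata Optional data.frame with columns `temperature` and `day`.
#' @param ... Unused.
#' @return Predicted VFA, mg COD/L.
#' @export
predict.vfa_surface <- function(object, temperature = NULL, day = NULL,
                                newdata = NULL, ...) {
  if (!is.null(newdata)) {
    temperature <- newdata$temperature; day <- newdata$day
  }
  if (is.null(temperature) || is.null(day))
    stop_vfa("vfa_error_domain", "supply temperature and day (or newdata)")
  if (any(!is.finite(temperature)) || any(!is.finite(day)))
    stop_vfa("vfa_error_domain", "prediction coordinates must be finite")
  X <- poly_design_matrix(temperature, day, object$degree)
  drop(X %*% object$coefficients)
}

#' @export
confint.vfa_surface <- function(object, parm, level = 0.95, ...) {
  q <- stats::qt((1 + level) / 2, object$df.residual)
  ci <- cbind(object$coefficients - q * object$se,
              object$coefficients + q * object$se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, (1 + level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.vfa_surface <- function(x, digits = 4, ...) {
  cat(sprintf("Degree-%d VFA response surface, treatment %s\n",
              x$degree, format(x$treatment)))
  cat(sprintf("n = %d, residual df = %d, r^2 = %.3f, residual SD = %.1f mg COD/L\n",
              x$n, x$df.residual, x$r.squared, x$sigma))
  cat("Coefficients (raw monomial scale):\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.vfa_surface <- function(object, ...) {
  tab <- cbind(
    Estimate = object$coefficients,
    `Std. Error` = object$se,
    `t value` = object$t_values,
    `Pr(>|t|)` = 2 * stats::pt(abs(object$t_values), object$df.residual,
                               lower.tail = FALSE)
  )
  out <- list(treatment = object$treatment, coefficients = tab,
              r.squared = object$r.squared,
              adj.r.squared = object$adj.r.squared, sigma = object$sigma,
              df.residual = object$df.residual, n = object$n,
              degree = object$degree)
  class(out) <- "summary.vfa_surface"
  out
}

#' @export
print.summary.vfa_surface <- function(x, ...) {
  cat(sprintf("Degree-%d VFA response surface, treatment %s\n\n",
              x$degree, format(x$treatment)))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nr^2 = %.4f (adjusted %.4f), residual SD = %.1f mg COD/L on %d df (n = %d)\n",
              x$r.squared, x$adj.r.squared, x$sigma, x$df.residual, x$n))
  invisible(x)
}

#' Contour plot of a fitted surface
#'
#' Draws the predicted response over the feasible domain with the design
#' points overlaid, in the style of the study's contour maps.
#'
#' @param x A `"vfa_surface"` fit.
#' @param domain A `"vfa_domain"`; defaults to [study_domain()] at a coarse
#'   plotting resolution.
#' @param ... Passed to [graphics::filled.contour()].
#' @return `x`, invisibly.
#' @export
plot.vfa_surface <- function(x, domain = study_domain(resolution = 0.25), ...) {
  ts <- seq(domain$temp_range[1], domain$temp_range[2], by = domain$resolution)
  ds <- seq(domain$day_range[1], domain$day_range[2], by = domain$resolution)
  z <- outer(ts, ds, function(a, b) predict(x, a, b))
  mask <- outer(ts, ds, function(a, b) b <= domain$max_day_at(a) + 1e-9)
  z[!mask] <- NA
  graphics::filled.contour(
    ts, ds, z, color.palette = grDevices::hcl.colors,
    xlab = "temperature (deg C)", ylab = "retention time (days)",
    main = sprintf("Predicted VFA (mg COD/L), %s", format(x$treatment)),
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::points(x$data$temperature, x$data$day, pch = 3)
    }, ...)
  invisible(x)
}

#' Pareto ranking of coefficient t-values
#'
#' Ranks the polynomial terms by decreasing absolute t-value and flags each
#' as significant when |t| exceeds the two-sided critical t at the given
#' level with the fit's residual degrees of freedom.  High-ranking cubic
#' terms justify the third-degree model: a lower-degree polynomial could not
#' capture the response.  The intercept is ranked like any other term.
#'
#' @param model A `"vfa_surface"` fit.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A data.frame with columns `term`, `t_value`, `abs_t`,
#'   `significant`, sorted by `abs_t` descending, with attributes
#'   `threshold` (the critical t) and `alpha`.
#' @examples
#' obs <- simulate_study(seed = 1)
#' fit <- vfa_surface(obs, treatment_key("PS", 14, 10.5))
#' pareto_tvalues(fit)
#' @export
pareto_tvalues <- function(model, alpha = 0.05) {
  if (!inherits(model, "vfa_surface"))
    stop_vfa("vfa_error_domain", "model must be a vfa_surface fit")
  thr <- critical_t(alpha, model$df.residual)
  out <- data.frame(term = names(model$t_values),
                    t_value = unname(model$t_values),
                    abs_t = abs(unname(model$t_values)),
                    stringsAsFactors = FALSE)
  out$significant <- out$abs_t > thr
  out <- out[order(-out$abs_t), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "alpha") <- alpha
  out
}

#' Compare polynomial degrees on the same data
#'
#' Fits full bivariate polynomials of the requested degrees (default 2, 3
#' and 4) to one treatment's observations and reports r-squared, adjusted
#' r-squared and residual degrees of freedom per degree — the check that the
#' cubic is a good balance between simplicity and accuracy (a quartic should
#' not perform much better despite spending five more parameters).
#'
#' @param observations An observation table.
#' @param treatment The treatment to fit (optional for single-treatment
#'   tables).
#' @param degrees Integer vector of total degrees.
#' @return A data.frame with columns `degree`, `n_terms`, `r_squared`,
#'   `adj_r_squared`, `residual_df`.
#' @export
compare_degrees <- function(observations, treatment = NULL, degrees = c(2L, 3L, 4L)) {
  rows <- lapply(sort(as.integer(degrees)), function(g) {
    f <- vfa_surface(observations, treatment, degree = g)
    data.frame(degree = g, n_terms = n_poly_terms(g),
               r_squared = f$r.squared, adj_r_squared = f$adj.r.squared,
               residual_df = f$df.residual)
  })
  do.call(rbind, rows)
}
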