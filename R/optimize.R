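# Brute-force grid optimization over the methane-censored feasible domain.

#' Feasible (temperature, day) domain of the study
#'
#' The sweep domain is the rectangle 25-55 degrees C by 0-12 days at a given
#' lattice resolution, censored by methane onset: reactors above 45 degrees C
#' only ran 9 days.  Two censoring shapes are available: a step rule
#' (12 days up to 45 degrees C, 9 above — the default, which adds no
#' information beyond the experiment) and a linear taper from 12 to 9 days
#' between 45 and 55 degrees C.
#'
#' @param resolution Lattice step in both axes; default 0.05 (degrees C and
#'   days).
#' @param censor `"step"` or `"linear"`.
#' @param temp_range,day_range Numeric length-2 ranges.
#' @param censor_day Maximum day in the censored region (default 9).
#' @param censor_above Temperature above which censoring applies (default
#'   45).
#' @return An object of class `"vfa_domain"`: a list with the ranges, the
#'   resolution and `max_day_at`, a vectorized function mapping temperature
#'   to the maximum admissible day.
#' @examples
#' dom <- study_domain()
#' dom$max_day_at(c(35, 55))  # 12 9
#' @export
study_domain <- function(resolution = 0.05, censor = c("step", "linear"),
                         temp_range = c(25, 55), day_range = c(0, 12),
                         censor_day = 9, censor_above = 45) {
  censor <- match.arg(censor)
  if (resolution <= 0)
    stop_vfa("vfa_error_domain", "resolution must be > 0")
  if (temp_range[1] >= temp_range[2] || day_range[1] >= day_range[2])
    stop_vfa("vfa_error_domain", "ranges must satisfy min < max")
  if (censor_day < day_range[1] || censor_day > day_range[2])
    stop_vfa("vfa_error_domain", "censor_day must lie within day_range")
  dmax <- day_range[2]; tmax <- temp_range[2]
  max_day_at <- if (censor == "step") {
    function(t) ifelse(t <= censor_above, dmax, censor_day)
  } else {
    function(t) ifelse(t <= censor_above, dmax,
                       dmax - (dmax - censor_day) *
                         pmin(1, (t - censor_above) / (tmax - censor_above)))
  }
  structure(
    list(temp_range = temp_range, day_range = day_range,
         resolution = resolution, censor = censor,
         max_day_at = max_day_at),
    class = "vfa_domain"
  )
}

#' @export
print.vfa_domain <- function(x, ...) {
  cat(sprintf("Feasible domain: t in [%g, %g] deg C, d in [%g, %g] days, step %g, %s censoring\n",
              x$temp_range[1], x$temp_range[2], x$day_range[1],
              x$day_range[2], x$resolution, x$censor))
  invisible(x)
}

#' Admissible lattice points of a feasible domain
#'
#' Enumerates the sweep lattice: all (temperature, day) grid points at the
#' domain resolution with `day <= max_day_at(temperature)`, ordered by
#' temperature then day ascending (the tie-break order of
#' [sweep_optimum()]).  Grid points are generated as
#' `min + resolution * 0:k` so lattices at nested resolutions share points.
#'
#' @param domain A `"vfa_domain"`.
#' @return A data.frame with columns `temperature`, `day`.
#' @export
domain_lattice <- function(domain) {
  if (!inherits(domain, "vfa_domain"))
    stop_vfa("vfa_error_domain", "domain must come from study_domain()")
  r <- domain$resolution
  tn <- floor((domain$temp_range[2] - domain$temp_range[1]) / r + 1e-9)
  dn <- floor((domain$day_range[2] - domain$day_range[1]) / r + 1e-9)
  ts <- domain$temp_range[1] + r * (0:tn)
  ds <- domain$day_range[1] + r * (0:dn)
  grid <- expand.grid(day = ds, temperature = ts, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("temperature", "day")]
  keep <- grid$day <= domain$max_day_at(grid$temperature) + 1e-9
  out <- grid[keep, , drop = FALSE]
  if (!nrow(out))
    stop_vfa("vfa_error_domain", "admissible lattice is empty")
  rownames(out) <- NULL
  out
}

# Fast inner sweep: raw coefficient vector against a precomputed lattice
# design matrix.  Ties resolve to the first lattice row, i.e. lowest
# temperature then lowest day.
.sweep_beta <- function(beta, X, lattice) {
  v <- drop(X %*% beta)
  i <- which.max(v)
  list(temperature = lattice$temperature[i], day = lattice$day[i],
       predicted_vfa = v[i])
}

#' Locate the production optimum by exhaustive lattice sweep
#'
#' Evaluates the fitted surface at every admissible lattice point of the
#' feasible domain and returns the maximizer.  Ties are broken toward the
#' lowest temperature, then the lowest day — the cheaper operating
#' condition.  Gradient-based optimization is deliberately avoided: the
#' censored domain makes an exhaustive sweep at 0.05 resolution both simpler
#' and amply precise relative to experimental error.
#'
#' @param model A `"vfa_surface"` fit (or `"vfa_truth"` surface).
#' @param domain A `"vfa_domain"`; default [study_domain()].
#' @return An object of class `"vfa_optimum"`: list with `temperature`,
#'   `day`, `predicted_vfa`, `treatment` (if known).
#' @examples
#' obs <- simulate_study(seed = 1)
#' fit <- vfa_surface(obs, treatment_key("PS", 14, 10.5))
#' sweep_optimum(fit)
#' @export
sweep_optimum <- function(model, domain = study_domain()) {
  beta <- stats::coef(model)
  degree <- if (!is.null(model$degree)) model$degree else 3L
  lat <- domain_lattice(domain)
  X <- poly_design_matrix(lat$temperature, lat$day, degree)
  opt <- .sweep_beta(beta, X, lat)
  structure(
    c(opt, list(treatment = model$treatment, resolution = domain$resolution)),
    class = "vfa_optimum"
  )
}

#' @export
print.vfa_optimum <- function(x, ...) {
  cat(sprintf("Optimum%s: %.2f deg C, %.2f days, predicted VFA %.0f mg COD/L\n",
              if (!is.null(x$treatment)) paste0(" (", format(x$treatment), ")") else "",
              x$temperature, x$day, x$predicted_vfa))
  invisible(x)
}

#' Predicted time profile at a fixed temperature
#'
#' Evaluates the fitted surface along the admissible days at one temperature
#' (at the domain resolution), e.g. to compare laboratory predictions with a
#' pilot-scale time series.
#'
#' @param model A `"vfa_surface"` fit (or `"vfa_truth"`).
#' @param temperature Temperature, degrees C; must lie in the domain's
#'   temperature range.
#' @param domain A `"vfa_domain"`.
#' @return A data.frame with columns `day`, `predicted_vfa`.
#' @export
profile_at_temperature <- function(model, temperature, domain = study_domain()) {
  if (!inherits(domain, "vfa_domain"))
    stop_vfa("vfa_error_domain", "domain must come from study_domain()")
  if (temperature < domain$temp_range[1] || temperature > domain$temp_range[2])
    stop_vfa("vfa_error_domain",
             sprintf("temperature %g outside domain [%g, %g]", temperature,
                     domain$temp_range[1], domain$temp_range[2]))
  r <- domain$resolution
  dn <- floor((domain$day_range[2] - domain$day_range[1]) / r + 1e-9)
  ds <- domain$day_range[1] + r * (0:dn)
  ds <- ds[ds <= domain$max_day_at(temperature) + 1e-9]
  beta <- stats::coef(model)
  degree <- if (!is.null(model$degree)) model$degree else 3L
  X <- poly_design_matrix(rep(temperature, length(ds)), ds, degree)
  data.frame(day = ds, predicted_vfa = drop(X %*% beta))
}
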