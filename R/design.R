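# Factorial study design, observation-table validation and VFA yield.

# Canonical study levels.  Admissible organic loads depend on the sludge:
# digested sludge was fed at 4 or 6 g VS/L, primary sludge at 10 or 14.
.design_levels <- list(
  sludge = c("DS", "PS"),
  loads = list(DS = c(4, 6), PS = c(10, 14)),
  ph = c(9.5, 10.5, 11.5),
  temperature = c(25, 35, 45, 55)
)

#' Enumerate the factorial study design
#'
#' The batch study crossed two sludge types (each at two organic loads),
#' three initial pH levels and four incubation temperatures, giving 48
#' combinations run in triplicate.  Temperature is a continuous covariate of
#' the response surface, so the 48 combinations collapse to 12 discrete
#' treatments (see [vfa_treatments()]).
#'
#' @return A data.frame with 48 rows and columns `sludge_type`,
#'   `organic_load`, `initial_ph`, `temperature`, ordered by sludge type,
#'   load, pH and temperature (all ascending).
#' @seealso [vfa_treatments()], [design_days()]
#' @examples
#' nrow(vfa_design())  # 48
#' @export
vfa_design <- function() {
  lv <- .design_levels
  rows <- lapply(lv$sludge, function(s) {
    expand.grid(
      temperature = lv$temperature,
      initial_ph = lv$ph,
      organic_load = lv$loads[[s]],
      sludge_type = s,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[, c("sludge_type", "organic_load", "initial_ph", "temperature")]
  out <- out[order(out$sludge_type, out$organic_load, out$initial_ph,
                   out$temperature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse design combinations to discrete treatments
#'
#' Drops the temperature column and returns the unique discrete treatments,
#' in the same deterministic order as the design.  Temperature does not
#' define a treatment: each treatment's response is modelled continuously
#' over temperature and retention day.
#'
#' @param combinations A data.frame with columns `sludge_type`,
#'   `organic_load`, `initial_ph` (a `temperature` column, if present, is
#'   ignored), e.g. the output of [vfa_design()].
#' @return A data.frame of unique treatments (12 for the full study design).
#' @examples
#' nrow(vfa_treatments())  # 12
#' @export
vfa_treatments <- function(combinations = vfa_design()) {
  if (!is.data.frame(combinations) || nrow(combinations) == 0L)
    stop_vfa("vfa_error_validation", "combinations must be a non-empty data.frame")
  need <- c("sludge_type", "organic_load", "initial_ph")
  miss <- setdiff(need, names(combinations))
  if (length(miss))
    stop_vfa("vfa_error_missing_column",
             paste0("missing column(s): ", paste(miss, collapse = ", ")))
  out <- unique(combinations[, need, drop = FALSE])
  out <- out[order(out$sludge_type, out$organic_load, out$initial_ph), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sampling days for a given incubation temperature
#'
#' Reactors were sacrificed every 3 days over a 12-day horizon, except at
#' 55 degrees C where methane onset cut the experiment at 9 days.  Day 0 is
#' optional: the figures plot a day-0 baseline but the surface is usually
#' fitted from day 3 onward.
#'
#' @param temperature Incubation temperature, degrees C.
#' @param include_day0 Include a day-0 baseline row? Default `FALSE`.
#' @return Numeric vector of sampling days.
#' @examples
#' design_days(35)  # 3 6 9 12
#' design_days(55)  # 3 6 9
#' @export
design_days <- function(temperature, include_day0 = FALSE) {
  if (!is.finite(temperature))
    stop_vfa("vfa_error_domain", "temperature must be finite")
  days <- if (temperature >= 55) c(3, 6, 9) else c(3, 6, 9, 12)
  if (isTRUE(include_day0)) days <- c(0, days)
  days
}

#' VFA production yield
#'
#' Yield normalizes the VFA output concentration by the volatile solids fed:
#' yield = (VFA output) / (VS fed), with VFA converted from mg COD/L to
#' g COD/L so the result is in g COD per g VS.
#'
#' @param vfa_output VFA concentration, mg COD/L (>= 0). Vectorized.
#' @param vs_fed Volatile solids fed, g VS/L (> 0). Vectorized.
#' @return Yield in g COD/g VS.
#' @examples
#' vfa_yield(7112, 14)  # ~ 0.508
#' @export
vfa_yield <- function(vfa_output, vs_fed) {
  vfa_output <- as.numeric(vfa_output)
  vs_fed <- as.numeric(vs_fed)
  if (any(!is.finite(vs_fed)) || any(vs_fed <= 0))
    stop_vfa("vfa_error_domain", "vs_fed must be positive (g VS/L)")
  if (any(!is.finite(vfa_output)) || any(vfa_output < 0))
    stop_vfa("vfa_error_domain", "vfa_output must be finite and non-negative (mg COD/L)")
  (vfa_output / 1000) / vs_fed
}

# Canonical CSV header for observation tables.
.obs_csv_cols <- c("sludge_type", "organic_load", "initial_ph",
                   "temperature", "day", "replicate", "vfa_mg_cod_per_l")

#' Validate an observation table
#'
#' Checks the schema invariants of a tidy VFA observation table: all seven
#' columns present, numeric fields finite, `day` in \[0, 12\], replicate
#' indices integral and >= 1, VFA non-negative, and no duplicated
#' (treatment, temperature, day, replicate) key.  Errors are classed
#' (`vfa_error_missing_column`, `vfa_error_bad_numeric`,
#' `vfa_error_duplicate_key`, `vfa_error_negative_vfa`,
#' `vfa_error_domain`) and name the offending row.
#'
#' @param x A data.frame with columns `sludge_type`, `organic_load`,
#'   `initial_ph`, `temperature`, `day`, `replicate`, `vfa` (or the CSV
#'   header name `vfa_mg_cod_per_l`).
#' @return The table, invisibly classed `"vfa_obs"` with canonical column
#'   names.
#' @export
validate_observations <- function(x) {
  if (!is.data.frame(x))
    stop_vfa("vfa_error_validation", "observations must be a data.frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if ("vfa_mg_cod_per_l" %in% names(x) && !"vfa" %in% names(x))
    names(x)[names(x) == "vfa_mg_cod_per_l"] <- "vfa"
  need <- c("sludge_type", "organic_load", "initial_ph", "temperature",
            "day", "replicate", "vfa")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_vfa("vfa_error_missing_column",
             paste0("missing column(s): ", paste(miss, collapse = ", ")))
  x <- x[, need, drop = FALSE]
  x$sludge_type <- as.character(x$sludge_type)
  for (col in need[-1]) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_vfa("vfa_error_bad_numeric",
               sprintf("column '%s' is not finite numeric at row %d", col, bad[1]))
    x[[col]] <- v
  }
  bad <- which(x$day < 0 | x$day > 12)
  if (length(bad))
    stop_vfa("vfa_error_domain",
             sprintf("day outside [0, 12] at row %d", bad[1]))
  bad <- which(x$replicate < 1 | x$replicate != round(x$replicate))
  if (length(bad))
    stop_vfa("vfa_error_domain",
             sprintf("replicate must be an integer >= 1 at row %d", bad[1]))
  bad <- which(x$vfa < 0)
  if (length(bad))
    stop_vfa("vfa_error_negative_vfa",
             sprintf("negative vfa at row %d", bad[1]))
  key <- paste(x$sludge_type, x$organic_load, x$initial_ph, x$temperature,
               x$day, x$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop_vfa("vfa_error_duplicate_key",
             sprintf("duplicate (treatment, temperature, day, replicate) key at row %d",
                     dup[1]))
  class(x) <- c("vfa_obs", "data.frame")
  invisible(x)
}

#' Read an observation table from CSV
#'
#' Expects the dialect
#' `sludge_type,organic_load,initial_ph,temperature,day,replicate,vfa_mg_cod_per_l`
#' (UTF-8, dot decimal separator).  All schema invariants are enforced; rows
#' keep file order.
#'
#' @param source Path to a CSV file, or a character vector of CSV lines.
#' @return A validated observation table of class `"vfa_obs"`, with a
#'   `"provenance"` attribute recording the source.
#' @seealso [write_observations()], [validate_observations()]
#' @export
read_observations <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                           colClasses = "character")
    prov <- source
  } else {
    raw <- utils::read.csv(text = paste(source, collapse = "\n"),
                           stringsAsFactors = FALSE, colClasses = "character")
    prov <- "inline text"
  }
  out <- validate_observations(raw)
  attr(out, "provenance") <- prov
  out
}

#' Write an observation table to CSV
#'
#' Inverse of [read_observations()]: emits the canonical seven-column CSV
#' dialect so that a written table reads back identically.
#'
#' @param x An observation table (validated or coercible).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(x, path) {
  x <- validate_observations(x)
  out <- as.data.frame(x)
  names(out)[names(out) == "vfa"] <- "vfa_mg_cod_per_l"
  utils::write.csv(out[, .obs_csv_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.vfa_obs <- function(x, n = 10, ...) {
  tr <- unique(treatment_label(x$sludge_type, x$organic_load, x$initial_ph))
  cat(sprintf("VFA observation table: %d rows, %d treatment(s)\n",
              nrow(x), length(tr)))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("provenance:", prov, "\n")
  print.data.frame(utils::head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat("# ...", nrow(x) - n, "more rows\n")
  invisible(x)
}

# Subset an observation table to one treatment (all rows if tr is NULL and
# the table holds a single treatment).
obs_for_treatment <- function(x, treatment = NULL) {
  x <- validate_observations(x)
  lab <- treatment_label(x$sludge_type, x$organic_load, x$initial_ph)
  if (is.null(treatment)) {
    if (length(unique(lab)) != 1L)
      stop_vfa("vfa_error_validation",
               "table holds several treatments; supply `treatment`")
    return(x)
  }
  tr <- as_treatment(treatment)
  keep <- lab == format(tr)
  if (!any(keep))
    stop_vfa("vfa_error_validation",
             paste0("no rows for treatment ", format(tr)))
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
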