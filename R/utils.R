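# Internal helpers: classed error conditions and treatment keys.

stop_vfa <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "vfa_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Construct a treatment key
#'
#' A treatment is the discrete experimental unit of the study: a sludge type
#' (`"PS"` primary or `"DS"` digested), an organic load in g VS/L and an
#' initial pH.  Temperature and retention day are continuous covariates of
#' the response surface, not treatment factors.
#'
#' @param sludge_type `"PS"` or `"DS"`.
#' @param organic_load Organic load fed at startup, g VS/L (> 0).
#' @param initial_ph Initial pH (> 0).
#' @return An object of class `"vfa_treatment"`: a named list with the three
#'   fields.
#' @examples
#' treatment_key("PS", 14, 10.5)
#' @export
treatment_key <- function(sludge_type, organic_load, initial_ph) {
  sludge_type <- as.character(sludge_type)
  if (length(sludge_type) != 1L || !sludge_type %in% c("PS", "DS"))
    stop_vfa("vfa_error_domain", "sludge_type must be \"PS\" or \"DS\"")
  organic_load <- as.numeric(organic_load)
  initial_ph <- as.numeric(initial_ph)
  if (!is.finite(organic_load) || organic_load <= 0)
    stop_vfa("vfa_error_domain", "organic_load must be a positive number (g VS/L)")
  if (!is.finite(initial_ph) || initial_ph <= 0)
    stop_vfa("vfa_error_domain", "initial_ph must be a positive number")
  structure(
    list(sludge_type = sludge_type, organic_load = organic_load,
         initial_ph = initial_ph),
    class = "vfa_treatment"
  )
}

# Coerce a treatment given as vfa_treatment, named list, or one-row
# data.frame into a vfa_treatment.
as_treatment <- function(x) {
  if (inherits(x, "vfa_treatment")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L)
      stop_vfa("vfa_error_domain", "a treatment data.frame must have exactly one row")
    x <- as.list(x)
  }
  if (is.list(x) &&
      all(c("sludge_type", "organic_load", "initial_ph") %in% names(x)))
    return(treatment_key(x$sludge_type, x$organic_load, x$initial_ph))
  stop_vfa("vfa_error_domain",
           "cannot interpret object as a treatment (need sludge_type, organic_load, initial_ph)")
}

#' @export
format.vfa_treatment <- function(x, ...) {
  sprintf("%s OL%g pH%g", x$sludge_type, x$organic_load, x$initial_ph)
}

#' @export
print.vfa_treatment <- function(x, ...) {
  cat("Treatment:", format(x), "\n")
  invisible(x)
}

# Label used for matching/grouping rows of an observation table.
treatment_label <- function(sludge_type, organic_load, initial_ph) {
  sprintf("%s OL%g pH%g", as.character(sludge_type),
          as.numeric(organic_load), as.numeric(initial_ph))
}

# Evaluate f with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, f) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  f()
}
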