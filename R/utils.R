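# Internal helpers shared across modules.

#' @keywords internal
cs_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cellscatter_error", "error", "condition")))
}

#' Evaluate an expression with a temporarily fixed RNG state
#'
#' Restores the caller's `.Random.seed` on exit so generators are pure
#' functions of `(truth, seed)` without disturbing the session RNG.
#' `seed = NULL` draws from the current RNG stream (used when a caller has
#' already seeded an enclosing block).
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    cs_abort("seed must be a single integer", "cs_validation_error")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Gaussian in (amplitude, center, fwhm) parameterization; sigma = fwhm/2.3548.
# Used by both the WAXS decomposition and the Kratky peak fit.
#' @keywords internal
gaussian_afc <- function(q, amplitude, center, fwhm) {
  amplitude * exp(-4 * log(2) * ((q - center) / fwhm)^2)
}

# Analytic area of gaussian_afc: amplitude * fwhm * sqrt(pi / (4 log 2)).
#' @keywords internal
gaussian_area <- function(amplitude, fwhm) {
  amplitude * fwhm * sqrt(pi / (4 * log(2)))
}

#' @keywords internal
check_window <- function(window, what = "window") {
  if (!is.numeric(window) || length(window) != 2L || any(is.na(window)) ||
      window[1] >= window[2]) {
    cs_abort(sprintf("%s must be an increasing numeric pair", what),
             "cs_validation_error")
  }
  invisible(window)
}
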