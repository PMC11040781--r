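#' Aggregate replicate measurements for one condition
#'
#' Mean and sample standard deviation (n - 1 denominator) of a set of
#' parallel replicate measurements, as used for triplicate error bars. With
#' a single value the sd is undefined and flagged rather than reported as 0.
#'
#' @param values numeric replicate measurements.
#' @param condition condition label.
#' @return An object of class `condition_summary`: `condition`, `n`, `mean`,
#'   `sd`, `sd_defined`.
#' @export
aggregate_replicates <- function(values, condition = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    cs_abort("values must be finite and non-empty", "cs_validation_error")
  }
  n <- length(values)
  structure(list(condition = as.character(condition), n = n,
                 mean = mean(values),
                 sd = if (n >= 2L) stats::sd(values) else NA_real_,
                 sd_defined = n >= 2L,
                 values = values),
            class = "condition_summary")
}

#' Percent change of a treated condition relative to a reference
#'
#' Signed `100 * (mean_treated - mean_reference) / mean_reference`.
#'
#' @param reference,treated [aggregate_replicates()] summaries.
#' @return Percent change (signed).
#' @export
percent_change <- function(reference, treated) {
  stopifnot(inherits(reference, "condition_summary"),
            inherits(treated, "condition_summary"))
  if (reference$mean == 0) {
    cs_abort("reference mean is zero; percent change undefined", "cs_domain_error")
  }
  100 * (treated$mean - reference$mean) / reference$mean
}

#' Two-tailed two-sample t-test
#'
#' Unpaired two-tailed t-test between two replicate groups; Welch's
#' unequal-variance form by default, Student's equal-variance form on
#' request. Degenerate zero-variance inputs follow the conventions: equal
#' constant groups give t = 0, p = 1; unequal constant groups give infinite
#' t and p = 0, flagged.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param variant `"welch"` (default) or `"student"`.
#' @return List with `t`, `p`, `df`, `variant`, `degenerate`.
#' @export
two_tailed_t_test <- function(group_a, group_b,
                              variant = c("welch", "student")) {
  variant <- match.arg(variant)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L) {
    cs_abort("each group needs at least 2 values", "cs_validation_error")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1, df = NA_real_, variant = variant,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = NA_real_,
                variant = variant, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, alternative = "two.sided",
                      var.equal = identical(variant, "student"))
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), variant = variant, degenerate = FALSE)
}

#' Compare a treated condition against a reference
#'
#' Bundles replicate aggregation, percent change and the two-tailed t-test
#' into one comparison record; `significant` is `p <= 0.05`, the threshold
#' used throughout for treatment effects.
#'
#' @param reference_values,treated_values numeric replicate vectors.
#' @param reference_label,treated_label condition labels.
#' @param variant t-test variant, see [two_tailed_t_test()].
#' @param alpha significance threshold (default 0.05).
#' @return An object of class `study_comparison`.
#' @export
compare_conditions <- function(reference_values, treated_values,
                               reference_label = "reference",
                               treated_label = "treated",
                               variant = "welch", alpha = 0.05) {
  ref <- aggregate_replicates(reference_values, reference_label)
  trt <- aggregate_replicates(treated_values, treated_label)
  tt <- two_tailed_t_test(treated_values, reference_values, variant = variant)
  structure(list(reference = ref, treated = trt,
                 percent_change = percent_change(ref, trt),
                 t_statistic = tt$t, p_value = tt$p,
                 significant = tt$p <= alpha, alpha = alpha),
            class = "study_comparison")
}

#' @export
print.study_comparison <- function(x, ...) {
  cat(sprintf("<study_comparison> %s (n=%d, %.4g +/- %.4g) vs %s (n=%d, %.4g +/- %.4g)\n",
              x$treated$condition, x$treated$n, x$treated$mean, x$treated$sd,
              x$reference$condition, x$reference$n, x$reference$mean,
              x$reference$sd))
  cat(sprintf("  percent change %+.2f%%, t = %.3f, two-tailed p = %.4g %s\n",
              x$percent_change, x$t_statistic, x$p_value,
              if (x$significant) "(*)" else ""))
  invisible(x)
}

#' Percent of protein bound in a pull-down assay
#'
#' `(1 - final/initial) * 100`, the fraction of added protein depleted from
#' solution by binding to the insoluble polysaccharide. Values are clamped
#' to [0, 100]; an apparent final concentration above the initial one is
#' flagged via the `"clamped"` attribute rather than reported as negative
#' binding.
#'
#' @param initial_conc,final_conc protein concentrations (same units, e.g.
#'   mg/mL); initial > 0, final >= 0.
#' @return Percent bound in [0, 100], with attribute `clamped`.
#' @export
percent_bound <- function(initial_conc, final_conc) {
  if (!is.finite(initial_conc) || initial_conc <= 0) {
    cs_abort("initial concentration must be > 0", "cs_domain_error")
  }
  if (!is.finite(final_conc) || final_conc < 0) {
    cs_abort("final concentration must be >= 0", "cs_domain_error")
  }
  raw <- (1 - final_conc / initial_conc) * 100
  out <- max(0, min(100, raw))
  attr(out, "clamped") <- raw < 0 || raw > 100
  out
}

#' Fit a linear colorimetric standard curve
#'
#' Ordinary least squares of absorbance on concentration for a dilution
#' series (e.g. glucose standards from 0.01 to 0.3 mg/mL in a
#' reducing-sugar assay). The stored slope and intercept describe the
#' absorbance = slope * concentration + intercept line; [quantify()] inverts
#' it.
#'
#' @param concentrations standard concentrations (mg/mL), >= 3 distinct.
#' @param absorbances measured absorbances, same length.
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `valid_range`.
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  x <- as.numeric(concentrations); y <- as.numeric(absorbances)
  if (length(x) < 3L || length(x) != length(y) || any(!is.finite(c(x, y)))) {
    cs_abort("need >= 3 finite calibration points", "cs_validation_error")
  }
  if (length(unique(x)) < 2L) {
    cs_abort("degenerate calibration: all concentrations identical", "cs_fit_error")
  }
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 valid_range = range(x)),
            class = "standard_curve")
}

#' Quantify a sample from a standard curve
#'
#' Inverts the fitted absorbance line to a concentration; results outside
#' the calibrated concentration range are returned but flagged as
#' extrapolated rather than silently trusted.
#'
#' @param absorbance measured absorbance(s).
#' @param curve a [fit_standard_curve()] result.
#' @return Concentration(s) with attribute `extrapolated` (logical vector).
#' @export
quantify <- function(absorbance, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) cs_abort("flat standard curve", "cs_domain_error")
  conc <- (as.numeric(absorbance) - curve$intercept) / curve$slope
  tol <- 1e-9 * diff(curve$valid_range)  # boundary points are in range
  attr(conc, "extrapolated") <-
    conc < curve$valid_range[1] - tol | conc > curve$valid_range[2] + tol
  conc
}
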