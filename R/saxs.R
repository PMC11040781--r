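#' Fit the SAXS power-law + constant background
#'
#' Models the non-peak SAXS intensity as `A * q^-alpha + c`: the constant
#' `c` is estimated as the median intensity over the high-q window (robust to
#' residual peak tails) and the prefactor `A` is fitted by least squares on
#' the low-q window with the exponent fixed (alpha = 4 for dry samples) or
#' co-fitted when `alpha = "free"`. The two estimates are alternated a few
#' times — c re-estimated on the power-law-corrected intensity, A on the
#' constant-corrected intensity — so that the power-law tail reaching into
#' the high-q window does not inflate the constant.
#'
#' @param profile a SAXS [scattering_profile()].
#' @param alpha fixed positive exponent (default 4) or `"free"`.
#' @param low_q,high_q disjoint fitting windows (1/Angstrom), low below high,
#'   each containing at least 5 points.
#' @return An object of class `saxs_background` with `prefactor`, `exponent`,
#'   `constant`, `low_q_window`, `high_q_window`.
#' @export
fit_saxs_background <- function(profile, alpha = 4,
                                low_q = c(0.010, 0.030),
                                high_q = c(0.25, 0.30)) {
  validate_profile(profile)
  if (profile$modality != "SAXS") {
    cs_abort("fit_saxs_background expects a SAXS profile", "cs_validation_error")
  }
  check_window(low_q, "low_q"); check_window(high_q, "high_q")
  if (low_q[2] >= high_q[1]) {
    cs_abort("low_q and high_q windows must be disjoint, low below high",
             "cs_validation_error")
  }
  in_low <- profile$q >= low_q[1] & profile$q <= low_q[2]
  in_high <- profile$q >= high_q[1] & profile$q <= high_q[2]
  if (sum(in_low) < 5L || sum(in_high) < 5L) {
    cs_abort("each background window must contain at least 5 points",
             "cs_validation_error")
  }
  if (!identical(alpha, "free") && (!is.numeric(alpha) || alpha <= 0)) {
    cs_abort("alpha must be positive or \"free\"", "cs_validation_error")
  }
  ql <- profile$q[in_low]; yl_raw <- profile$intensity[in_low]
  qh <- profile$q[in_high]; yh <- profile$intensity[in_high]
  const <- stats::median(yh)
  A <- 0; a <- if (identical(alpha, "free")) 4 else alpha
  for (pass in 1:4) {
    yl <- yl_raw - const
    if (identical(alpha, "free")) {
      fit <- minpack.lm::nls.lm(
        par = c(A = max(sum(yl * ql^-a) / sum(ql^(-2 * a)), 0), alpha = a),
        lower = c(0, 0.5), upper = c(Inf, 8),
        fn = function(p) yl - p[1] * ql^-p[2])
      A <- fit$par[1]; a <- fit$par[2]
    } else {
      # closed-form least squares for I - c = A q^-alpha on the low-q window
      A <- max(sum(yl * ql^-a) / sum(ql^(-2 * a)), 0)
    }
    new_const <- stats::median(yh - A * qh^-a)
    if (abs(new_const - const) <= 1e-10 * max(abs(const), 1)) { const <- new_const; break }
    const <- new_const
  }
  structure(list(prefactor = unname(A), exponent = unname(a),
                 constant = max(const, 0),
                 low_q_window = low_q, high_q_window = high_q),
            class = "saxs_background")
}

#' Subtract a fitted SAXS background model
#'
#' Returns `I(q) - A * q^-alpha - c` on the profile's own grid. Negative
#' residuals are retained and their fraction recorded in the diagnostics.
#'
#' @param profile a SAXS [scattering_profile()].
#' @param model a [fit_saxs_background()] result.
#' @return A [scattering_profile()] of the background-subtracted intensity.
#' @export
subtract_background <- function(profile, model) {
  validate_profile(profile)
  stopifnot(inherits(model, "saxs_background"))
  out <- profile
  out$intensity <- profile$intensity -
    model$prefactor * profile$q^(-model$exponent) - model$constant
  out$diagnostics$frac_negative <- mean(out$intensity < 0)
  out
}

#' Kratky transform
#'
#' Multiplies the intensity pointwise by q^2, giving the Kratky
#' representation (q^2 I vs q) that turns the fibril-packing correlation into
#' a localized peak. Uncertainties are scaled by q^2 as well.
#'
#' @param profile a [scattering_profile()].
#' @return An object of class `kratky_curve` with `q`, `y` (= q^2 I), `sigma`.
#' @export
kratky_transform <- function(profile) {
  validate_profile(profile)
  structure(list(q = profile$q, y = profile$q^2 * profile$intensity,
                 sigma = if (is.null(profile$sigma)) NULL
                         else profile$sigma * profile$q^2),
            class = "kratky_curve")
}

#' Center-to-center microfibril distance from the Kratky peak position
#'
#' Bragg conversion of the packing-peak position to the average
#' center-to-center distance between neighboring microfibrils,
#' d_cc = 2*pi/q_peak (Angstrom).
#'
#' @param q_peak Kratky peak position (1/Angstrom), > 0.
#' @return d_cc in Angstrom.
#' @export
center_to_center_distance <- function(q_peak) {
  if (any(!is.finite(q_peak)) || any(q_peak <= 0)) {
    cs_abort("q_peak must be > 0", "cs_domain_error")
  }
  2 * pi / q_peak
}

#' Fit a Gaussian to the Kratky packing peak
#'
#' Locates the peak as the global argmax of a 5-point moving-average smoothed
#' copy of the curve inside the analysis window (smoothing is used for
#' initialization only), then fits a Gaussian (amplitude, center, fwhm) to
#' the raw curve over `center +/- max(2 * fwhm_guess, 0.05)`. A monotone
#' curve (argmax on the window edge) raises a no-peak error; multiple equal
#' maxima resolve to the lowest-q one and are flagged `ambiguous`; a fitted
#' center at the local window edge is flagged `at_edge`.
#'
#' @param kratky a [kratky_transform()] result.
#' @param window analysis window in q (1/Angstrom).
#' @param init_center optional center guess overriding the argmax.
#' @return An object of class `kratky_peak`: `center`, `fwhm`, `amplitude`,
#'   `d_cc` (Angstrom), `flags`, `residual_rms`.
#' @export
fit_kratky_peak <- function(kratky, window = c(0.05, 0.25), init_center = NULL) {
  stopifnot(inherits(kratky, "kratky_curve"))
  check_window(window)
  sel <- which(kratky$q >= window[1] & kratky$q <= window[2])
  if (length(sel) < 7L) {
    cs_abort("analysis window contains too few points", "cs_validation_error")
  }
  q <- kratky$q[sel]; y <- kratky$y[sel]
  sm <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  interior <- which(!is.na(sm))
  flags <- character()

  if (is.null(init_center)) {
    peak_val <- max(sm[interior])
    cand <- interior[sm[interior] >= peak_val - 1e-12 * max(abs(peak_val), 1)]
    idx <- cand[1]  # lowest-q maximum wins on ties
    if (length(cand) > 1L && any(diff(cand) > 1L)) flags <- c(flags, "ambiguous")
    if (idx <= min(interior) || idx >= max(interior) ||
        sm[idx] <= sm[min(interior)] || sm[idx] <= sm[max(interior)]) {
      cs_abort("no interior maximum in the Kratky analysis window (monotone curve)",
               "cs_no_peak_error")
    }
    center0 <- q[idx]
  } else {
    center0 <- init_center
    idx <- which.min(abs(q - center0))
  }
  # FWHM guess from half-max crossings of the smoothed curve
  half <- sm[idx] / 2
  left <- idx; while (left > min(interior) && sm[left] > half) left <- left - 1
  right <- idx; while (right < max(interior) && sm[right] > half) right <- right + 1
  fwhm0 <- max(q[right] - q[left], diff(range(q)) / 20)

  halfwin <- max(2 * fwhm0, 0.05)
  fsel <- q >= center0 - halfwin & q <= center0 + halfwin
  qf <- q[fsel]; yf <- y[fsel]
  fit <- minpack.lm::nls.lm(
    par = c(max(yf), center0, fwhm0),
    lower = c(0, max(center0 - halfwin, window[1]), 1e-4),
    upper = c(Inf, min(center0 + halfwin, window[2]), diff(window)),
    fn = function(p) yf - gaussian_afc(qf, p[1], p[2], p[3]),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!(fit$info %in% 1:4)) {
    cs_abort(sprintf("Kratky peak fit did not converge (info=%d): %s",
                     fit$info, fit$message), "cs_fit_error")
  }
  center <- fit$par[2]
  if (abs(center - min(qf)) < 1e-9 || abs(center - max(qf)) < 1e-9) {
    flags <- c(flags, "at_edge")
  }
  structure(list(center = center, fwhm = fit$par[3], amplitude = fit$par[1],
                 d_cc = center_to_center_distance(center),
                 flags = flags,
                 residual_rms = sqrt(mean(fit$fvec^2))),
            class = "kratky_peak")
}

#' Default SAXS analysis settings
#'
#' Windows within typical pinhole SAXS coverage (~0.01-0.3 1/Angstrom):
#' power-law window 0.010-0.030, constant window 0.25-0.30, peak analysis
#' window 0.05-0.25 (all 1/Angstrom); exponent fixed at 4 (dry samples).
#' @param alpha power-law exponent or `"free"`.
#' @param low_q,high_q background windows (1/Angstrom).
#' @param peak_window Kratky analysis window (1/Angstrom).
#' @return A named list of settings for [analyze_saxs()].
#' @export
saxs_config <- function(alpha = 4, low_q = c(0.010, 0.030),
                        high_q = c(0.25, 0.30), peak_window = c(0.05, 0.25)) {
  list(alpha = alpha, low_q = low_q, high_q = high_q, peak_window = peak_window)
}

#' Full SAXS fibril-spacing analysis
#'
#' Composition of the four SAXS stages: background fit, subtraction, Kratky
#' transform, Gaussian peak fit, and Bragg conversion to the center-to-center
#' microfibril distance. Intermediates are retained for inspection; a failure
#' in any stage is re-raised with the stage name.
#'
#' @param profile a SAXS [scattering_profile()].
#' @param config settings from [saxs_config()].
#' @return An object of class `saxs_result`: `background`, `subtracted`,
#'   `kratky`, `peak`, `d_cc` (Angstrom), `d_cc_nm`, `diagnostics`.
#' @export
analyze_saxs <- function(profile, config = saxs_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, cellscatter_error = function(e) {
      cs_abort(sprintf("stage %s: %s", name, conditionMessage(e)), class(e)[1])
    })
  }
  bg <- stage("background_fit",
              fit_saxs_background(profile, alpha = config$alpha,
                                  low_q = config$low_q, high_q = config$high_q))
  sub <- stage("background_subtraction", subtract_background(profile, bg))
  kr <- stage("kratky_transform", kratky_transform(sub))
  pk <- stage("peak_fit", fit_kratky_peak(kr, window = config$peak_window))
  structure(list(background = bg, subtracted = sub, kratky = kr, peak = pk,
                 d_cc = pk$d_cc, d_cc_nm = pk$d_cc / 10,
                 diagnostics = list(
                   residual_rms = pk$residual_rms,
                   frac_negative = sub$diagnostics$frac_negative,
                   flags = pk$flags)),
            class = "saxs_result")
}

#' @export
print.saxs_result <- function(x, ...) {
  cat("<saxs_result>\n")
  cat(sprintf("  background: A=%.4g q^-%.3g + %.4g\n", x$background$prefactor,
              x$background$exponent, x$background$constant))
  cat(sprintf("  Kratky peak: q=%.5g 1/A, fwhm=%.4g, amplitude=%.4g\n",
              x$peak$center, x$peak$fwhm, x$peak$amplitude))
  cat(sprintf("  center-to-center distance: %.2f A (%.3f nm)\n",
              x$d_cc, x$d_cc_nm))
  if (length(x$diagnostics$flags)) {
    cat("  flags:", paste(x$diagnostics$flags, collapse = ", "), "\n")
  }
  invisible(x)
}
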