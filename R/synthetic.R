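# Forward simulators with retained ground truth. They emulate the analysis
# model exactly (crystalline + amorphous Gaussians for WAXS; power law +
# constant + Kratky-space Gaussian for SAXS), not a physical paracrystalline
# lattice: they exist to validate parameter recovery, not cellulose physics.

#' Ground truth for a synthetic WAXS measurement
#'
#' Five-Gaussian cellulose I-beta model: four crystalline reflections plus a
#' broad amorphous halo. The amorphous amplitude is solved analytically so
#' that the area-based crystallinity index over `window` equals `ci`; the
#' resulting truth stores the exact per-peak d-spacings, Scherrer sizes and
#' CI alongside the generating parameters.
#'
#' @param centers,fwhm,amplitude crystalline peak parameters (named by
#'   reflection), 1/Angstrom and intensity units.
#' @param amorphous_center,amorphous_fwhm amorphous Gaussian parameters.
#' @param ci target crystallinity index over `window` (0 < ci <= 1).
#' @param window q window used for the CI area ratio (1/Angstrom).
#' @param noise multiplicative Gaussian noise fraction (0 = noiseless).
#' @param q_grid `(min, max, n)` grid specification (1/Angstrom).
#' @return An object of class `waxs_truth`.
#' @export
waxs_truth <- function(centers = c("1-10" = 1.05, "110" = 1.17,
                                   "102" = 1.46, "200" = 1.60),
                       fwhm = c(0.10, 0.10, 0.12, 0.13),
                       amplitude = c(0.35, 0.40, 0.25, 1.00),
                       amorphous_center = 1.35, amorphous_fwhm = 0.60,
                       ci = 0.55, window = c(0.7, 2.0),
                       noise = 0.01, q_grid = c(0.1, 3.0, 400)) {
  stopifnot(length(centers) == 4L, length(fwhm) == 4L, length(amplitude) == 4L,
            ci > 0, ci <= 1, noise >= 0)
  check_window(window)
  cryst_area <- sum(gaussian_area(amplitude, fwhm))
  # fraction of the amorphous Gaussian's area falling inside the CI window
  s <- amorphous_fwhm / (2 * sqrt(2 * log(2)))
  frac_in <- stats::pnorm(window[2], amorphous_center, s) -
             stats::pnorm(window[1], amorphous_center, s)
  am_area_in_window <- cryst_area * (1 - ci) / ci
  am_amplitude <- am_area_in_window / frac_in / gaussian_area(1, amorphous_fwhm)
  peaks <- data.frame(
    label = c(names(centers), "amorphous"),
    center = c(unname(centers), amorphous_center),
    fwhm = c(unname(fwhm), amorphous_fwhm),
    amplitude = c(unname(amplitude), am_amplitude),
    stringsAsFactors = FALSE)
  structure(list(modality = "WAXS", peaks = peaks,
                 d_spacings = stats::setNames(2 * pi / unname(centers),
                                              names(centers)),
                 crystal_sizes = stats::setNames(2 * pi / unname(fwhm),
                                                 names(centers)),
                 ci = ci, window = window,
                 noise = noise, q_grid = q_grid),
            class = "waxs_truth")
}

#' Ground truth for a synthetic SAXS measurement
#'
#' `I(q) = A q^-alpha + c + G(q)/q^2` where G is a Gaussian in Kratky space
#' centered on the fibril-packing peak, so the Kratky transform of the peak
#' term is exactly Gaussian. Defaults place the packing peak at
#' d_cc = 40 Angstrom (q_peak = 2*pi/40, within the 3-5 nm microfibril
#' scale) over a dry-sample q^-4 background.
#'
#' @param d_cc center-to-center distance truth (Angstrom).
#' @param peak_fwhm,peak_amplitude Kratky-space Gaussian width (1/Angstrom)
#'   and height (intensity * Angstrom^-2).
#' @param prefactor,alpha,constant background parameters.
#' @param noise multiplicative Gaussian noise fraction.
#' @param q_grid `(min, max, n)` grid specification (1/Angstrom).
#' @param peak_shape `"kratky"` (Gaussian in q^2 I, the analysis model) or
#'   `"real"` (Gaussian in I, to probe model mismatch).
#' @return An object of class `saxs_truth`.
#' @export
saxs_truth <- function(d_cc = 40, peak_fwhm = 0.05, peak_amplitude = 0.01,
                       prefactor = 2e-5, alpha = 4, constant = 0.05,
                       noise = 0.01, q_grid = c(0.01, 0.3, 300),
                       peak_shape = c("kratky", "real")) {
  stopifnot(d_cc > 0, peak_fwhm > 0, peak_amplitude >= 0,
            prefactor >= 0, constant >= 0, alpha > 0, noise >= 0)
  structure(list(modality = "SAXS", d_cc = d_cc, q_peak = 2 * pi / d_cc,
                 peak_fwhm = peak_fwhm, peak_amplitude = peak_amplitude,
                 prefactor = prefactor, alpha = alpha, constant = constant,
                 noise = noise, q_grid = q_grid,
                 peak_shape = match.arg(peak_shape)),
            class = "saxs_truth")
}

#' @keywords internal
truth_grid <- function(truth) {
  seq(truth$q_grid[1], truth$q_grid[2], length.out = truth$q_grid[3])
}

#' @keywords internal
apply_noise <- function(y, noise) {
  if (noise == 0) return(y)
  y * (1 + noise * stats::rnorm(length(y)))
}

#' Generate a synthetic WAXS profile
#'
#' Evaluates the five-Gaussian truth model on the grid and applies
#' multiplicative Gaussian noise. Deterministic per `(truth, seed)`.
#'
#' @param truth a [waxs_truth()].
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @param ... labels passed to [scattering_profile()].
#' @return List with `profile` and the `truth` it was generated from.
#' @export
generate_waxs_profile <- function(truth, seed = NULL, ...) {
  stopifnot(inherits(truth, "waxs_truth"))
  q <- truth_grid(truth)
  if (any(truth$peaks$center < min(q)) || any(truth$peaks$center > max(q))) {
    cs_abort("truth peak centers fall outside the q grid", "cs_validation_error")
  }
  y <- rowSums(vapply(seq_len(nrow(truth$peaks)), function(k) {
    gaussian_afc(q, truth$peaks$amplitude[k], truth$peaks$center[k],
                 truth$peaks$fwhm[k])
  }, numeric(length(q))))
  y <- with_seed(seed, apply_noise(y, truth$noise))
  list(profile = scattering_profile(q, y, modality = "WAXS",
                                    normalized = TRUE, ...),
       truth = truth)
}

#' @keywords internal
saxs_model_intensity <- function(truth, q) {
  peak <- gaussian_afc(q, truth$peak_amplitude, truth$q_peak, truth$peak_fwhm)
  if (identical(truth$peak_shape, "kratky")) peak <- peak / q^2
  truth$prefactor * q^(-truth$alpha) + truth$constant + peak
}

#' Generate a synthetic SAXS profile
#'
#' Evaluates the background-plus-packing-peak truth model on the grid and
#' applies multiplicative Gaussian noise. Deterministic per `(truth, seed)`.
#'
#' @inheritParams generate_waxs_profile
#' @param truth a [saxs_truth()].
#' @return List with `profile` and `truth`.
#' @export
generate_saxs_profile <- function(truth, seed = NULL, ...) {
  stopifnot(inherits(truth, "saxs_truth"))
  q <- truth_grid(truth)
  if (truth$q_peak < min(q) || truth$q_peak > max(q)) {
    cs_abort("truth q_peak falls outside the q grid", "cs_validation_error")
  }
  y <- with_seed(seed, apply_noise(saxs_model_intensity(truth, q), truth$noise))
  list(profile = scattering_profile(q, y, modality = "SAXS",
                                    normalized = TRUE, ...),
       truth = truth)
}

#' Render a 1D profile as an isotropic 2D detector image
#'
#' Every pixel receives the profile intensity linearly interpolated at its
#' own q (same geometry convention as [azimuthal_integrate()]); expected
#' counts are `intensity * exposure * flux_factor`, optionally Poisson
#' sampled. The profile must cover the detector's full q range.
#'
#' @param profile a [scattering_profile()] (per-second units).
#' @param geometry a [detector_geometry()].
#' @param shape image dimensions (rows, cols).
#' @param seed integer seed for the Poisson draw.
#' @param poisson sample counts from a Poisson law instead of returning the
#'   noiseless expectation.
#' @return A [detector_image()] of raw counts.
#' @export
generate_detector_image <- function(profile, geometry, shape = c(64, 64),
                                    seed = NULL, poisson = FALSE) {
  validate_profile(profile)
  stopifnot(inherits(geometry, "detector_geometry"))
  qmap <- pixel_q_map(shape, geometry)
  if (min(qmap) < min(profile$q) || max(qmap) > max(profile$q)) {
    cs_abort(sprintf(
      "profile q range [%.4g, %.4g] does not cover detector range [%.4g, %.4g]",
      min(profile$q), max(profile$q), min(qmap), max(qmap)),
      "cs_validation_error")
  }
  intens <- stats::approx(profile$q, profile$intensity, xout = as.numeric(qmap))$y
  expected <- matrix(intens, shape[1], shape[2]) *
    geometry$exposure * geometry$flux_factor
  counts <- if (poisson) {
    with_seed(seed, matrix(stats::rpois(length(expected), expected),
                           shape[1], shape[2]))
  } else expected
  detector_image(counts, geometry)
}

#' Simulate a two-condition treatment study
#'
#' Emulates the reference-versus-treatment design used for expansin-treated
#' pulp: `n_replicates` reference samples drawn from `saxs` and the same
#' number of treated samples whose packing peak is moved to lower q by
#' dividing `q_peak` by `1 + spacing_increase` (a pure interfibrillar-spacing
#' effect). Per-replicate truths are jittered multiplicatively on the peak
#' position and intensity scale. When a `waxs` truth is supplied the same
#' (spacing-only) treatment leaves the WAXS truth identical in both
#' conditions; only its intensity scale is jittered.
#'
#' @param saxs a [saxs_truth()] for the reference condition.
#' @param spacing_increase fractional increase in d_cc for the treated
#'   condition (e.g. 0.22 for +22%).
#' @param n_replicates replicates per condition (>= 3).
#' @param replicate_jitter fractional between-replicate jitter, in [0, 0.2).
#' @param seed integer seed governing all jitter and noise.
#' @param waxs optional [waxs_truth()] measured in parallel.
#' @param conditions labels for (reference, treated).
#' @return An object of class `treatment_study`: `profiles` (list with
#'   condition/replicate labels), `truth` (tidy per-replicate truth table),
#'   `seed`.
#' @export
generate_treatment_study <- function(saxs, spacing_increase = 0.22,
                                     n_replicates = 3, replicate_jitter = 0.01,
                                     seed = 1, waxs = NULL,
                                     conditions = c("reference", "treated")) {
  stopifnot(inherits(saxs, "saxs_truth"))
  if (n_replicates < 3L) {
    cs_abort("need at least three parallel samples per condition",
             "cs_validation_error")
  }
  if (spacing_increase < 0 || replicate_jitter < 0 || replicate_jitter >= 0.2) {
    cs_abort("spacing_increase must be >= 0 and jitter in [0, 0.2)",
             "cs_validation_error")
  }
  with_seed(seed, {
    profiles <- list()
    truth_rows <- list()
    for (cond_i in 1:2) {
      cond <- conditions[cond_i]
      base_qpeak <- if (cond_i == 2L) saxs$q_peak / (1 + spacing_increase)
                    else saxs$q_peak
      for (rep_i in seq_len(n_replicates)) {
        tr <- saxs
        tr$q_peak <- base_qpeak * (1 + replicate_jitter * stats::rnorm(1))
        tr$d_cc <- 2 * pi / tr$q_peak
        tr$peak_amplitude <- saxs$peak_amplitude *
          (1 + replicate_jitter * stats::rnorm(1))
        gen <- generate_saxs_profile(tr, seed = NULL, sample_id =
                 sprintf("%s_saxs_%d", cond, rep_i),
                 condition = cond, replicate = as.character(rep_i))
        profiles[[length(profiles) + 1L]] <- gen$profile
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          condition = cond, replicate = rep_i, modality = "SAXS",
          q_peak_truth = tr$q_peak, d_cc_truth = tr$d_cc,
          ci_truth = NA_real_, stringsAsFactors = FALSE)
        if (!is.null(waxs)) {
          tw <- waxs
          tw$peaks$amplitude <- waxs$peaks$amplitude *
            (1 + replicate_jitter * stats::rnorm(1))
          genw <- generate_waxs_profile(tw, seed = NULL, sample_id =
                    sprintf("%s_waxs_%d", cond, rep_i),
                    condition = cond, replicate = as.character(rep_i))
          profiles[[length(profiles) + 1L]] <- genw$profile
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            condition = cond, replicate = rep_i, modality = "WAXS",
            q_peak_truth = NA_real_, d_cc_truth = NA_real_,
            ci_truth = tw$ci, stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(profiles = profiles,
                   truth = do.call(rbind, truth_rows),
                   seed = seed,
                   spacing_increase = spacing_increase,
                   conditions = conditions),
              class = "treatment_study")
  })
}
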