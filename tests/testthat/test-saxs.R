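make_saxs <- function(y, q = seq(0.01, 0.3, length.out = 300)) {
  scattering_profile(q, y, modality = "SAXS", normalized = TRUE)
}

test_that("pure power-law backgrounds are recovered essentially exactly", {
  q <- seq(0.01, 0.3, length.out = 300)
  bg <- fit_saxs_background(make_saxs(2.5 * q^-4))
  expect_equal(bg$prefactor, 2.5, tolerance = 1e-6)
  expect_lt(bg$constant, 1e-6)
  expect_equal(bg$exponent, 4)

  bg2 <- fit_saxs_background(make_saxs(1 * q^-4 + 0.05))
  expect_equal(bg2$prefactor, 1, tolerance = 0.01)
  expect_equal(bg2$constant, 0.05, tolerance = 0.01 * 0.05)

  free <- fit_saxs_background(make_saxs(2 * q^-3.5 + 0.02), alpha = "free")
  expect_equal(free$exponent, 3.5, tolerance = 0.02)
  expect_equal(free$prefactor, 2, tolerance = 0.05)
})

test_that("background window preconditions are enforced", {
  q <- seq(0.05, 0.3, length.out = 100)
  p <- scattering_profile(q, q^-4, modality = "SAXS")
  expect_error(fit_saxs_background(p, low_q = c(0.01, 0.03)),
               class = "cs_validation_error")   # empty low-q window
  expect_error(fit_saxs_background(p, low_q = c(0.05, 0.28),
                                   high_q = c(0.2, 0.3)),
               class = "cs_validation_error")   # overlapping windows
  waxs <- scattering_profile(seq(0.7, 2, length.out = 50), rep(1, 50),
                             modality = "WAXS")
  expect_error(fit_saxs_background(waxs), class = "cs_validation_error")
})

test_that("background subtraction is consistent and identity-preserving", {
  q <- seq(0.01, 0.3, length.out = 300)
  pure <- make_saxs(3 * q^-4 + 0.1)
  model <- fit_saxs_background(pure)
  resid <- subtract_background(pure, model)
  expect_lt(abs(mean(resid$intensity)) / mean(pure$intensity), 1e-6)

  truth <- saxs_truth(noise = 0)
  gen <- generate_saxs_profile(truth, seed = 1)
  injected <- gaussian_afc(q, truth$peak_amplitude, truth$q_peak,
                           truth$peak_fwhm) / q^2
  sub <- subtract_background(gen$profile,
                             fit_saxs_background(gen$profile))
  peak_region <- q > 0.1 & q < 0.22
  expect_lt(max(abs(sub$intensity[peak_region] - injected[peak_region])) /
              max(injected), 0.01)

  ident <- structure(list(prefactor = 0, exponent = 4, constant = 0,
                          low_q_window = c(0.01, 0.03),
                          high_q_window = c(0.25, 0.3)),
                     class = "saxs_background")
  expect_equal(subtract_background(pure, ident)$intensity, pure$intensity)
})

test_that("Kratky transform obeys its algebraic identities", {
  q <- seq(0.01, 0.3, length.out = 100)
  expect_equal(kratky_transform(make_saxs(1 / q^2, q))$y, rep(1, 100))
  expect_equal(kratky_transform(make_saxs(rep(0, 100), q))$y, rep(0, 100))
  p <- scattering_profile(q, 1 / q, sigma = rep(2, 100), modality = "SAXS")
  expect_equal(kratky_transform(p)$sigma, 2 * q^2)

  # peak generated as Gaussian in Kratky space reappears at its center
  truth <- saxs_truth(d_cc = 2 * pi / 0.157, prefactor = 0, constant = 0,
                      noise = 0)
  kr <- kratky_transform(generate_saxs_profile(truth, seed = 1)$profile)
  dq <- diff(kr$q[1:2])  # argmax can only be located to grid resolution
  expect_lt(abs(kr$q[which.max(kr$y)] - 0.157), dq)
})

test_that("Kratky peak fitting recovers, tie-breaks and fails as specified", {
  q <- seq(0.05, 0.25, length.out = 300)
  kr <- structure(list(q = q, y = gaussian_afc(q, 1, 0.157, 0.06),
                       sigma = NULL), class = "kratky_curve")
  pk <- fit_kratky_peak(kr)
  expect_equal(pk$center, 0.157, tolerance = 1e-4 * 0.157)
  expect_equal(pk$fwhm, 0.06, tolerance = 1e-4)
  expect_equal(pk$d_cc * pk$center, 2 * pi)

  # two equal maxima: the lower-q one wins, flagged ambiguous
  twin <- structure(list(q = q,
                         y = gaussian_afc(q, 1, 0.11, 0.02) +
                             gaussian_afc(q, 1, 0.19, 0.02),
                         sigma = NULL), class = "kratky_curve")
  pt <- fit_kratky_peak(twin)
  expect_true("ambiguous" %in% pt$flags)
  expect_equal(pt$center, 0.11, tolerance = 0.005)

  mono <- structure(list(q = q, y = rev(sort(runif(300))), sigma = NULL),
                    class = "kratky_curve")
  expect_error(fit_kratky_peak(mono), class = "cs_no_peak_error")
  rising <- structure(list(q = q, y = q^2, sigma = NULL),
                      class = "kratky_curve")
  expect_error(fit_kratky_peak(rising), class = "cs_no_peak_error")
})

test_that("center-to-center conversion matches hand values", {
  expect_equal(center_to_center_distance(0.157), 40.02, tolerance = 1e-4)
  expect_equal(center_to_center_distance(2 * pi), 1.0)
  expect_equal(center_to_center_distance(0.1), 62.83185, tolerance = 1e-6)
  expect_error(center_to_center_distance(0), class = "cs_domain_error")
})

test_that("full SAXS analysis inverts the generator", {
  noiseless <- analyze_saxs(
    generate_saxs_profile(saxs_truth(noise = 0), seed = 1)$profile)
  expect_lt(abs(noiseless$d_cc / 40 - 1), 0.001)
  expect_equal(noiseless$d_cc_nm, noiseless$d_cc / 10)
  expect_equal(noiseless$peak$d_cc * noiseless$peak$center, 2 * pi)

  noisy <- analyze_saxs(
    generate_saxs_profile(saxs_truth(noise = 0.01), seed = 2)$profile)
  expect_lt(abs(noisy$d_cc / 40 - 1), 0.02)

  bg_only <- saxs_truth(peak_amplitude = 0, noise = 0)
  expect_error(analyze_saxs(generate_saxs_profile(bg_only, seed = 1)$profile),
               "peak_fit", class = "cs_no_peak_error")
})

test_that("q_peak and d_cc are intensity-scale invariant and monotone in truth", {
  base <- generate_saxs_profile(saxs_truth(noise = 0), seed = 1)$profile
  r1 <- analyze_saxs(base)
  scaled <- base; scaled$intensity <- scaled$intensity * 41.5
  r2 <- analyze_saxs(scaled)
  expect_equal(r2$peak$center, r1$peak$center, tolerance = 1e-9)
  expect_equal(r2$d_cc, r1$d_cc, tolerance = 1e-9)

  # increasing truth d_cc by f shifts q_peak by 1/f and d_cc by f
  f <- 1.22
  shifted <- analyze_saxs(
    generate_saxs_profile(saxs_truth(d_cc = 40 * f, noise = 0), seed = 1)$profile)
  expect_equal(shifted$peak$center, r1$peak$center / f, tolerance = 1e-3)
  expect_equal(shifted$d_cc, r1$d_cc * f, tolerance = 1e-3 * 40 * f)
})
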