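test_that("Bragg and Scherrer conversions match hand-evaluated values", {
  expect_equal(bragg_d_spacing(2 * pi), 1.0)
  expect_equal(bragg_d_spacing(0.1), 62.83185, tolerance = 1e-6)
  expect_equal(bragg_d_spacing(0.1) / 10, 6.283185, tolerance = 1e-6) # ~6 nm
  expect_equal(bragg_d_spacing(1.60), 3.926991, tolerance = 1e-6)
  expect_equal(scherrer_crystal_size(2 * pi), 1.0)
  expect_equal(scherrer_crystal_size(0.2), 31.41593, tolerance = 1e-6)
  fw <- c(0.01, 0.2, 1.3, 5)
  expect_equal(scherrer_crystal_size(fw) * fw, rep(2 * pi, 4))
  expect_error(bragg_d_spacing(0), class = "cs_domain_error")
  expect_error(bragg_d_spacing(-1), class = "cs_domain_error")
  expect_error(scherrer_crystal_size(0), class = "cs_domain_error")
})

test_that("noiseless five-Gaussian profiles are recovered to 1e-4 relative", {
  truth <- waxs_truth(noise = 0)
  prof <- generate_waxs_profile(truth, seed = 1)$profile
  fit <- fit_waxs_profile(prof)
  expect_equal(fit$peaks$center, truth$peaks$center, tolerance = 1e-4)
  expect_equal(fit$peaks$fwhm, truth$peaks$fwhm, tolerance = 1e-4)
  expect_equal(fit$peaks$amplitude, truth$peaks$amplitude, tolerance = 1e-4)
  expect_equal(unname(fit$d_spacings), unname(truth$d_spacings),
               tolerance = 1e-4)
  # Gaussian area identity: area = amplitude * (fwhm/2.3548) * sqrt(2*pi)
  expect_equal(fit$peaks$area,
               fit$peaks$amplitude * (fit$peaks$fwhm / 2.3548) * sqrt(2 * pi),
               tolerance = 1e-4)
})

test_that("1% noise keeps centers within 0.5% and widths within 5%", {
  truth <- waxs_truth(noise = 0.01)
  fit <- fit_waxs_profile(generate_waxs_profile(truth, seed = 7)$profile)
  expect_lt(max(abs(fit$peaks$center[1:4] / truth$peaks$center[1:4] - 1)), 0.005)
  expect_lt(max(abs(fit$peaks$fwhm[1:4] / truth$peaks$fwhm[1:4] - 1)), 0.05)
})

test_that("degenerate WAXS inputs raise fit or validation errors", {
  q <- seq(0.1, 3, length.out = 200)
  flat <- scattering_profile(q, rep(0, 200), modality = "WAXS")
  expect_error(fit_waxs_profile(flat), class = "cs_fit_error")
  saxs <- scattering_profile(seq(0.01, 0.3, length.out = 50),
                             rep(1, 50), modality = "SAXS")
  expect_error(fit_waxs_profile(saxs), class = "cs_validation_error")
  expect_error(fit_waxs_profile(generate_waxs_profile(waxs_truth(noise = 0))$profile,
                                window = c(0.7, 5)),
               class = "cs_validation_error")
})

test_that("crystallinity index covers the pure, balanced and 0.60 cases", {
  # no amorphous contribution -> CI = 1
  pure <- waxs_truth(ci = 1 - 1e-12, noise = 0)
  pure$peaks$amplitude[5] <- 0
  fit <- fit_waxs_profile(generate_waxs_profile(pure, seed = 1)$profile)
  expect_equal(fit$crystallinity_index, 1.0, tolerance = 1e-3)

  half <- waxs_truth(ci = 0.5, noise = 0)
  fit_half <- fit_waxs_profile(generate_waxs_profile(half, seed = 1)$profile)
  expect_equal(fit_half$crystallinity_index, 0.5, tolerance = 1e-2)

  t60 <- waxs_truth(ci = 0.60, noise = 0.01)
  fit60 <- fit_waxs_profile(generate_waxs_profile(t60, seed = 3)$profile)
  expect_lt(abs(fit60$crystallinity_index - 0.60), 0.05)
  expect_gte(fit60$crystallinity_index, 0)
  expect_lte(fit60$crystallinity_index, 1)
})

test_that("fits are scale invariant and q-shift covariant", {
  truth <- waxs_truth(noise = 0)
  prof <- generate_waxs_profile(truth, seed = 1)$profile
  base <- fit_waxs_profile(prof)
  scaled <- prof
  scaled$intensity <- scaled$intensity * 137
  fs <- fit_waxs_profile(scaled)
  expect_equal(fs$peaks$center, base$peaks$center, tolerance = 1e-6)
  expect_equal(fs$peaks$fwhm, base$peaks$fwhm, tolerance = 1e-6)
  expect_equal(fs$crystallinity_index, base$crystallinity_index,
               tolerance = 1e-6)
  expect_equal(fs$peaks$area, 137 * base$peaks$area, tolerance = 1e-6)

  delta <- 0.05
  shifted_truth <- truth
  shifted_truth$peaks$center <- truth$peaks$center + delta
  shifted <- generate_waxs_profile(shifted_truth, seed = 1)$profile
  fsh <- fit_waxs_profile(shifted)
  expect_equal(fsh$peaks$center, base$peaks$center + delta, tolerance = 1e-4)
  expect_equal(unname(fsh$d_spacings),
               2 * pi / (truth$peaks$center[1:4] + delta), tolerance = 1e-4)
})

test_that("CI stays in [0,1] and d errors stay small across noisy replicates", {
  truth <- waxs_truth(noise = 0.01)
  errs <- vapply(1:20, function(s) {
    fit <- fit_waxs_profile(generate_waxs_profile(truth, seed = s)$profile)
    expect_gte(fit$crystallinity_index, 0)
    expect_lte(fit$crystallinity_index, 1)
    c(d = max(abs(fit$d_spacings / truth$d_spacings - 1)),
      ci = abs(fit$crystallinity_index - truth$ci))
  }, c(d = 0, ci = 0))
  expect_lt(median(errs["d", ]), 0.005)
  expect_lt(median(errs["ci", ]), 0.05)
})
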