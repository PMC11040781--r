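test_that("profile files round-trip with labels and full precision", {
  q <- seq(0.02, 0.3, length.out = 100)
  set.seed(42)
  p <- scattering_profile(q, 1 / q^3 + rnorm(100, 0, 1e-4),
                          sigma = runif(100, 0, 0.01),
                          modality = "SAXS", sample_id = "s1",
                          condition = "reference", replicate = "2")
  f <- withr::local_tempfile(fileext = ".dat")
  write_profile(p, f)
  r <- read_profile(f)
  expect_identical(r$q, p$q)
  expect_identical(r$intensity, p$intensity)
  expect_identical(r$sigma, p$sigma)
  expect_identical(r$modality, "SAXS")
  expect_identical(r$sample_id, "s1")
  expect_identical(r$condition, "reference")
  expect_identical(r$replicate, "2")

  p2 <- scattering_profile(q, 1 / q^3, modality = "SAXS")
  f2 <- withr::local_tempfile(fileext = ".dat")
  write_profile(p2, f2)
  body <- grep("^#", readLines(f2), value = TRUE, invert = TRUE)
  expect_length(strsplit(body[1], " ")[[1]], 2L)  # no sigma -> two columns
  expect_null(read_profile(f2)$sigma)
})

test_that("reading sorts descending q and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".dat")
  q <- seq(1.0, 0.1, length.out = 20)
  writeLines(sprintf("%.17g,%.17g", q, q^2), f)
  p <- read_profile(f, modality = "WAXS")
  expect_true(all(diff(p$q) > 0))
  expect_equal(p$intensity, p$q^2)  # intensities co-permuted with q

  writeLines(c("0.1 1.0", "0.2 oops", "0.3 3.0",
               rep("0.4 1", 0)), f)
  expect_error(read_profile(f), "data line 2", class = "cs_parse_error")

  writeLines(sprintf("%g %g", c(0.1, 0.2, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
                     1:8), f)
  expect_error(read_profile(f), class = "cs_validation_error")
})

test_that("profile invariants are enforced", {
  q <- seq(0.1, 1, length.out = 10)
  expect_error(scattering_profile(q[1:5], q[1:5]), class = "cs_validation_error")
  expect_error(scattering_profile(-q, q), class = "cs_validation_error")
  expect_error(scattering_profile(q, q, sigma = rep(-1, 10)),
               class = "cs_validation_error")
  expect_error(write_profile(scattering_profile(q, q, modality = "WAXS"),
                             "/nonexistent-dir-zz/x.dat"),
               class = "cs_io_error")
})

test_that("exposure/flux normalization is idempotence-guarded", {
  geom_saxs <- detector_geometry(600, 0.5, c(32, 32), exposure_s = 1000,
                                 flux_factor = 4.5)
  q <- seq(0.02, 0.3, length.out = 50)
  p <- scattering_profile(q, rep(9000, 50), modality = "SAXS")
  n1 <- normalize_exposure(p, geom_saxs)
  expect_equal(n1$intensity, rep(2.0, 50))          # 9000 / (1000 * 4.5)
  expect_error(normalize_exposure(n1, geom_saxs), class = "cs_state_error")

  geom_waxs <- detector_geometry(55, 0.5, c(32, 32), exposure_s = 2400,
                                 flux_factor = 1)
  pw <- scattering_profile(q, rep(2400, 50), modality = "WAXS")
  expect_equal(normalize_exposure(pw, geom_waxs)$intensity, rep(1, 50))
})

test_that("empty-holder subtraction inverts construction by addition", {
  q <- seq(0.02, 0.3, length.out = 120)
  truth <- exp(-(q - 0.15)^2 / 0.002)
  empty_q <- seq(0.015, 0.31, length.out = 90)     # different grid
  empty_y <- 0.4 + 2 * empty_q
  sample_y <- truth + approx(empty_q, empty_y, xout = q)$y
  s <- scattering_profile(q, sample_y, modality = "SAXS", normalized = TRUE)
  e <- scattering_profile(empty_q, empty_y, modality = "SAXS", normalized = TRUE)
  res <- subtract_empty_holder(s, e)
  expect_lt(max(abs(res$intensity - truth) / max(truth)), 1e-3)

  same <- subtract_empty_holder(s, s)
  expect_equal(same$intensity, rep(0, length(q)))
  expect_equal(subtract_empty_holder(s, e, scale = 0)$intensity, s$intensity)

  short <- scattering_profile(q[q < 0.1], empty_y[seq_len(sum(q < 0.1))],
                              modality = "SAXS")
  expect_error(subtract_empty_holder(s, short), "90%",
               class = "cs_validation_error")
})

test_that("uncertainties combine in quadrature during subtraction", {
  q <- seq(0.1, 1, length.out = 30)
  s <- scattering_profile(q, q * 0 + 5, sigma = rep(3, 30), modality = "SAXS")
  e <- scattering_profile(q, q * 0 + 1, sigma = rep(4, 30), modality = "SAXS")
  expect_equal(subtract_empty_holder(s, e)$sigma, rep(5, 30))
})

test_that("replicate averaging matches closed forms and reduces noise", {
  q <- seq(0.1, 1, length.out = 40)
  mk <- function(v) scattering_profile(q, rep(v, 40), modality = "WAXS")
  avg <- average_profiles(list(mk(1), mk(2), mk(3)))
  expect_equal(avg$intensity, rep(2, 40))
  expect_equal(avg$sigma, rep(1, 40))

  same <- average_profiles(list(mk(7), mk(7), mk(7)))
  expect_equal(same$intensity, rep(7, 40))
  expect_equal(same$sigma, rep(0, 40))

  truth <- sin(q * 3) + 2
  set.seed(11)
  reps <- lapply(1:3, function(i)
    scattering_profile(q, truth * (1 + 0.05 * rnorm(40)), modality = "WAXS"))
  avg2 <- average_profiles(reps)
  rms <- function(y) sqrt(mean((y - truth)^2))
  expect_lt(rms(avg2$intensity), min(sapply(reps, function(p) rms(p$intensity))))

  expect_error(average_profiles(list(mk(1))), class = "cs_validation_error")
  saxs <- scattering_profile(q, rep(1, 40), modality = "SAXS")
  expect_error(average_profiles(list(mk(1), saxs)), class = "cs_validation_error")
})

test_that("reductions are invariant under input row order", {
  q <- seq(0.02, 0.3, length.out = 60)
  y <- 1 / q^2
  f <- withr::local_tempfile(fileext = ".dat")
  perm <- sample(60)
  writeLines(sprintf("%.17g %.17g", q[perm], y[perm]), f)
  shuffled <- read_profile(f)
  expect_equal(shuffled$q, q)
  expect_equal(shuffled$intensity, y)
})
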