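# Independent oracles and small fixture builders used across tests.

# Brute-force azimuthal integration: explicit per-pixel loop with explicit
# per-bin comparisons, sharing no code with azimuthal_integrate().
brute_force_integrate <- function(image, n_bins, q_range) {
  geom <- image$geometry
  edges <- seq(q_range[1], q_range[2], length.out = n_bins + 1)
  sums <- numeric(n_bins); npix <- integer(n_bins)
  for (i in seq_len(nrow(image$counts))) {
    for (j in seq_len(ncol(image$counts))) {
      if (image$mask[i, j]) next
      r <- sqrt((i - 0.5 - geom$beam_center[1])^2 +
                (j - 0.5 - geom$beam_center[2])^2) * geom$pixel_size
      q <- (4 * pi / geom$wavelength) * sin(atan(r / geom$distance) / 2)
      if (q < q_range[1] || q > q_range[2]) next
      b <- NA
      for (k in seq_len(n_bins)) {
        hi_ok <- if (k == n_bins) q <= edges[k + 1] else q < edges[k + 1]
        if (q >= edges[k] && hi_ok) { b <- k; break }
      }
      sums[b] <- sums[b] + image$counts[i, j]
      npix[b] <- npix[b] + 1L
    }
  }
  keep <- npix > 0
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  scale <- geom$exposure * geom$flux_factor
  list(q = centers[keep], intensity = (sums[keep] / npix[keep]) / scale)
}

# Two-sided t-test p-value by numerical integration of the t density,
# independent of stats::t.test and of pt().
quadrature_t_p <- function(t_stat, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-10)$value
}

# Welch t statistic and degrees of freedom from the explicit formulas.
welch_t_df <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  c(t = t, df = df)
}

# Smooth isotropic test profile covering a detector's q range.
smooth_test_profile <- function(q_max = 2.5, n = 500) {
  q <- seq(1e-3, q_max, length.out = n)
  scattering_profile(q, exp(-q^2), modality = "WAXS", normalized = TRUE)
}
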