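#' Construct a 1D scattering profile
#'
#' The basic container for a reduced X-ray scattering measurement: a strictly
#' increasing grid of scattering-vector magnitudes `q` (1/Angstrom), measured
#' intensities (counts or counts/s, arbitrary scale), and optional per-point
#' uncertainties. All internal q units are 1/Angstrom and all lengths
#' Angstrom; nanometre values appear only in reporting.
#'
#' @param q numeric vector of scattering-vector magnitudes (1/Angstrom),
#'   strictly increasing and positive.
#' @param intensity numeric vector, same length as `q`.
#' @param sigma optional non-negative uncertainties, same length.
#' @param modality `"SAXS"` or `"WAXS"`.
#' @param sample_id,condition,replicate free-text labels.
#' @param normalized logical; `TRUE` once intensities are in per-second units
#'   (see [normalize_exposure()]).
#' @return An object of class `scattering_profile`.
#' @export
scattering_profile <- function(q, intensity, sigma = NULL,
                               modality = c("SAXS", "WAXS"),
                               sample_id = NA_character_,
                               condition = NA_character_,
                               replicate = NA_character_,
                               normalized = FALSE) {
  modality <- match.arg(modality)
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (!is.null(sigma)) sigma <- as.numeric(sigma)
  ord <- order(q)
  q <- q[ord]; intensity <- intensity[ord]
  if (!is.null(sigma)) sigma <- sigma[ord]
  p <- structure(list(q = q, intensity = intensity, sigma = sigma,
                      modality = modality,
                      sample_id = as.character(sample_id),
                      condition = as.character(condition),
                      replicate = as.character(replicate),
                      normalized = isTRUE(normalized),
                      diagnostics = list()),
                 class = "scattering_profile")
  validate_profile(p)
}

#' @keywords internal
validate_profile <- function(p) {
  n <- length(p$q)
  if (n < 8L) cs_abort("profile must have at least 8 points", "cs_validation_error")
  if (length(p$intensity) != n ||
      (!is.null(p$sigma) && length(p$sigma) != n)) {
    cs_abort("q, intensity and sigma lengths differ", "cs_validation_error")
  }
  if (any(!is.finite(p$q)) || any(p$q <= 0)) {
    cs_abort("q must be finite and > 0", "cs_validation_error")
  }
  if (any(diff(p$q) <= 0)) {
    cs_abort("q must be strictly increasing (duplicate q values rejected)",
             "cs_validation_error")
  }
  if (!is.null(p$sigma) && any(p$sigma < 0, na.rm = TRUE)) {
    cs_abort("sigma must be >= 0 elementwise", "cs_validation_error")
  }
  p
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> %s, %d points, q in [%.4g, %.4g] 1/A\n",
              x$modality, length(x$q), min(x$q), max(x$q)))
  cat(sprintf("  sample=%s condition=%s replicate=%s normalized=%s sigma=%s\n",
              x$sample_id, x$condition, x$replicate, x$normalized,
              if (is.null(x$sigma)) "no" else "yes"))
  invisible(x)
}

#' @export
as.data.frame.scattering_profile <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' Read a scattering profile from delimited text
#'
#' Accepts whitespace- or comma-delimited text with two or three numeric
#' columns (q in 1/Angstrom, intensity, optional sigma). Lines starting with
#' `#` are comments; comments of the form `# key: value` written by
#' [write_profile()] restore the modality and sample labels. Rows are sorted
#' by ascending q; duplicate q values are rejected.
#'
#' @param path file path.
#' @param modality fallback modality when the header does not record one.
#' @return A [scattering_profile()].
#' @export
read_profile <- function(path, modality = "SAXS") {
  if (!file.exists(path)) cs_abort(paste("no such file:", path), "cs_io_error")
  lines <- readLines(path, warn = FALSE)
  meta <- list(modality = modality, sample_id = NA, condition = NA,
               replicate = NA, normalized = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([a-z_]+)\\s*:\\s*(.*\\S)\\s*$", ln))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta)) {
      meta[[m[2]]] <- if (m[2] == "normalized") identical(m[3], "TRUE") else m[3]
    }
  }
  data_lines <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(data_lines) == 0L) cs_abort("no data rows", "cs_parse_error")
  rows <- lapply(seq_along(data_lines), function(i) {
    fields <- strsplit(trimws(data_lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || any(is.na(vals))) {
      cs_abort(sprintf("malformed numeric row at data line %d: '%s'",
                       i, data_lines[i]), "cs_parse_error")
    }
    vals[1:min(3L, length(vals))]
  })
  ncol <- min(vapply(rows, length, 1L))
  mat <- do.call(rbind, lapply(rows, `[`, seq_len(ncol)))
  if (anyDuplicated(mat[, 1])) {
    cs_abort("duplicate q values in input", "cs_validation_error")
  }
  scattering_profile(q = mat[, 1], intensity = mat[, 2],
                     sigma = if (ncol >= 3L) mat[, 3] else NULL,
                     modality = meta$modality, sample_id = meta$sample_id,
                     condition = meta$condition, replicate = meta$replicate,
                     normalized = isTRUE(meta$normalized))
}

#' Write a scattering profile to delimited text
#'
#' Full-precision whitespace-delimited text with a commented header recording
#' column names, units and the profile labels, so that
#' `read_profile(write_profile(p, f))` round-trips exactly.
#'
#' @param profile a [scattering_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  hdr <- c(sprintf("# modality: %s", profile$modality),
           sprintf("# sample_id: %s", profile$sample_id),
           sprintf("# condition: %s", profile$condition),
           sprintf("# replicate: %s", profile$replicate),
           sprintf("# normalized: %s", profile$normalized),
           if (is.null(profile$sigma)) "# columns: q[1/A] I[counts/s]"
           else "# columns: q[1/A] I[counts/s] sigma")
  body <- if (is.null(profile$sigma)) {
    sprintf("%.17g %.17g", profile$q, profile$intensity)
  } else {
    sprintf("%.17g %.17g %.17g", profile$q, profile$intensity, profile$sigma)
  }
  ok <- tryCatch({ writeLines(c(hdr, body), path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) cs_abort(paste("cannot write:", path), "cs_io_error")
  invisible(path)
}

#' Normalize a profile or image to per-second units
#'
#' Divides intensities by `exposure * flux_factor` from the geometry, e.g.
#' 2400 s at unit flux for the reference wide-angle configuration, or a
#' 4.5-fold flux factor when a brighter beam compensated a shorter
#' acquisition. A `normalized` flag guards against double normalization.
#'
#' @param x a [scattering_profile()] or [detector_image()].
#' @param geometry a [detector_geometry()] supplying exposure and flux_factor.
#' @return Object of the same class with per-second intensities.
#' @export
normalize_exposure <- function(x, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  scale <- geometry$exposure * geometry$flux_factor
  if (inherits(x, "scattering_profile")) {
    if (x$normalized) {
      cs_abort("profile already normalized to per-second units", "cs_state_error")
    }
    x$intensity <- x$intensity / scale
    if (!is.null(x$sigma)) x$sigma <- x$sigma / scale
    x$normalized <- TRUE
    return(x)
  }
  if (inherits(x, "detector_image")) {
    if (isTRUE(x$normalized)) {
      cs_abort("image already normalized to per-second units", "cs_state_error")
    }
    x$counts <- x$counts / scale
    x$normalized <- TRUE
    return(x)
  }
  cs_abort("normalize_exposure expects a profile or detector image",
           "cs_validation_error")
}

#' Subtract an empty-holder background profile
#'
#' Subtracts `scale` times the empty-holder measurement (washer and Kapton
#' tape only) from the sample, interpolating the empty profile linearly onto
#' the sample q grid. Extrapolation is never performed: sample points outside
#' the empty profile's q range are dropped, and the overlap must cover at
#' least 90% of the sample's q span. Negative differences are retained (not
#' clipped) and counted in the result's diagnostics; uncertainties are added
#' in quadrature when both profiles carry them.
#'
#' @param sample,empty [scattering_profile()]s in the same intensity units.
#' @param scale multiplier for the empty profile (default 1; no transmission
#'   correction).
#' @return A [scattering_profile()] on the (possibly trimmed) sample grid.
#' @export
subtract_empty_holder <- function(sample, empty, scale = 1.0) {
  validate_profile(sample); validate_profile(empty)
  span <- diff(range(sample$q))
  lo <- max(min(sample$q), min(empty$q))
  hi <- min(max(sample$q), max(empty$q))
  if (hi <= lo || (hi - lo) / span < 0.9) {
    cs_abort("empty profile q-overlap is below 90% of the sample range",
             "cs_validation_error")
  }
  keep <- sample$q >= lo & sample$q <= hi
  q <- sample$q[keep]
  bg <- stats::approx(empty$q, empty$intensity, xout = q)$y
  out <- sample
  out$q <- q
  out$intensity <- sample$intensity[keep] - scale * bg
  if (!is.null(sample$sigma) && !is.null(empty$sigma)) {
    bg_sig <- stats::approx(empty$q, empty$sigma, xout = q)$y
    out$sigma <- sqrt(sample$sigma[keep]^2 + (scale * bg_sig)^2)
  } else if (!is.null(sample$sigma)) {
    out$sigma <- sample$sigma[keep]
  } else {
    out$sigma <- NULL
  }
  out$diagnostics$n_negative <- sum(out$intensity < 0)
  out$diagnostics$frac_negative <- mean(out$intensity < 0)
  validate_profile(out)
}

#' Average replicate profiles
#'
#' Pointwise mean across two or more same-modality profiles, interpolated
#' linearly onto the first profile's q grid (each profile must cover that
#' grid; extrapolation is refused). The returned sigma is the pointwise
#' standard deviation across profiles, matching the convention of reporting
#' replicate scatter as error bars.
#'
#' @param profiles list of [scattering_profile()]s, length >= 2.
#' @return A [scattering_profile()] on the first profile's grid.
#' @export
average_profiles <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L) {
    cs_abort("need >= 2 profiles; pass a single profile through unchanged",
             "cs_validation_error")
  }
  lapply(profiles, validate_profile)
  modality <- unique(vapply(profiles, `[[`, "", "modality"))
  if (length(modality) != 1L) {
    cs_abort("profiles mix SAXS and WAXS modalities", "cs_validation_error")
  }
  ref <- profiles[[1]]
  mat <- vapply(profiles, function(p) {
    if (min(p$q) > min(ref$q) + 1e-12 || max(p$q) < max(ref$q) - 1e-12) {
      cs_abort("replicate does not cover the first profile's q grid",
               "cs_validation_error")
    }
    stats::approx(p$q, p$intensity, xout = ref$q)$y
  }, numeric(length(ref$q)))
  out <- ref
  out$intensity <- rowMeans(mat)
  out$sigma <- apply(mat, 1, stats::sd)
  out$diagnostics$n_replicates <- length(profiles)
  validate_profile(out)
}
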