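#' Pinhole detector geometry
#'
#' Geometry of a flat detector in a pinhole camera: sample-to-detector
#' distance and square pixel size in mm, beam center in fractional pixel
#' coordinates (row, col), X-ray wavelength in Angstrom (Cu K-alpha 1.542 by
#' default), exposure time in seconds and a dimensionless relative beam-flux
#' factor (1.0 = the wide-angle reference beam; 4.5 for a small-angle beam
#' run at 4.5-fold intensity).
#'
#' Pixel convention: pixel (i, j) has its center at coordinate
#' (i - 0.5, j - 0.5) in pixel units; radii are computed center-to-center
#' against the fractional beam center.
#'
#' @param distance_mm sample-to-detector distance (mm), > 0.
#' @param pixel_mm pixel edge (mm), > 0.
#' @param beam_center numeric pair (row, col) in fractional pixel units.
#' @param wavelength_A wavelength (Angstrom), > 0.
#' @param exposure_s exposure (s), > 0.
#' @param flux_factor relative beam intensity, > 0.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(distance_mm, pixel_mm, beam_center,
                              wavelength_A = 1.542, exposure_s = 1,
                              flux_factor = 1) {
  vals <- c(distance_mm, pixel_mm, wavelength_A, exposure_s, flux_factor)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    cs_abort("distance, pixel size, wavelength, exposure and flux must be > 0",
             "cs_validation_error")
  }
  if (length(beam_center) != 2L || any(!is.finite(beam_center))) {
    cs_abort("beam_center must be a finite (row, col) pair", "cs_validation_error")
  }
  structure(list(distance = distance_mm, pixel_size = pixel_mm,
                 beam_center = as.numeric(beam_center),
                 wavelength = wavelength_A, exposure = exposure_s,
                 flux_factor = flux_factor),
            class = "detector_geometry")
}

#' Default instrument geometries
#'
#' Convenience constructors mirroring a Cu-source pinhole SAXS/WAXS camera:
#' WAXS at 55 mm with a 2400 s exposure at unit flux, SAXS at 600 mm with a
#' 1000 s exposure and a 4.5-fold beam-intensity factor.
#' @param beam_center (row, col) fractional pixel beam center.
#' @param pixel_mm pixel edge (mm).
#' @name default_geometries
#' @export
waxs_geometry <- function(beam_center = c(32, 32), pixel_mm = 0.5) {
  detector_geometry(distance_mm = 55, pixel_mm = pixel_mm,
                    beam_center = beam_center, exposure_s = 2400,
                    flux_factor = 1)
}

#' @rdname default_geometries
#' @export
saxs_geometry <- function(beam_center = c(32, 32), pixel_mm = 0.5) {
  detector_geometry(distance_mm = 600, pixel_mm = pixel_mm,
                    beam_center = beam_center, exposure_s = 1000,
                    flux_factor = 4.5)
}

#' 2D detector image
#'
#' @param counts non-negative numeric matrix of detector counts.
#' @param geometry a [detector_geometry()].
#' @param mask logical matrix of the same shape, `TRUE` = excluded.
#' @return An object of class `detector_image`.
#' @export
detector_image <- function(counts, geometry, mask = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    cs_abort("counts must be finite and >= 0", "cs_validation_error")
  }
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  if (!identical(dim(mask), dim(counts))) {
    cs_abort("counts and mask shapes differ", "cs_validation_error")
  }
  stopifnot(inherits(geometry, "detector_geometry"))
  structure(list(counts = counts, mask = mask, geometry = geometry,
                 normalized = FALSE),
            class = "detector_image")
}

#' Read a detector image from grid text or single-frame TIFF
#'
#' Text grids are whitespace-delimited numeric matrices (`#` comments
#' allowed); `.tif`/`.tiff` files are read with the tiff package.
#'
#' @param path image file.
#' @param geometry a [detector_geometry()].
#' @return A [detector_image()].
#' @export
read_detector_image <- function(path, geometry) {
  if (!file.exists(path)) cs_abort(paste("no such file:", path), "cs_io_error")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      cs_abort("the tiff package is required to read TIFF images", "cs_io_error")
    }
    counts <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(counts)) == 3L) counts <- counts[, , 1]
  } else {
    counts <- as.matrix(utils::read.table(path, comment.char = "#"))
    dimnames(counts) <- NULL
  }
  detector_image(counts, geometry)
}

# Per-pixel q map: radius r from beam center (pixel centers at integer - 0.5),
# 2*theta = atan(r * pixel / distance), q = (4*pi/lambda) * sin(theta).
#' @keywords internal
pixel_q_map <- function(dims, geometry) {
  rows <- matrix(seq_len(dims[1]) - 0.5, dims[1], dims[2])
  cols <- matrix(rep(seq_len(dims[2]) - 0.5, each = dims[1]), dims[1], dims[2])
  r <- sqrt((rows - geometry$beam_center[1])^2 +
            (cols - geometry$beam_center[2])^2) * geometry$pixel_size
  two_theta <- atan2(r, geometry$distance)
  (4 * pi / geometry$wavelength) * sin(two_theta / 2)
}

#' Azimuthally integrate a 2D detector image
#'
#' Reduces an isotropic 2D image to a 1D intensity-vs-q profile. Each
#' unmasked pixel is assigned q from its center-to-center radius to the beam
#' center (see [detector_geometry()] for the convention) and pixels are
#' mean-aggregated into `n_bins` equal-width q bins across `q_range`; empty
#' bins are dropped. No solid-angle or polarization correction is applied.
#' Bin uncertainty assumes Poisson counts: `sqrt(sum counts) / n_pixels`,
#' converted to per-second units by the exposure-flux scale.
#'
#' @param image a [detector_image()].
#' @param n_bins number of q bins (>= 8).
#' @param q_range numeric pair (1/Angstrom) within detector coverage.
#' @param modality modality label for the output profile.
#' @return A [scattering_profile()] in per-second units (`normalized = TRUE`).
#' @export
azimuthal_integrate <- function(image, n_bins = 200,
                                q_range = NULL, modality = "WAXS") {
  stopifnot(inherits(image, "detector_image"))
  if (n_bins < 8L) cs_abort("n_bins must be >= 8", "cs_validation_error")
  qmap <- pixel_q_map(dim(image$counts), image$geometry)
  ok <- !image$mask
  if (!any(ok)) cs_abort("all pixels masked", "cs_validation_error")
  if (is.null(q_range)) q_range <- range(qmap[ok])
  check_window(q_range, "q_range")
  if (q_range[1] >= max(qmap[ok]) || q_range[2] <= min(qmap[ok])) {
    cs_abort("q_range entirely outside detector coverage", "cs_validation_error")
  }
  edges <- seq(q_range[1], q_range[2], length.out = n_bins + 1L)
  sel <- ok & qmap >= q_range[1] & qmap <= q_range[2]
  bin <- findInterval(qmap[sel], edges, rightmost.closed = TRUE)
  counts <- image$counts[sel]
  n_pix <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(counts[bin == b]), 0)
  keep <- n_pix > 0L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  geom <- image$geometry
  scale <- if (isTRUE(image$normalized)) 1 else geom$exposure * geom$flux_factor
  scattering_profile(
    q = centers[keep],
    intensity = (sums[keep] / n_pix[keep]) / scale,
    sigma = sqrt(pmax(sums[keep], 0)) / n_pix[keep] / scale,
    modality = modality, normalized = TRUE)
}
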