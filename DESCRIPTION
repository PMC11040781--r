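Package: cellscatter
Title: WAXS and SAXS Analysis of Cellulose Fibril Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduction and analysis of one-dimensional X-ray scattering
    profiles of cellulosic materials. Wide-angle (WAXS) profiles are
    decomposed into the four cellulose I-beta reflections (1-10, 110, 102,
    200) plus a broad amorphous Gaussian, yielding Bragg d-spacings
    (d = 2*pi/q_max), Scherrer crystal sizes (L = 2*pi/delta-q) and an
    area-based crystallinity index. Small-angle (SAXS) profiles are reduced
    by power-law plus constant background subtraction, transformed to a
    Kratky plot (q^2*I vs q), and the fibril-packing correlation peak is
    fitted with a Gaussian whose position gives the center-to-center
    microfibril distance. Includes azimuthal integration of isotropic 2D
    detector images, empty-holder background subtraction, exposure and flux
    normalization, replicate aggregation with Welch t-tests and percent
    change, small colorimetric-assay helpers, a synthetic scattering-data
    generator with retained ground truth for validation, and an end-to-end
    study pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml
Config/testthat/edition: 3
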