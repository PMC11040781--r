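# cellscatter

Quantitative X-ray scattering analysis of cellulose fibril structure in R.

Treatments that open up cellulose fiber networks — expansins, enzymes,
mechanical refining — can either degrade the crystalline microfibrils or
push intact microfibrils apart. This package implements the combined
WAXS/SAXS analysis that distinguishes the two for 1D scattering profiles of
cellulosic materials (e.g. kraft pulp), together with the replicate
statistics needed to call a treatment effect, a synthetic-data generator
with retained ground truth for validating every estimator, and an
end-to-end study pipeline.

**WAXS (wide angle, ~0.1–3.0 Å⁻¹)** — the profile is decomposed into the
four prominent cellulose Iβ reflections (1-10, 110, 102, 200) plus a broad
amorphous Gaussian. Each fitted peak yields

- the lattice d-spacing by Bragg's law, *d* = 2π/*q*<sub>max</sub>,
- the crystallite size by the Scherrer relation, *L* = 2π/Δ*q*
  (Δ*q* = FWHM, shape factor 1),

and the crystallinity index is the summed crystalline peak area divided by
the total area under the observed curve over the fit window.

**SAXS (small angle, ~0.01–0.3 Å⁻¹)** — after subtracting a
*A q*<sup>−α</sup> power law (α = 4 for dry samples) fitted at low *q* and a
constant fitted at high *q*, the intensity is plotted as a Kratky curve
(*q*²*I* vs *q*); a Gaussian fitted to the fibril-packing peak gives the
average center-to-center microfibril distance *d*<sub>cc</sub> =
2π/*q*<sub>peak</sub>. A shift of the peak to lower *q* is an increase in
interfibrillar spacing.

**Statistics** — per-condition replicate means ± sd, percent change versus
a reference condition, and unpaired two-tailed t-tests (Welch by default),
significant at p ≤ 0.05. Helpers for pull-down percent-bound and linear
standard-curve quantification round out the assay layer.

Also included: azimuthal integration of isotropic 2D detector images
(text or TIFF) with a pinhole geometry, empty-holder background
subtraction, exposure/flux normalization and replicate averaging.

## Worked example

Simulate a triplicate treatment study whose ground truth is a pure 22%
increase in interfibrillar spacing (reference *d*<sub>cc</sub> = 40 Å, 1%
measurement noise, 1% replicate jitter, parallel WAXS measurements), then
run the full pipeline:

```r
library(cellscatter)
cfg <- run_config(seed = 7, simulate = list(
  d_cc = 40, spacing_increase = 0.22, n_replicates = 3,
  replicate_jitter = 0.01, noise = 0.01, waxs = TRUE))
run_study(cfg)
#> <study_report> 12 samples, seed 7
#>
#>  condition             measure n    mean        sd
#>  reference crystallinity_index 3  0.5509 0.0016888
#>    treated crystallinity_index 3  0.5501 0.0007279
#>  reference               d_200 3  3.9256 0.0013550
#>    treated               d_200 3  3.9260 0.0008315
#>  reference                d_cc 3 39.7403 0.6897877
#>    treated                d_cc 3 48.8317 0.3009221
#>  reference               L_200 3 48.4999 0.3985984
#>    treated               L_200 3 48.4159 0.3885419
#>
#>              measure reference treated percent_change t_statistic   p_value significant sig
#>                 d_cc reference treated      22.877019     20.9240 0.0004242        TRUE   *
#>                d_200 reference treated       0.009806      0.4194 0.7006011       FALSE
#>                L_200 reference treated      -0.173150     -0.2613 0.8067659       FALSE
#>  crystallinity_index reference treated      -0.156307     -0.8111 0.4822656       FALSE
```

Reading the report: the SAXS center-to-center distance rises from ~39.7 Å to
~48.8 Å — a +22.9% change, recovering the built-in 22% effect — and is the
only significant comparison (p = 4.2 × 10⁻⁴). The WAXS side is flat: the
200-reflection d-spacing (~3.93 Å), its Scherrer crystal size (~48.5 Å) and
the crystallinity index (~0.55) are statistically indistinguishable between
conditions, exactly the signature of a treatment that spreads microfibrils
apart without altering the crystals themselves.

Individual stages are available directly, e.g.:

```r
res <- analyze_saxs(read_profile("sample.dat"))
res$d_cc                    # center-to-center distance, Angstrom
fit <- fit_waxs_profile(read_profile("waxs.dat", modality = "WAXS"))
fit$d_spacings; fit$crystal_sizes; fit$crystallinity_index
```

A thin command-line front end (`inst/cli/cellscatter`) exposes `simulate`,
`integrate`, `waxs-fit`, `saxs-fit`, `compare` and `run` subcommands over
the same functions.

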