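---
title: "Quantifying cellulose fibril structure from WAXS and SAXS profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cellulose fibril structure from WAXS and SAXS profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellscatter)
```

## The measurement problem

Treatments that loosen cellulose fiber networks — enzymes, expansins,
mechanical refining — can act in two physically distinct ways: by degrading
the crystalline core of the elementary microfibrils, or by pushing intact
microfibrils apart. X-ray scattering separates the two. Wide-angle
scattering (WAXS, q of roughly 0.1–3.0 Å⁻¹) probes the sub-nanometre crystal
lattice: peak positions give lattice d-spacings, peak widths give crystallite
sizes, and the crystalline-to-total intensity ratio gives a crystallinity
index. Small-angle scattering (SAXS, roughly 0.01–0.3 Å⁻¹) probes the
nanometre-scale packing of the 3–5 nm microfibrils: a correlation peak in the
Kratky representation moves to lower q when the average center-to-center
distance between neighboring fibrils grows. A treatment that fibrillates
pulp without attacking the crystals shows a SAXS peak shift with an
unchanged WAXS pattern; `cellscatter` implements that whole comparison as a
reusable, tested pipeline.

## WAXS: peak decomposition and derived quantities

A 1D WAXS profile of cellulose I$\beta$ is modelled over the fit window
(default 0.7–2.0 Å⁻¹) as the sum of four crystalline Gaussians — the 1-10,
110, 102 and 200 reflections — plus one broad amorphous Gaussian beneath
them. Each Gaussian is parameterized by amplitude, center and full width at
half maximum ($\sigma = \mathrm{FWHM}/2.3548$). From a converged fit:

* **d-spacing** of each reflection: $d = 2\pi/q_{\max}$ (Å),
* **crystal size** from each width: $L = 2\pi/\Delta q$ (Å), shape factor 1,
  no instrumental-broadening correction,
* **crystallinity index**: the summed areas of the four crystalline
  Gaussians divided by the trapezoidal area under the *observed* intensity
  over the fit window, clamped to $[0,1]$. Using the observed rather than
  modelled total is the default; the modelled alternative is available via
  `ci_denominator = "model"`.

The solver is box-constrained Levenberg–Marquardt. Centers may move at most
±0.15 Å⁻¹ from their initial guesses (defaults 1.05, 1.17, 1.46, 1.60 Å⁻¹
for the crystalline reflections, 1.35 Å⁻¹ for the amorphous halo — standard
cellulose I$\beta$ assignments, all overridable), widths are confined to
[0.01, 1.5] Å⁻¹ and amplitudes to non-negative values. The amorphous
component must stay at least twice as wide as the widest crystalline peak;
because that couples two parameters, it is enforced by re-tightening the
amorphous lower bound from the current crystalline estimates and refitting
(at most five passes). Parameters ending on a bound are reported as warnings
in the result rather than silently accepted.

```{r waxs-demo}
truth <- waxs_truth(ci = 0.55, noise = 0.01)
prof <- generate_waxs_profile(truth, seed = 1)$profile
fit <- fit_waxs_profile(prof)
fit
```

## SAXS: background, Kratky peak, fibril spacing

The SAXS branch reduces a profile in four stages, each exposed on its own
and composed by `analyze_saxs()`:

1. **Background model** $I_{bg}(q) = A\,q^{-\alpha} + c$, with $\alpha = 4$
   fixed for dry samples (a free-$\alpha$ mode exists for wet samples). The
   constant is the *median* intensity over the high-q window (robust to
   residual peak tails) and $A$ is a closed-form least-squares fit on the
   low-q window; the two estimates are alternated a few times so the
   power-law tail reaching into the high-q window cannot inflate the
   constant. Default windows: 0.010–0.030 Å⁻¹ (power law), 0.25–0.30 Å⁻¹
   (constant) — declared defaults within typical pinhole coverage, both
   overridable.
2. **Subtraction**, retaining negative residuals and recording their
   fraction as a diagnostic.
3. **Kratky transform** $q^2 I$ vs $q$.
4. **Peak fit**: the peak is located as the argmax of a 5-point
   moving-average smoothed copy of the Kratky curve inside the analysis
   window (0.05–0.25 Å⁻¹ by default; smoothing initializes the fit only),
   then a Gaussian is fitted to the *raw* curve over
   $q_{peak} \pm \max(2\,\mathrm{FWHM}_{guess},\,0.05)$ Å⁻¹. A monotone
   curve raises a no-peak error; equal maxima resolve deterministically to
   the lowest-q candidate and are flagged.

The fitted center converts to the average center-to-center microfibril
distance by Bragg's law, $d_{cc} = 2\pi/q_{peak}$, reported in both Å and nm.

```{r saxs-demo}
res <- analyze_saxs(generate_saxs_profile(saxs_truth(noise = 0.01), seed = 2)$profile)
res
```

## Replicate statistics

Conditions are summarized by mean and sample standard deviation (n − 1) over
parallel replicates; a treated condition is compared to the reference by the
signed percent change of means and an unpaired two-tailed t-test,
significant at p ≤ 0.05. Welch's unequal-variance form is the default —
the safer choice when nothing is known about variance homogeneity — with
Student's form selectable; at n = 3 per group Welch is mildly conservative
(empirical type-I rate ≈ 0.035 at the 0.05 level under this package's null
simulation). No multiple-testing correction is applied by default, matching
the single-comparison-per-treatment design. Two small assay helpers follow
the same conventions: pull-down percent bound, $(1 - C_{final}/C_{initial})
\times 100$ clamped to $[0, 100]$, and a linear colorimetric standard curve
(absorbance regressed on concentration, inverted for quantification, with
out-of-range results flagged as extrapolated).

## What the synthetic generator emulates — and what it does not

No public machine-readable pulp scattering data accompany the analysis this
package implements, so validation rests on forward simulation with retained
ground truth. The generators reproduce the *analysis model* exactly:

* WAXS: the five-Gaussian sum on a 400-point grid over 0.1–3.0 Å⁻¹. The
  amorphous amplitude is solved analytically so the area-based crystallinity
  index over the fit window equals a requested value (default 0.55).
* SAXS: $A q^{-4} + c$ plus a peak defined as a *Gaussian in Kratky space*
  (divided by $q^2$ in intensity space) on a 300-point grid over
  0.01–0.3 Å⁻¹. Defaults: $d_{cc} = 40$ Å ($q_{peak} = 2\pi/40 \approx
  0.157$ Å⁻¹, inside the 3–5 nm microfibril scale), peak FWHM 0.05 Å⁻¹,
  Kratky amplitude 0.01, $A = 2\times10^{-5}$, $c = 0.05$. $A$ and $c$ are
  chosen so the low-q window is power-law dominated and the high-q window
  constant-dominated, as in a well-designed measurement.
* Noise: multiplicative Gaussian with a fractional amplitude (default 1%);
  Poisson sampling is available for simulated detector images, where
  expected counts are intensity × exposure × flux.
* Treatment studies: n ≥ 3 replicates per condition; the treated condition
  divides $q_{peak}$ by $1 + \text{effect}$ (a pure spacing increase), and
  per-replicate truths are jittered multiplicatively (default 1%) to mimic
  sample-to-sample variability. A parallel WAXS truth, when requested, is
  identical between conditions except for an intensity-scale jitter — the
  signature of a treatment that spreads fibrils without touching crystals.

Because the generator and the analysis share their model family, noiseless
recovery is essentially exact and the recovery tests measure estimator
behavior, not model adequacy. Real pulp data depart from this ideal:
peaks are not exactly Gaussian, the amorphous halo is not one Gaussian, the
background is not an exact power law, and orientation or absorption effects
can survive azimuthal integration. A `peak_shape = "real"` generator variant
(Gaussian in intensity rather than Kratky space) is provided to probe that
kind of mismatch. Passing tests therefore demonstrate correctness of the
estimation machinery under the stated model, not accuracy guarantees on
arbitrary experimental curves.

## Reduction conventions and numerical choices

* Internal units are Å⁻¹ and Å everywhere; nm appears only in reports.
* Azimuthal integration: pixel centers sit at integer − 0.5 pixel
  coordinates, radii are measured center-to-center to a fractional beam
  center, $2\theta = \arctan(r\,p/D)$, $q = (4\pi/\lambda)\sin\theta$.
  Pixels are mean-aggregated into equal-width q bins; empty bins are
  dropped; no solid-angle or polarization correction is applied. The
  implementation is vectorized and is tested against an explicit per-pixel
  loop oracle to floating tolerance.
* Grid alignment for empty-holder subtraction and replicate averaging is
  linear interpolation with extrapolation forbidden; subtraction requires
  ≥ 90% q-overlap and drops sample points outside the empty profile's range.
* Normalization to per-second units divides by exposure × flux factor
  (e.g. 2400 s at unit flux for WAXS; a 4.5-fold flux factor for a SAXS
  beam run brighter to offset shorter exposures) and is guarded against
  double application.
* Degenerate inputs fail loudly with typed conditions: flat profiles,
  monotone Kratky curves, zero-variance t-test groups, zero reference
  means, all-masked images.

## Problem sizes in the test suite

The shipped tests and the acceptance script run entirely on synthetic data
at deliberately modest sizes — 64×64 detector images, 300–500-point
profiles, 20-seed recovery ensembles and a 200-study null calibration —
sizes at which every property they check is already stable and the whole
suite completes in seconds on one core.

## Known limitations

* No Rietveld refinement, preferred-orientation or paracrystalline lattice
  modelling; the WAXS model is five independent Gaussians and the SAXS model
  is strictly background + one packing peak.
* The Segal height-based crystallinity index is deliberately not offered;
  only the area method is implemented.
* Azimuthal integration assumes an isotropic, flat, single-frame image;
  vendor formats beyond plain TIFF and geometry calibration from standards
  are out of scope.
* With triplicates, the Welch test's conservatism means marginal effects
  (a few percent) need either more replicates or lower replicate jitter to
  reach significance; the 20–25% spacing effects this pipeline targets are
  detected reliably at n = 3.
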