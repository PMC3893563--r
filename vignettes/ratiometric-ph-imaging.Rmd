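---
title: "Ratiometric nanosensor pH imaging: models and methods"
author: "nanosensR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric nanosensor pH imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosensR)
```

## The measurement problem

Fluorescent pH nanosensors are nanoparticles (polyacrylamide or silica
sol-gel, ~30–500 nm) carrying two fluorophores: a pH-sensitive *indicator*
whose emission tracks proton concentration, and a pH-insensitive
*reference* (e.g. TAMRA) that acts as an internal standard. The per-pixel
ratio of indicator to reference intensity cancels fluctuations in
excitation, detector sensitivity, light scattering and local sensor
concentration, so the ratio — not either raw intensity — is the
quantitative signal. Extended-range sensors combine two indicators with
identical emission but different dissociation constants (Oregon Green,
pKa 4.8, responsive at acidic pH; 5(6)-FAM, pKa 6.5, responsive near
neutral), so the summed response stays informative across roughly pH
3.5–7.5, the span of intracellular compartments from lysosomes to
cytosol.

## The calibration model

The ratio–pH relationship is sigmoidal:

$$R(\mathrm{pH}) = R_{\min} + \frac{R_{\max} - R_{\min}}
  {1 + 10^{(pK_a - \mathrm{pH})\cdot \mathrm{hillslope}}}$$

with lower/upper asymptotes $R_{\min}, R_{\max}$, inflection $pK_a$ and
steepness `hillslope` (negative for fluorophores whose ratio falls with
pH; the same formula is used unchanged). Its inverse,

$$\mathrm{pH} = pK_a - \frac{1}{\mathrm{hillslope}}
  \log_{10}\!\left(\frac{R_{\max}-R_{\min}}{R - R_{\min}} - 1\right),$$

is defined only for $R$ strictly between the asymptotes. Ratios at or
beyond the asymptotes, and inverted pH values falling outside the
calibrated buffer interval, receive a distinguished *out-of-range
sentinel* rather than a clamped number; reports label this class
"pH > 10" and colour maps render it black, so excluded measurements stay
visible instead of silently biasing the distribution.

`fit_calibration()` estimates the four parameters by weighted
Levenberg–Marquardt least squares (`minpack.lm`). Starting values are
data-driven — observed ratio extremes for the asymptotes, the pH of the
point nearest the mid-ratio for $pK_a$, hillslope $+1$ — with a
multi-start fallback over hillslope $\{-2,-1,1,2\}$ if the first attempt
fails. Fits are deterministic for fixed input. A structural identity,
$R(pK_a) = (R_{\min}+R_{\max})/2$, holds for every converged fit and is
used as a test invariant.

Two modelling choices were genuinely open and are resolved as follows.
*Weighting:* image-derived calibration points are weighted by their total
background-subtracted reference intensity (i.e. by sensor abundance),
consistent with the pixel-weighting philosophy below; unweighted fitting
is available via `weighted = FALSE`. *Aggregation:* "mean ratio" for a pH
level averages pixels within an image (reference-weighted), then images
within a level (weighted by each image's total reference intensity).
Dual-fluorophore sensors are fitted with the single sigmoid by default —
empirically their summed response remains sigmoid-like over the working
range — while the two-term sum-of-sigmoids response is available in the
simulator for studying the approximation error.

## The image-analysis pipeline

Measurement follows the same stages as calibration:

1. **Background subtraction** — a per-channel scalar, from an
   outside-cell ROI, a sensor-free companion image, or a constant.
   Negative results clamp to zero and the clamped fraction is recorded,
   so systematic over-subtraction is visible.
2. **Masking** — pixels with background-subtracted reference intensity
   *strictly above* a threshold are taken to contain sensors.
3. **Threshold selection** — `select_threshold()` implements the rule
   that the threshold be the lowest value at which more than 90% of
   masked pixels are within the calibration range. Candidates are scanned
   in ascending order on an integer grid (step 1 count by default) from 0
   to the reference maximum; "in range" means the ratio lies strictly
   inside $(R_{\min}, R_{\max})$ *and* the inverted pH lies within the
   calibrated buffer interval. Pixels are counted unweighted here. The
   full scan curve is returned for diagnostics, and failure to reach 90%
   is an error that advises recalibration and reports the best achievable
   fraction.
4. **Ratioing and weighting** — per-pixel indicator/reference ratios;
   weights proportional to reference intensity, normalised to sum to one
   per image. Weighting makes the histogram report the proportion of
   *sensors* at each pH rather than the spatial area at each pH. Masked
   pixels with zero reference are excluded and counted, never divided by.
5. **pH conversion, aggregation, presentation** — per-pixel inversion
   with sentinel handling; weight-mass histograms over the calibrated
   interval with half-open bins $[lo, hi)$ (final bin closed, default
   width 0.2 pH) plus a separate out-of-range bin so total mass is
   exactly 1; weighted and unweighted means with SD across the chosen
   replication unit (pixels, regions, or frames); linear colour maps with
   black sentinels.

Three analysis modes mirror common practice: whole-image (one pH from
the weighted mean ratio; fast, no spatial information), pixel-by-pixel
(full distribution), and region mode, a compromise in which 8-connected
components of the mask filtered by a pixel-count criterion act as
replication units. Connectivity, bin conventions and 0-based pixel
indexing in serialized coordinates are stated conventions; the in-focus
slice of a z-stack is user-designated (`slice` config field), as focus
metrics are out of scope.

## Calibration buffers

The calibration series uses citrate–phosphate (McIlvaine-type) universal
buffers: mixing 0.2 M disodium hydrogen phosphate and 0.1 M citric acid
stocks in varying ratio spans pH ~2.5–8. `solve_ph()` computes the
equilibrium pH of any mixture from the charge balance over H⁺, OH⁻, the
six citrate/phosphate deprotonation states and the Na⁺ counterions (2 per
phosphate formula unit), with speciation fractions from the pKa ladders
(citric 3.13/4.76/6.40; phosphoric 2.15/7.20/12.35; Kw $10^{-14}$; 25 °C
reference values, kept in one documented constants object). The root is
found by 100 bisection steps on pH ∈ [0, 14], driving the residual below
$10^{-12}$ eq/L. The optional Davies activity correction (A = 0.5085,
b = 0.3) converts the thermodynamic constants to conditional ones at the
current ionic strength, iterating speciation and ionic strength to
convergence and reporting proton *activity* — what a glass electrode
reads. It is off by default for transparency and on in `design_recipe()`,
which inverts the (strictly monotone) pH–composition map to generate
recipes for arbitrary targets.

Known limitation: solved pH values track the published bench recipe
series to about 0.1–0.35 pH (Davies on), not better. The bench volumes
are themselves recipe-table values — one row (pH 7.0) deviates from the
classical mixing tables by about 1 ml and from its own series spacing —
and the Davies equation degrades above ionic strength ~0.3 M, which the
phosphate-rich mixtures reach. The solver reproduces a certified
equimolar phosphate reference standard to ~0.015 pH, so the residual
misfit reflects the recipe table and activity model, not the charge
balance. Temperature-dependent pKa values and buffers other than this
two-stock system are out of scope.

## The synthetic-data generator

Because no public micrograph accessions exist for this methodology, the
package ships a simulator that makes every stage testable against known
truth. A `sensor_response_spec()` gives the indicator channel as baseline
plus a sum of sigmoidal fluorophore terms and a constant reference
channel; the default is the dual-fluorophore design (equal amplitudes of
800 counts, pKa 4.8 and 6.5, hillslopes 1, reference 2000 counts,
baseline 200), chosen so ratios span ~0.1–0.9 at realistic mid-range
camera counts. The amplitude ratio between the two fluorophores is not
quantified anywhere authoritative; equal amplitudes are a documented
default, not a claim, and under them the combined curve is monotone
nondecreasing on pH 3–8 with local sensitivity staying above 20% of its
maximum across pH 4.0–7.5 (a tested invariant).

A `scene_phantom()` holds per-pixel truth pH and sensor density (expected
reference counts), background offsets, and an optional indicator→reference
bleed-through fraction (the pipeline deliberately does not correct
bleed-through; the simulator only generates it). Noise is the standard
camera model — Poisson shot noise on expected counts, additive Gaussian
read noise (default SD 5 counts), rounding to integer counts clipped at
16 bits — and identical seeds give bit-identical images; time-lapse
frames derive per-frame seeds deterministically from the master seed.
What the simulator does *not* emulate: optics (PSF/defocus blur),
photobleaching, chromatic misregistration, cellular autofluorescence
structure, or sensor aggregation kinetics. Passing the pipeline-identity
tests therefore demonstrates correctness of the arithmetic and
conventions on ideal sensor-laden images, not robustness to real-data
artefacts, which the protocol controls at acquisition time (registration
beads, bleed-through checks, stable illumination).

## Numerical choices and validation scale

Degenerate inputs are handled explicitly: empty masks and all-sentinel
fields are errors with actionable messages; out-of-range ratios map to
the sentinel, never an exception; an image whose mask empties during
image-based calibration is dropped with a warning, and a pH level losing
all images is an error. pH maps are stored as a two-page 32-bit float
TIFF (pH scaled by 1/14, plus a code plane distinguishing unmasked,
numeric and sentinel pixels) because the available TIFF writer defines
float samples only on [0, 1]; the package reader restores exact `NA`/`NaN`
semantics, and the sidecar provenance JSON records configuration,
calibration and software version.

The validation experiments are desk-scale by design: 12-point calibration
fits replicated over 100 seeds for pKa-recovery (mean fitted pKa within
±0.05 of truth at ratio noise σ = 0.02), 128×128 two-population scenes
for the threshold rule (cross-checked against an exhaustive scan over all
distinct reference values), 48×48 noiseless scenes for end-to-end
pipeline identity at 10⁻⁶ pH, and 16×16 scenes × 1000 replicates for
noise-model convergence. Forward/inverse round-trips hold to 10⁻⁹, and
histogram mass conservation to 10⁻¹².
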