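---
title: "Quantifying dorsoventral signaling gradients and nascent transcription in embryo cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dorsoventral signaling gradients and nascent transcription in embryo cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvquant)
```

## The measurement problem

In the blastoderm-stage *Drosophila* embryo, BMP signaling forms a dorsal
nuclear gradient that refines over nuclear cycle 14 from a broad, weak
profile into a narrow, intense peak, while some of its target genes keep
transcribing in a much broader dorsal domain. Quantifying this from live
imaging requires turning two-channel confocal cross-sections — a nuclear
marker (histone-RFP or DAPI) and a signal reporter (nuclear Medea-GFP,
pMad immunostain, or MCP-GFP bound to MS2 stem-loops) — into per-nucleus
intensity measurements placed on a common dorsoventral (DV) coordinate
axis, and then into a small number of biologically meaningful parameters:
the gradient's amplitude, basal level, peak position and width, and the
boundary of the transcribing domain.

`dvquant` implements that chain end to end:

1. **Geometry** — detect the embryo outline, form the annulus containing the
   cortical nuclear layer, unroll it to a rectangular strip, and assign
   every nucleus a signed DV coordinate (arc-length fraction from the
   dorsal midline, `0` dorsal, `±1` ventral).
2. **Segmentation** — regional-maxima-seeded watershed on the strip with a
   per-compartment Otsu threshold, mask cleaning, and per-nucleus record
   extraction.
3. **Gradient** — Gaussian fitting, the three multiplicative normalization
   layers, multi-embryo averaging after width rescaling, control-embryo
   background processing, and the two-channel nuclear correlation.
4. **Spots** — nascent-transcript dot calling in z-stack time courses by a
   percentile score, and expression-boundary estimation by a penalized
   dorsal-count score.
5. **Synthetic data** — a generator that renders all of the above with
   complete ground truth, so every stage is testable without microscopy
   data.

## The gradient model

Per frame, nuclear signal intensity versus signed DV coordinate $x$ is fit
by nonlinear least squares (Levenberg–Marquardt, analytic Jacobian, via
`minpack.lm`) to

$$I(x) = A\,\exp\!\left(-\frac{(x-\mu)^2}{2\sigma^2}\right) + B,$$

with amplitude $A$ (above-basal nuclear signal at the peak), basal level
$B$ (resting nuclear reporter level — distinct from, and in practice above,
the no-reporter imaging background), peak position $\mu$, and gradient
width $\sigma$ in DV fraction units. `fit_gaussian()` returns a classed
`gradient_fit` object with `coef`, `predict`, `residuals` and `plot`
methods.

Initialization is deterministic so that fits are reproducible: $\mu_0$ is
the DV position of the maximum of a 15-nucleus moving-average profile,
$B_0$ and $A_0$ come from the 5th/95th intensity percentiles, and
$\sigma_0 = 0.15$. Bounds are $A \ge 0$ and $\sigma \in (0.005, 1]$; a fit
ending on the $\sigma$ bounds, or a non-convergent one, raises a `fit
failed` condition (the time-course driver then carries the previous
frame's parameters forward and flags the frame). Data whose 5th–95th
percentile spread is numerically zero short-circuit to $A = 0$, $B$ = mean
— fitting a four-parameter peak to flat data is not meaningful, and this
is the answer that model family degenerates to. We read $\mu$ as the
gradient peak position; nothing downstream depends on any other
interpretation, and in practice the fold to $|x|$ happens only in the
averaging and spot modules, so the sign convention never leaks out.

## Normalization

Three multiplicative layers make intensities comparable across imaging
sessions, embryos, and positions along the DV axis. Only the measured
inputs and the reference constants of the first two layers are fixed by
convention; their algebraic forms are this package's own design choice,
built to be linear in measured brightness, inverse in laser power, and
equal to 1 at the reference constants:

* session: $\mathrm{Calib}_{norm} = \dfrac{\mathrm{Calib}_{mean}}{1.74\times 10^{4}}\cdot\dfrac{0.1}{\mathrm{Calib}_{LP}}$,
  from a no-sample calibration image (`session_factor()`);
* embryo: $\mathrm{timecourse}_{norm} = \dfrac{\mathrm{nuc}_{mean}}{100\cdot \mathrm{nuc}_{LP}}$,
  from the time-course mean nuclear intensity (`timecourse_factor()`),
  correcting for overall brighter time courses (e.g. different imaging
  depth);
* DV axis: a unit-mean curve on an equally spaced 151-point grid over
  $[0,1]$, built per frame from a 30-nucleus sliding-window of nuclear
  intensity versus folded DV coordinate and averaged over frames
  (`dv_norm_curve()`), absorbing position-dependent attenuation that is
  assumed constant over the time course.

Normalized intensity is raw / (session × embryo × curve at the nucleus's
position). Because all three layers are multiplicative, their order is
immaterial — a property the test suite asserts. Fixed embryos instead
divide each nucleus's signal by its own nuclear-channel intensity and then
apply the per-channel affine normalization $(I - B)/A$ from the Gaussian
fit (`normalize_fixed()`).

## Averaging embryos

Embryos differ in gradient width but share its shape, so a naive average
would distort the shape. `average_embryos()` therefore (i) smooths each
embryo's $A_k(t), B_k(t), \sigma_k(t)$ with a 10-frame centered moving
average (shrunken at the edges) and averages them into ensemble parameters
$\bar A, \bar B, \bar\sigma$; (ii) rescales each embryo's DV coordinates
by $\chi_k(t) = \bar\sigma(t)/\sigma_k(t)$, dropping rescaled $|x| > 1$
(by then the gradient has decayed to basal, so nothing of substance is
lost); (iii) affinely normalizes intensities per embryo, pools, and
de-normalizes with $\bar A, \bar B$; (iv) folds left and right halves onto
$[0,1]$; and (v) bins onto a 36-point mesh ($dx = 1/35 \approx 0.0286$)
with half-width bins at both edges. Empty bins are filled by linear
interpolation between neighboring bins and flagged, and each bin reports
the s.e.m. of its members. Frames are aligned across embryos by the
caller's frame correspondence; the intended usage is alignment by time
before gastrulation, supplied per embryo in the run configuration, since
gastrulation onset is the one observable temporal anchor in this system.

Control embryos carrying the nuclear marker but no reporter measure the
imaging background. Their DV-averaged intensity-vs-time curves show slow
oscillatory fluctuations with a period of roughly 9 min, which
`control_background()` removes with a centered moving average spanning
**twice** the nominal period. A boxcar of width $W$ attenuates a sinusoid
of period $T$ by $|\mathrm{sinc}(W/T)|$: $W = 2T$ nulls the nominal period
exactly and stays below 10% residual amplitude for ±10% period error,
whereas e.g. $W = 1.5T$ would leave 21% — that arithmetic fixed the
default. Each microscope set is then normalized by $\beta_{norm}$, the
mean of its own filtered control curves, which makes basal levels
comparable across instruments.

## Spot calling and the domain boundary

For z-stack time courses of MS2/MCP reporters, each segmented nucleus in
each slice yields $I_{nuc}$ (nuclear-channel mean), $I_{max}$ (max signal
pixel) and $I_{mean}$ (signal mean after removing the 5×5 neighborhood of
the max pixel), giving the dot score

$$S = \frac{I_{max} - I_{mean}}{I_{nuc}}.$$

Per time point, records with $S$ at or above the $\theta = 0.98$ quantile
— linear interpolation between order statistics, pooled over the whole
z-stack rather than per slice, since the threshold is a property of the
time point — are called dot-positive. A nucleus counts as transcribing at
a time point if any of its z records is called. Per embryo half (the
halves are treated independently, so the exact midline position is
immaterial; the test suite perturbs it by ±3 nucleus spacings), the
boundary is the candidate position $x_0$ maximizing

$$\mathrm{score}(x_0) = \#\{\text{dots with } x \le x_0\} - \gamma\,\#\{\text{non-dots with } x \le x_0\},
\qquad \gamma = 1 - \theta = 0.02,$$

with candidates restricted to observed nucleus positions (the score is
piecewise constant between them) and ties broken toward the more dorsal
position. The domain width is the mean of the two halves' boundaries; an
embryo's time-course summary is the mean ± s.d. over time points. Dorsal
clustering of high scores is treated as an observation, not an extra
filter — calling is percentile-only.

## What the synthetic generator emulates

`synthetic_config()` renders 1024×1024 16-bit-range frames of an
elliptical cross-section (default semi-axes 180×160 µm at 0.4 µm/px) whose
cortical nuclear layer fills the 18.36 µm annulus used by the unrolling
stage. Defaults were chosen once, for realism at nc 14, and the tests are
run at these values:

* **80 nuclei** per cross-section, radially elongated (5 µm tangential
  semi-axis, elongation 1.6), placed at near-equal arc spacing with 10%
  jitter; placement refuses configurations that cannot avoid overlap.
  Nuclei render as flat-topped super-Gaussian disks
  ($\exp(-1.5\,q^4)$ in normalized squared radius $q$) — chromatin fills
  the nucleus and falls off at its rim, and the flat top keeps
  Otsu-segmented areas above the 400-px cleaning floor at the default
  pixel size, as in real data.
* The signal channel renders $B + A e^{-(x-\mu)^2/2\sigma^2}$ flat within
  each nucleus footprint and 50% of the local gradient value in the
  cytoplasm (nuclear enrichment contrast); additive Gaussian pixel noise
  (s.d. 0.15 au ≈ 1.5% of the nuclear dynamic range) and 5%
  nucleus-to-nucleus brightness variation.
* The default live trajectory refines from $(A, \sigma) = (2, 0.35)$ to
  $(10, 0.12)$ at constant $B = 2$ — broad/weak to narrow/intense.
* MS2 stacks (default 10 slices at 2 µm) have a uniform nuclear MCP level;
  every nucleus with folded $|x| \le 0.27$ carries, with probability 0.8
  per frame, one 3×3 dot at full contrast in one slice and 40% contrast in
  the adjacent slices, mirroring the axial extent of a diffraction-limited
  spot relative to the slice spacing.
* Fixed two-channel embryos draw both channels from one shared per-nucleus
  gradient field with independent 20% multiplicative channel noise; by the
  variance decomposition of the shared-field model this places the
  expected nuclear correlation near ρ = 0.9, the regime where pMad and
  nuclear Medea-GFP track each other.
* Control embryos render a flat signal background whose level oscillates
  with 9-min period and 15% amplitude.

The generator does **not** emulate optics or chromatin texture: no PSF
convolution beyond the implicit pixel sampling, no photobleaching, stage
drift, mitotic domains, or nucleus tracking. Passing tests therefore
demonstrate that the *algorithms* recover known ground truth through the
full image chain — not that the pipeline is robust to every artifact of
real microscopy.

## Numerical choices and degenerate inputs

* Embryo detection: Otsu on the 5-px Gaussian-filtered frame; if the
  largest region covers less than 5% of the image the threshold descends
  (Otsu re-applied below the current threshold, at most 3 times), since a
  single split can latch onto the bright nuclear layer instead of the
  embryo/background division. Blank frames raise `no embryo found`; two
  comparable regions raise `multiple embryos`.
* The arc origin (dorsal midline of the strip) anchors at the circular
  mean of the smoothed contour's apex band (points within 1 px of the top)
  — on a flat apex the raw topmost pixel can sit ~20 px off the symmetry
  axis, which would bias $\mu$ by ~0.016.
* The "projective" unrolling is realized as the piecewise mapping
  (arc-length fraction, normal depth) from a smoothed, uniformly resampled
  outer contour, with wide-stencil smoothed tangents so a constant inward
  offset cannot fold on pixel-scale noise; self-intersecting offsets raise
  `annulus degenerate`. Masks map back by nearest-neighbor painting with
  2×2 subsampling per strip pixel to avoid pinholes.
* Band finding ("sudden rise/drop" per strip column): the first/last
  crossings of the midpoint between the column's 10th and 90th intensity
  percentiles — scale-free, so brightness variation does not move the
  criterion; columns without a crossing inherit neighbors by
  interpolation, and an all-flat strip is flagged `degenerate` with the
  full strip as band.
* Compartments below 16 px or with zero variance contribute empty masks
  (counted in an attribute); the component floor is strict — area ≥ 400 px
  survives, 399 does not; "large" components default to >10× the frame's
  median nucleus area; the opening element is a 2-px-radius disk, the
  smallest that removes watershed-line stubble.
* Quantiles everywhere are type-7 (linear interpolation); dot calling uses
  $S \ge$ threshold; a time point whose scores are all equal calls
  everything and is flagged.
* A half with no called dot reports boundary 0 (empty domain) and is
  flagged rather than dropped.

## Sizes used by the tests and the acceptance script

The unit tests run the image chain mostly on half-resolution embryos
(512 px at 0.8 µm/px — same physical geometry, with the cleaning floor
scaled to 100 px accordingly) and on analytic fixtures. The end-to-end
checks use 8 embryos per condition, a typical cohort for this assay:
8 MS2 time courses of 8 time points × 10 slices at full resolution for the
domain width, and 8 fixed cross-sections for the channel correlation. The
domain width statistic is stationary by construction, so 8 time points
summarize it as well as a full nc-14 course; the tests also verify the
absence of a time trend.

## Known limitations

* Frames are processed independently; there is no nucleus tracking, no
  mitosis handling, and no 3-D surface reconstruction — one annulus per
  cross-section.
* The boundary statistic inherits the percentile threshold's fixed calling
  budget: when nearly every domain nucleus transcribes (dot probability
  near 1), per-time-point recall saturates at roughly the fraction
  $\theta$ cuts off, and single ventral false calls can transiently drag a
  half's boundary — the γ penalty bounds, but does not eliminate, that
  sensitivity.
* The recovered domain width sits slightly dorsal of the generating
  halfwidth (the most ventral *called* dot lies inside the domain edge by
  about one nucleus spacing); at 80 nuclei per section this is a ~1–2% DV
  effect, well inside the reported spread.
* `Calib`/`timecourse` factors implement the canonical forms above; if an
  instrument's response is not linear in laser power, supply your own
  factors — all three layers are plain multiplicative hooks.
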