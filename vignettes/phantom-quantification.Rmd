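---
title: "Quantifying fluorescence-guided-surgery sensitivity metrics on tumor phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescence-guided-surgery sensitivity metrics on tumor phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirphantom)
```

## The problem

Fluorescence-guided surgery (FGS) systems image near-infrared contrast
agents such as indocyanine green (ICG) to delineate tumor from normal
tissue intraoperatively. Comparing systems — or tracking one system over
time — requires a stable, quantifiable target: a tissue-mimicking *phantom*
with a fluorescent tumor inclusion of known concentration embedded in bulk
material of known optical properties. Given an image of such a phantom, the
question becomes: **how should tumor and background regions be defined, and
which summary ratio should be reported?** The answer changes the reported
sensitivity severalfold, which is the phenomenon this package quantifies.

`nirphantom` implements the full desk-scale workflow:

1. a **synthetic phantom-image generator** with exact ground truth,
2. **loaders** that bring heterogeneous system output (16-bit grayscale
   TIFF, 8-bit RGB PNG) onto a common normalized scale,
3. the two **region-definition methods** (Otsu-derived intensity bands and
   fixed-diameter circular ROIs at the intensity peak),
4. the four **sensitivity metrics** (SBR, SNR, CNR, CVR), and
5. **study aggregation** across replicates, concentrations, methods and ROI
   sizes.

## The metrics

With $\mu_T,\sigma_T$ the mean and sample standard deviation of tumor-region
pixel intensities and $\mu_B,\sigma_B$ those of the background region:

$$\mathrm{SBR} = \frac{\mu_T}{\mu_B},\qquad
  \mathrm{SNR} = \frac{\mu_T}{\sigma_B},\qquad
  \mathrm{CNR} = \frac{\mu_T-\mu_B}{\sigma_B},\qquad
  \mathrm{CVR} = \frac{\mu_T-\mu_B}{\sqrt{\sigma_T^2+\sigma_B^2}}.$$

All four are ratios of homogeneous degree zero: they are invariant to
positive rescaling of the image, which is why images from systems of
different bit depth and gain can be compared after normalizing each frame by
its maximum. CNR and CVR are additionally invariant to a constant offset;
SBR and SNR are not. CVR, a discriminability measure related to an
ideal-observer index, never exceeds CNR when the tumor is brighter than the
background (its denominator dominates). Zero denominators raise typed
errors and serialize as `null` — a deliberately undefined cell must never be
confusable with a large ratio. Whether published grids of this kind use
sample or population SD is typically unstated; this package uses the sample
SD ($n-1$) throughout and records it here.

No rounding happens inside the pipeline. Rendering at two significant
figures (the conventional grid format) is done only by
`format_metric_grid()`. This matters in practice: region means reported at
two decimals (say $0.58/0.05$) imply SBR $11.6$, while the same grid
computed from unrounded per-pixel statistics can legitimately print $8.1$ —
dividing rounded summaries does not reproduce unrounded ratios.

## Region definition

**Otsu bands.** An Otsu threshold $t$ is computed on the cropped, normalized
image (256-bin histogram on $[0,1]$). The tumor is all pixels above
$1.5\,t$; the background is all pixels between $0.1\,t$ and $0.7\,t$. "150 %
above the threshold" is interpreted multiplicatively ($>1.5t$), consistent
with the 10–70 % band being fractions of $t$; `tumor_factor` exposes the
additive alternative ($2.5$) as a single argument. Two numerical choices are
worth recording:

* *Threshold search.* Class statistics are accumulated from exact per-bin
  value sums, so the maximizer coincides with splitting the raw pixel values
  at each candidate bin edge (the test suite checks this against exhaustive
  search). When the between-class variance has a plateau — the generic case
  for a cleanly bimodal image, where every edge between the modes ties — the
  **midpoint of the tied candidate edges** is returned, following Otsu's
  original recommendation to average tied maximizers. Taking the lowest tied
  edge instead would park $t$ immediately above the background mode and
  empty the 10–70 % band on exactly the images the method is meant for.
* *Bin count and crop.* Whether published analyses ran Otsu on the cropped
  or full frame, and with how many bins, is usually unstated; both are
  parameters (`bins`, and cropping is explicit via `crop_to_phantom()`).

**Peak circle ROIs.** The tumor ROI is a circle of fixed diameter (5 mm by
default; 7.5 and 10 mm are standard comparison sizes) centered on the global
maximum pixel, ties broken to the lowest row-major index. Pixel membership
is pixel-center distance $\le$ radius. The background circle of the same
size is placed "within the background region"; published descriptions stop
there, so placement is a design choice here: the center is the deepest
interior point (distance-transform argmax) of the background region after
**morphological closing with a 7-pixel disc**, and the circle is then
clipped to the true region (with a warning) if it does not fit. The closing
step exists because sensor noise punctures an intensity-band mask with
isolated below-band pixels; without it the distance transform is governed by
speckle and the "deepest" point lands systematically on the blur ring around
the tumor — the one place a background ROI should not sit. The image border
counts as region boundary.

Mask parameters (threshold and band factors, or centers and radius) are
recorded and round-trip through JSON to the exact masks, so any reported
number can be reconstructed.

## Normalization order

Analyses of this kind crop each frame to a box around the phantom but
report intensities relative to the frame maximum. With one phantom per
frame the two orders coincide; this package normalizes on the full frame
first, and `run_analyze()` exposes `normalize_after_crop` to flip the
order explicitly rather than leaving the ambiguity implicit.

## The synthetic phantom generator

The generator emulates top-down NIR fluorescence images of a 3D-printed
tumor inclusion in tissue-mimicking bulk. Its defaults are the breast-model
study condition: a $28.5 \times 21\,$mm elliptical tumor $2.2\,$mm below the
imaging plane, tumor concentrations drawn from
$\{0.03, 0.1, 0.3, 1\}\,\mu M$ ICG-equivalent, bulk at $0$ or $0.03\,\mu M$,
triplicate acquisitions, and bulk optical properties at 800 nm of
$\mu_a = 0.005$, $\mu_s' = 1.06\ \mathrm{mm^{-1}}$ for normal breast (with
presets for breast tumor, sarcoma, and liver: $\mu_a$ 0.013/0.006/0.143,
$\mu_s'$ 0.68/0.24/0.26 $\mathrm{mm^{-1}}$).

The forward model, in order:

1. **Emission**: $c_T\,e^{-\mu_{\mathrm{eff}} d}$ on tumor pixels and $c_B$
   elsewhere in the footprint, with
   $\mu_{\mathrm{eff}} = \sqrt{3\mu_a(\mu_a+\mu_s')}$ the
   diffusion-approximation effective attenuation applied over the
   tumor-to-plane distance $d$. Real fluorescence distributions depend on
   surface geometry and full photon transport; the single exponential is the
   simplest physically motivated stand-in with a testable closed form, and
   Monte-Carlo transport is deliberately out of scope.
2. **Illumination**: multiplication by a smooth field of exact mean 1 — a
   broad Gaussian beam profile (central hot spot, width half the frame,
   center jittered by up to 10 % of the frame per acquisition) with peak
   relative amplitude `field_inhomogeneity_amplitude` (default 0.05). A
   beam-expanded laser produces exactly this kind of profile, and it gives
   the image a well-defined intensity peak — the situation the peak-ROI
   method presumes.
3. **Blur**: Gaussian convolution (`blur_sigma`, mm; default 0.5) for
   system PSF plus diffusion spread, replicate boundary, unit-sum kernel
   (so blur can never raise the maximum).
4. **Noise**: optional Poisson shot noise (intensities scaled by
   `shot_noise_gain` photons per unit), then additive Gaussian read noise,
   then clipping at zero — the conventional sensor model. **The real
   systems' PSFs and noise figures are not published; the defaults
   (read noise SD 0.01, shot noise off) are placeholders** sized to be
   visible but mild, and every result in the test suite states its noise
   level explicitly.
5. **Quantization**: per system profile. The research profile is 16-bit
   grayscale at fixed gain (full scale = 1.0 intensity unit, brighter
   values clip); the clinical profile is 8-bit RGB with auto-gain (frame
   maximum mapped to full scale before quantization, emulating clinical
   display pipelines). Lossless PNG stands in for the clinical systems'
   lossy exports: compression artifacts are an acquisition nuisance this
   package records in provenance rather than simulates.

One seeded generator drives every stochastic step; a fixed spec yields
bit-identical rasters. Ground truth returned with each image contains the
tumor mask, a background mask excluding a 2-pixel dilation ring around the
tumor (so blur cannot contaminate background statistics in recovery tests),
the true emission ratio $c_T e^{-\mu_{\mathrm{eff}}d}/c_B$ (flagged
undefined at $c_B=0$), and the pre-noise, pre-quantization field.

Replicates in `generate_concentration_series()` differ by noise realization
and a sub-pixel jitter (default $\pm 0.5$ px) of the tumor position,
emulating removal and repositioning of the phantom between acquisitions.

### What the simulations do and do not show

The generator reproduces the *structure* of the measurement — depth-dimmed
inclusion, illumination gradient, blur, sensor noise, per-system
quantization — with exactly known truth, so it can validate the analysis
code and expose region-definition biases. It does **not** reproduce real
phantom images: no photon-transport spatial kernels, no surface reflections,
no autofluorescence texture, no lossy compression, no auto-gain nonlinearity
beyond a linear stretch. Passing tests therefore demonstrate correctness of
the quantification pipeline and qualitative robustness of its findings, not
agreement with any physical system's absolute numbers (which were measured
on undeposited raw images and are not reproducible at desk scale).

Three qualitative findings from physical-phantom studies do reproduce on
seeded simulations, and are locked in as tests:

* the 5-mm peak circle skews SBR, SNR and CNR well above the Otsu-band
  values on the same image;
* mean CNR against a fixed true background region falls when background
  fluorophore rises from 0 to 3 % of tumor concentration;
* mean SBR is monotone non-decreasing across the
  $0.03/0.1/0.3/1\,\mu M$ series, with triplicate standard errors.

On ratio recovery: with shallow unblurred phantoms and 2 % read noise, the
circle-ROI SBR averaged over 20 seeds recovers the true $c_T/c_B$ within
10 % across ratios 3–40 (measured ≈ 4–9 %). The background circle is
referenced to the ground-truth bulk here: at high ratios the normalized bulk
level falls below $0.1t$, so the Otsu band by construction excludes the true
background — itself an instructive failure mode of band-based backgrounds at
high contrast. Individual seeds can err further when the noisy peak falls
within an ROI radius of the tumor edge (nothing localizes the peak without
blur); the fixture uses $c_T = 0.9\,\mu M$ so read noise does not clip at
the fixed-gain full scale, which would tie the maximum across half the
tumor and park the row-major tie-break at the tumor's edge.

## Aggregation conventions

Replicate summaries report the per-metric mean and the standard error
computed as the sample SD of replicate-level metric values over $\sqrt n$ —
not pixel-level pooling — matching the convention of error bars over
repeated acquisitions. A single replicate reports its value with a missing
SE. Cells where segmentation fails (the zero-contrast end of the
concentration series is exactly where the Otsu bands degenerate) are
recorded as failed with the error message kept; the failure pattern is
itself a result. `concentration_sweep()` lets the circle-ROI background
come either from the Otsu band (as when analyzing physical images) or from
the simulation ground truth (`background = "truth"`), which is the right
reference when the question is recovery of a known ratio.

## Problem sizes and runtime

All simulated checks run on $256\times256$ px frames at 5 px/mm (a
51-mm field), 12-image series for sweeps, 20 seeds for recovery, and 200
random $8\times8$ images for the exhaustive Otsu cross-check — sizes chosen
so the whole suite completes in about a minute while every property is
exercised at realistic geometry (5-mm ROI = 25-px diameter).

## Known limitations

* The depth model is a scalar exponential; lateral spread with depth is
  folded into the single blur parameter.
* The auto-gain emulation is a linear stretch; real clinical auto-gain is
  nonlinear and undocumented, so images from such systems should be treated
  as relative-intensity only.
* JPEG inputs are not read; convert lossy clinical exports to PNG and
  record the lossy origin in provenance.
* Background-circle placement is deterministic (deepest interior point);
  published analyses may have placed it manually, which this package does
  not attempt to imitate.
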