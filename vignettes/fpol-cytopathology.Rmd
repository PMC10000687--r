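---
title: "Methylene-blue fluorescence polarization cytopathology: models and methods"
author: "fpolcyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylene-blue fluorescence polarization cytopathology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpolcyto)
```

## The measurement

Fluorescence polarization (Fpol) quantifies how much of the linear
polarization of the excitation light is retained in a fluorophore's
emission. For methylene blue (MB), an FDA-approved cytological stain,
Fpol reports on the dye's rotational mobility and micro-environment:
cancer cells accumulate the cationic dye in mitochondria (driven by
their elevated mitochondrial membrane potential) where its rotation is
hindered, so malignant cells exhibit measurably higher MB Fpol than
benign or normal cells. This makes per-cell Fpol a quantitative,
observer-independent adjunct to the visual cytomorphology used to read
fine-needle-aspiration (FNA) specimens.

A polarization microscope records two images simultaneously: the
co-polarized emission $I_{\parallel}$ and the cross-polarized emission
$I_{\perp}$. The package computes

$$Fpol = \frac{I_{\parallel} - G\,I_{\perp}}{I_{\parallel} + G\,I_{\perp}},$$

where $G$ corrects the instrument's unequal transmission of the two
polarization states. The raw ratio lives in $[-1, 1]$; all reporting
uses the field's $\times 10^{-2}$ display convention
(`fpol_display()`, i.e. raw $\times$ 100). Internally every computation
uses the raw ratio, and the display scale is applied only at reporting
boundaries — this avoids double-scaling bugs, which are easy to commit
when the literature mixes both conventions.

## G-factor calibration

$G$ is estimated from four acquisitions of a uniform dye solution:
vertical/horizontal excitation crossed with vertical/horizontal
detection, giving mean intensities $I_{vv}, I_{vh}, I_{hh}, I_{hv}$.
Because Fpol is a property of the solution and not of the instrument,
the value measured under vertical excitation,

$$Fpol_v = \frac{I_{vv} - G\,I_{vh}}{I_{vv} + G\,I_{vh}},$$

must equal the value measured under horizontal excitation, where the
analyzer roles swap and the weighting inverts,

$$Fpol_h = \frac{I_{hh} - G^{-1} I_{hv}}{I_{hh} + G^{-1} I_{hv}}.$$

Setting $Fpol_v = Fpol_h$ and solving gives
$G = \sqrt{I_{vv} I_{hv} / (I_{hh} I_{vh})}$. The radical matters: the
quadruple ratio itself does not satisfy the consistency condition
unless it happens to equal 1. `solve_g_factor()` therefore uses the
square-root form and reports the achieved residual
$|Fpol_v - Fpol_h|$ so the solution is auditable; tests verify
agreement with a brute-force root-find of $Fpol_v(g) = Fpol_h(g)$ to
$10^{-8}$ on random quadruples. The bundled instrument profile uses
$G = 0.75$.

Two calibration solutions are conventional: MB in aqueous buffer
(free rotation, low Fpol) and MB in glycerol (hindered rotation, high
Fpol). Their true polarizations are not pinned down by any published
value, so the package's defaults (0.05 and 0.35 raw) are configurable
fixture choices; calibration correctness is asserted through bias
recovery, which is invariant to the solution values.

## Image processing

`cmd_process()` and the underlying functions implement the processing
chain:

1. **Validity thresholding.** A pixel is usable iff its 8-bit value in
   *both* channels lies in $[2, 254]$ (inclusive), removing the noise
   floor and saturated pixels. Requiring validity in both channels
   prevents asymmetric censoring from biasing the ratio. With repeated
   frames, thresholds apply per frame before averaging; a pixel must be
   valid in every frame. (Whether the original workflow thresholded
   before or after averaging is not documented; per-frame is the
   stricter reading and is the package's choice.)
2. **Frame averaging.** Repeated acquisitions are averaged per pixel and
   per channel, real-valued (no re-quantization). The two channels are
   recorded concurrently, so "averaging" can only meaningfully refer to
   repeated frames; an optional 3×3 spatial mean filter is deliberately
   *not* applied by default.
3. **Background correction.** Per channel, the median intensity of valid
   non-cell pixels is subtracted and the result clamped at zero. The
   median is robust to bright debris; clamping keeps intensities
   physical. The operation is idempotent (the corrected background has
   median zero). Without a cell mask, the lowest-decile valid pixels
   stand in for background.
4. **Fpol image.** Difference ($I_{\parallel} - G I_{\perp}$) and
   emission ($I_{\parallel} + G I_{\perp}$) images form the per-pixel
   display-scale ratio. Invalid or zero-emission pixels are flagged
   undefined (`NA`), never raised as errors. Pseudo-color rendering
   clips to the 0.0–40.0 ($\times 10^{-2}$) display range through a
   fixed perceptual colormap (viridis), undefined pixels black.
5. **Per-cell quantification.** For each labeled region, the *means* of
   the valid co- and cross-polarized intensities are computed first and
   the ratio applied to the means — algebraically identical to the
   emission-weighted mean of per-pixel Fpol, and asserted as such to
   $10^{-9}$. Regions with fewer than 10 valid pixels are dropped with
   a logged reason. Cell size is projected area in µm² (mask pixel
   count × pixel area); the literature's "cell size" axis does not name
   its measure, and projected area is the package's documented choice.

Clinical workflows segment cells manually; for synthetic data the
package provides `segment_cells()` (Otsu threshold on the emission
image, connected components, 20 µm² minimum area) and validates it
against ground-truth masks at mean IoU > 0.9.

## Classification and cohort statistics

A single cell is flagged malignant-like iff its display-scale Fpol is
*strictly above* 23.3; cells at or exactly on the cutoff fall in the
complementary class (the phrasing "less than or equal to" fixes the
boundary side). The cutoff is an empirically determined constant of the
assay, not something the package re-estimates; comparisons are made on
exact values, not on rounded display values.

Group analysis fits, by REML via `lme4`,

$$Fpol_{ij} = \mu_{g(i)} + b_i + \epsilon_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2), \quad \epsilon_{ij} \sim N(0, \sigma^2),$$

for cell $j$ in specimen $i$ with a fixed effect per group. The
random-intercept unit is the **specimen**, not the subject: cells are
sampled within specimens, and a subject can contribute both a malignant
and a normal specimen. A subject-level option exists
(`unit = "subject"`). LS-means are the fixed-effect estimates with Wald
standard errors; pairwise comparisons use Wald $z$-tests on LS-mean
differences, with significance flagged at $\alpha = 0.001$ for the
diagnostic (malignant/benign/normal) and histologic (IDC/ILC/FA/IDP/
normal) groupings and $\alpha = 0.05$ for tumor grade. Pairwise
p-values are reported unadjusted by default, matching per-comparison
reporting conventions; a Holm option is available.

Two caveats are worth stating plainly. First, Wald $z$ ignores
uncertainty in the variance components; with many specimens this is
immaterial, but for a grouping containing a 2-specimen group the
per-comparison level at $\alpha = 0.05$ is only approximately nominal,
and the *familywise* rate across three unadjusted comparisons is
necessarily above 5% (about 13% empirically at the bundled grade
structure; about 9% even with Holm). The tests therefore assert
per-comparison calibration, not familywise control. Second, with a
between-specimen variance estimated at the zero boundary the model
collapses to ordinary group means; this degenerate equivalence is exact
for balanced designs and asserted to $10^{-8}$.

## The synthetic-data generator

No clinical images or tables are distributed with the assay, so every
input is simulated, and the generator is first-class, tested code.

**Detector model.** Ideal channel intensities come from the exact
forward model $I_{\parallel} = E(1+p)/2$,
$I_{\perp} = E(1-p)/(2G_{\text{true}})$ (so that
$I_{\parallel} + G I_{\perp}$ recovers $E$ and the ratio recovers $p$),
plus a uniform background added equally to both channels. Noise is
Poisson photon noise on the pre-quantization intensity plus additive
Gaussian read noise (SD 1), then clip-and-round to 8 bits — the
standard detector model, since no noise specification is published.
With all noise off the simulator returns the continuous radiometric
field *without* quantization, so noiseless round-trips are exact
(calibration recovery to $10^{-10}$); a `quantize` override forces
8-bit quantization with noise off, isolating pure quantization error
(per-cell error ≤ 1.0 ×10⁻², MAE ≈ 0.15–0.2 ×10⁻² at the default
emission range 120–220).

**Cell fields.** Cells are non-overlapping uniform disks (radius
4–10 µm) in a 205 µm field imaged at 512² px. Uniform disks suffice
because quantification uses region means, to which subcellular texture
is irrelevant; no optical point-spread function or axial sectioning is
modeled. Placement is rejection sampling with 200 attempts per cell.

**Cohorts.** The bundled fixture mirrors the published study structure:
44 specimens (3808 cells) from 28 subjects — 19 malignant (15 IDC/1335
cells, 4 ILC/242), 10 benign (6 FA/632, 4 IDP/278), 15 normal (1321) —
with tumor grades 1/2/3 spanning 2/12/5 specimens and 185/966/426
cells. Per-specimen cell counts, the subject map (15 subjects
contribute a malignant + a normal specimen; one contributes a malignant
+ a benign), and the grade assignment of ILC specimens are fixed
synthetic choices consistent with all published marginals; the true
per-specimen breakdown is not public. Each specimen carries generative
means at three granularities — diagnostic group (24.40/19.49/19.14
×10⁻²), histology (24.42/24.24/19.63/19.00/19.14), and grade
(24.22/24.65/24.32) — and each recovery experiment keys the generator
by the grouping whose parameters it recovers; the three published
keyings are mutually inconsistent as a single per-specimen generative
truth, since all are model estimates from the same unreleased data.

Cells are drawn hierarchically: a specimen intercept
$N(\text{mean}, \sigma_b)$, then cells $N(\text{intercept}, \sigma_w)$
on the display scale, clipped to the physical range. Defaults
$\sigma_w = 1.4$ and $\sigma_b = 0.5$ are fixture values chosen to land
specimen-level SDs near the published 1.2–1.7 ×10⁻² range and LS-mean
SEs at the published order of magnitude at the fixture's cell counts —
they are not published facts. Cell sizes are log-normal
(meanlog 5, sdlog 0.4 in µm²), a generic choice as no size
distribution is published.

**Mixture mode** emulates tumor heterogeneity: 27% of cells in each
malignant specimen are drawn from a noncancerous-like contamination
distribution (mean 19.1 ×10⁻²), and the cancer-cell component mean is
obtained by inverting the mixture so that the specimen's all-cells
expectation stays at its configured mean. Consequently the
at-or-below-cutoff fraction in malignant specimens tracks the injected
27% (the published heterogeneity narrative), while group-mean LS-means
remain recoverable. The cancer-cell-only mean is never published and is
not a target.

**What passing tests do and do not show.** The simulator reproduces the
*statistical and radiometric structure* of the assay: hierarchical
dispersion, detector noise, 8-bit quantization, instrument polarization
bias. It does not reproduce optical blur, subcellular texture, focus
variation, staining heterogeneity, debris, or segmentation ambiguity —
so green recovery tests validate the arithmetic and inference chain,
not clinical performance on real aspirates.

## Numerical choices and problem sizes

* Fpol with non-positive total emission is an error scalar-wise and an
  `NA` pixel-wise; intensities are carried as reals even when sourced
  from integer images.
* Calibration sets with any non-positive mean are rejected; saturation
  above 1% of pixels warns.
* The G-factor residual tolerance for noiseless inputs is $10^{-10}$;
  the closed form is exact, so the residual is rounding-level.
* Otsu thresholding operates on the emission image normalized to its
  maximum; blank images yield empty masks rather than errors.
* Monte-Carlo problem sizes were fixed once at scales where the checked
  property's sampling error is far below its tolerance: 1000 quadruples
  for the root-find equivalence, ~200 cells over 7 noisy fields for
  end-to-end recovery, 50 cohorts for LS-mean coverage, 200 null
  cohorts (20 cells/specimen at the fixture's 44-specimen layout) for
  type-I control — the null distribution of the specimen-level contrast
  is governed by specimen counts, so thinning cells keeps refits cheap
  without weakening the check.
* Every stochastic operation takes an explicit integer seed; identical
  spec + seed is byte-identical, and the caller's RNG state is restored.

## Known limitations

* The G-factor is assumed spatially uniform; field-dependent
  polarization bias is not modeled.
* Background is assumed spatially flat per channel (median
  subtraction); structured background would need a surface fit.
* Wald inference is anti-conservative for groupings with very few
  specimens, as quantified above; a denominator-df method would need to
  be swapped in for small-specimen designs.
* The 23.3 ×10⁻² cutoff is treated as a fixed assay constant;
  re-estimation (e.g. ROC-based) is deliberately out of scope.
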