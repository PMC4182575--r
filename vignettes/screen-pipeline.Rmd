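---
title: "From fluorescence fields to gene-level hit calls: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fluorescence fields to gene-level hit calls: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscreen)
```

## The assay and its model

hcscreen implements the quantitative core of an image-based arrayed
loss-of-function screen for positive regulators of antiviral defense.
The wet workflow it models: macrophage-like cells carrying one shRNA per
well are primed with interferon-gamma, infected with a GFP-expressing
virus, fixed, and stained with Hoechst. An automated microscope images
six fields per well in two channels; nuclei give the total cell count,
GFP-positive nuclei the infected count, and the well's **infection
efficiency** is the mean per-field percentage of GFP-positive cells.
Knocking down a gene the cell needs for antiviral control raises that
efficiency.

Dose is modeled with the single-hit Poisson relation: applying an MOI
$m$ (plaque-forming units per cell, computed from stock titer, dilution,
inoculum volume and cells per well) infects each cell independently with
probability $p = 1 - e^{-m}$. The single-hit form is the standard
virological choice; the data it must reproduce only constrain the curve
to be monotone and saturating. The default inoculum volume of 0.05 ml is
the unique value making a 3x10^6 PFU/ml stock at 1:10 dilution on
3x10^4 cells give MOI 0.5; it is configurable.

## Scoring statistics

For each plate, with $m_0$ and $m_1$ the median efficiencies of that
plate's negative (irrelevant shRNA) and positive control wells,

$$\mathrm{normalized} = \frac{\mathrm{eff} - m_0}{m_1 - m_0},$$

so the control medians map exactly to 0 and 1. Values are **not
clipped**: clipping would truncate the upper tail that hit calling
depends on. Because the transform is per-plate affine, adding or
multiplying all of a plate's efficiencies by a constant changes nothing,
which is how plate-to-plate offsets are removed.

Normalized values are pooled across plates and converted to Z scores
against the pooled valid negative-control wells,
$z = (x - \bar{x}_{null}) / s_{null}$. An shRNA is a **hit** when it is
not excluded and $z \ge 3$ (inclusive); a gene is a **positive
regulator** when at least 2 distinct hairpins are hits. Exclusions:
wells whose cell count falls strictly below 50% of the plate's
negative-control median cell count (cytotoxicity), genes annotated as
not expressed in the cell line (external table), and wells without a
valid efficiency. A count exactly at the cytotoxicity threshold is kept.

Choices the published procedure leaves open, decided here once:

* **SD estimator** for the null: sample (n-1); a population estimator is
  available via `hit_params(sd_estimator = "population")`.
* **Even-count medians**: mean of the two central order statistics.
* **Confirmation screens**: a repeat screen is the same pipeline on a
  second dataset; genes are confirmed by intersecting calls. No new
  statistic is introduced.

## What the simulators emulate

`simulate_screen()` is the fast, well-level generator. A well's measured
efficiency is
$\mathrm{clamp}_{[0,1]}(b \cdot f \cdot o_p + \varepsilon)$ with
baseline $b$, hairpin effect $f$, lognormal plate offset $o_p$, and
Gaussian well noise $\varepsilon$. Defaults encode the screen's stated
working regime: $b = 0.075$ (the 5-10% band the infection is titrated
into under interferon priming), positive-control effect 3.5 (the
fold increase seen when the interferon receptor is knocked down),
827 hairpins over 161 genes (five per gene, with the remainder genes
carrying six), 96-well plates with 6 negative and 6 positive controls
each (control counts per plate are not published; one half-column each
is a realistic arrayed-library layout), plate offset sdlog 0.1, well
noise sd 0.015, and 14 planted positive genes with 3 effective hairpins
each. The planted effect defaults to
$f = 1 + 5\,\sigma_{well}/b = 2.0$, i.e. five approximate null standard
deviations on the normalized scale. Truth (which genes are positive,
which hairpins are effective, which wells cytotoxic) is drawn from a
sub-seed separate from measurement noise, so noise settings never change
the truth.

`generate_field()` is the microscopy-level generator: nuclei are
truncated-Gaussian disks (sigma = radius/2, support one radius; radii
uniform in 4-6 px) placed uniformly with a hard minimum center
separation of 16 px and a border margin, each cell infected
independently at the requested probability, infected cells carrying an
elevated GFP disk over the same footprint; both channels get constant
background (0.05), Gaussian read noise (sd 0.01) and optional Poisson
shot noise. Overlapping blobs combine by **max**, not sum: summation
makes the waist between two close nuclei brighter than their peaks,
which would erase the intensity saddle that declumping resolves; max
preserves it, and at the default separation footprints never overlap so
the rules coincide. The optional "touching" mode places pairs at 1.2
fixed radii (1.6x the maximum radius) apart - sub-separation, mask-merged,
but declumpable at any orientation of the pixel grid; smaller radii make
the saddle unrepresentable on the integer grid at some orientations.

The default signal-to-noise (peak amplitude ~0.6 over background 0.05
with read noise 0.01) is deliberately clean: it yields >=99% nucleus
recall so that pipeline tests measure the statistics, not the
segmenter's noise robustness. What the generator does **not** emulate:
illumination gradients, cytoplasm, debris, focus drift, spectral
bleed-through, spatial plate artifacts, or infection kinetics. Passing
tests therefore certify the counting and scoring machinery on idealized
images, not segmentation performance on real micrographs.

## Segmentation and classification

The nuclei recipe is the canonical one (built on EBImage): threshold ->
fill holes -> optional distance-transform watershed -> area and border
filters. The threshold is Otsu computed over the image's observed
intensity range (hence invariant to affine rescaling) or a fixed value.
Two numerical guards matter in practice:

* Otsu always returns *some* threshold, even on a blank field where the
  "foreground" is half the noise. A field is declared empty (flag
  `low_contrast`) unless foreground and background means separate by at
  least `contrast_z` (default 2) whole-image standard deviations.
* Border-touching objects are removed by default, and the generator
  never places truth centers within one margin of the border, so truth
  and measurement use the same counting convention.

GFP positivity is per-field adaptive: mean GFP over the nucleus mask
dilated by 1 px must exceed the field background mean by `gfp_k`
(default 5) background standard deviations; background is everything
outside all dilated masks, and a confluent field falls back to a fixed
threshold with a `no_background` flag. The default k = 5 yields zero
false positives at the fixture SNR while infected cells sit tens of
standard errors above threshold. As k approaches 0 the rule degenerates:
uninfected footprint means scatter symmetrically around the background
mean, so roughly half of all cells get labeled positive - the guard-rail
tests assert this mass-false-positive behavior.

Well aggregation is the unweighted mean of per-field percentages (the
published convention), not the pooled-count ratio; both are computed and
they differ when field densities are unequal.

## Calibration: what Z against in-plate controls can and cannot promise

Pooled negative-control z-values self-standardize to mean 0, sd 1
exactly - an identity, asserted exactly. But test-well z-values under a
true null are *not* exactly standard normal under realistic conditions,
for two structural reasons. First, a test well's normalized value
carries the estimation noise of its plate's control medians, while the
pooled null controls contain their own median and are variance-shrunk;
with 6 negative controls per plate this alone inflates the observed
null hit rate at $z \ge 3$ from 0.00135 to ~0.0034. Second, lognormal
plate offsets make the per-plate noise-to-range ratio heterogeneous, so
the pooled z is a scale mixture with heavier-than-normal tails
(~0.0027 at 40 controls per plate). Together, measured on 10,080
simulated null test wells, the rate is ~0.0058 - about 4x nominal. With
many controls and no plate effects the machinery is exactly calibrated
(measured 0.00139 vs 0.00135), confirming the implementation; the
miscalibration is a property of the published scoring scheme itself,
worth knowing when interpreting screen-wide hit counts. Gene-level
calls are protected by the 2-hairpin redundancy rule, which is why
recovery specificity stays >= 0.99 regardless.

## Problem sizes used by the test suite

Statistical checks run at sizes chosen to make their Monte-Carlo error
small relative to the asserted margins: binomial checks on 100-250
generated fields (truth only, rendering skipped), segmentation fidelity
on 192-256 px fields with 40-50 nuclei, dose-series ordering on 50
fields per dilution, null calibration on a single 120-plate all-null
screen (10,080 test wells), and planted-hit recovery on 200 replicate
screens of the full 161-gene design. Seeds are fixed; every generator is
a pure function of (parameters, seed), with per-well and per-field
sub-seeds derived by a counter-based linear-congruential step so any
unit is regenerable in isolation.

## Known limitations

* The scoring scheme's null miscalibration above is reported, not
  "fixed": alternatives (robust z against sample wells, B-scores,
  redundancy-aware activity scores) are deliberately out of scope.
* The image generator's idealizations mean segmentation parameters
  (areas, watershed tolerance, GFP k) will need re-tuning on real data;
  all are surfaced in `seg_params()`.
* Cytotoxicity is operationalized purely from cell counts with a fixed
  50% threshold; no dose-response viability modeling.
* Expression filtering trusts an external annotation table; the package
  takes no position on how expression was measured.
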