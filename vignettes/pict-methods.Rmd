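---
title: "Quantifying induced-translocation interaction screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying induced-translocation interaction screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pictscreen)
```

## The assay and its readout

PICT (protein interactions from imaging of complexes after translocation)
encodes protein--protein interactions as localization changes. Yeast cells
carry three engineered components: an *anchor* (Pil1 fused to RFP and
FKBP) that forms discrete, immobile cortical platforms; a *bait* subunit of
the complex of interest fused to FRB; and a GFP-tagged *prey*. Rapamycin
drives FRB--FKBP heterodimerization, pulling the bait -- and any prey bound
to it -- onto the anchor sites. An interaction therefore appears as
rapamycin-induced colocalization of green prey puncta with the red anchor
puncta.

`pictscreen` implements the quantitative readout of that assay: image
preprocessing and segmentation, area-based colocalization scoring,
per-strain statistical hit calling for screens, and FRAP-based
quantification of prey exchange at the anchor sites. Because the original
image data are not publicly deposited, the package also ships a
synthetic-microscopy generator that produces ground-truthed two-channel
fields, whole screens, and FRAP traces; every stage of the pipeline is
developed and tested against it.

## Image pipeline

### Rolling-ball background subtraction

Each channel is background-corrected before segmentation. The background is
estimated as the grayscale opening of the image with a non-flat,
ball-shaped structuring element of radius 115 px (the pipeline default,
configurable via `pict_params()`), and subtracted with clipping at zero.
The opening is anti-extensive, so the subtracted image is always
non-negative and never exceeds the input; structures narrower than the ball
-- the diffraction-limited puncta of interest -- pass through unchanged,
while cytosolic haze and camera offset are removed.

For large radii the exact opening is computed on a block-minimum-reduced
image (factor 2--8 depending on the radius, in the manner of the classic
rolling-ball implementation) and interpolated back bilinearly; `shrink = 1`
forces the exact full-resolution computation, which the test suite compares
against a brute-force opening with an explicit ball. Bit-compatibility with
any particular historical implementation is not promised; agreement is
tolerance-based.

### Local-mean thresholding

Punctate structures are segmented by an adaptive rule: a pixel is
foreground iff it exceeds the mean of its neighborhood by a fixed offset,

$$\text{mask}(p) \;=\; I(p) > \overline{I}_{r}(p) + c,$$

with radius $r = 5$ px and offset $c = 12$ intensity units by default.
Adaptive-threshold conventions differ in the sign of the constant: in the
mean-based variant used here the constant is *subtracted* from the local
mean, so a historical setting of $-12$ corresponds to `thr_offset = 12` --
puncta must rise 12 ADU above their surroundings. The neighborhood is a
disk by default; a square window is available (`thr_window = "square"`)
and is the natural form for a brute-force oracle. Borders are handled by
reflective padding. The mask is invariant to adding a constant to the
image, so the rule is insensitive to residual uniform background.

Connected components of the mask are extracted with 8-connectivity,
filtered to areas between 4 and 200 px (bracketing diffraction-limited
puncta at the simulated pixel scale and excluding single-pixel noise and
large non-punctate structures), and summarized by pixel-mean centroids.
Coordinates are 1-based (row, column), following the host language's
convention.

### Colocalization scoring

The per-field score is area-based (no intensity-correlation measures):
the number of pixels in the intersection of the green and red masks,
normalized by the red-mask area,

$$s = \frac{|M_G \cap M_R|}{|M_R|}.$$

Rapamycin does not affect the anchor, so $|M_R|$ is proportional to the
number of cells in the field and cancels field-to-field density
variation. Normalization is per field -- each field of view contributes one
$s$ -- because the downstream t-test operates across fields; a pooled mode
(test on raw intersection areas, `test_on = "area"`) is available for
comparison. Per-strain recruitment is summarized by the ratio of mean
scores, $+$RAP over $-$RAP. If the vehicle mean is exactly zero the ratio
switches to pooled intersection counts with a one-pixel pseudocount in both
conditions, which avoids infinities, preserves ordering, and is flagged in
the output.

The manual scoring rule used for visually assessed experiments is also
implemented: the fraction of green patches whose centroid lies on the red
mask, with an interaction called when that fraction strictly exceeds 90%.
Centroid membership at tolerance 0 is the strictest reading of
"colocalized"; a dilation tolerance in pixels is available.

## Hit calling

For each strain the $+$RAP and $-$RAP per-field scores (9 fields per
condition by default) are compared with a one-tailed heteroscedastic
(Welch) t-test -- sample variances, Welch--Satterthwaite degrees of
freedom, upper-tail alternative. The direction is fixed to "+RAP exceeds
-RAP" because recruitment can only add colocalization. A strain is
*significant* when $p < 0.02$; on the display scale used for screen
summaries this is $\log_{10}(1/p) > 1.699$ (the base must be 10 for those
two statements to coincide). No multiple-testing correction is applied
across the 227 strains -- faithful to the screen design this reproduces --
though `p.adjust` can of course be applied to the returned table.

Statistical significance alone is not a hit: screens of this design
rescue strains whose recruitment is visually negligible despite a small
p-value. That visual inspection is made quantitative and reproducible here
as a minimum recruitment ratio (`min_ratio`, default 1.5): a *hit* is
significant **and** has ratio at least `min_ratio`. The default is an
artifact choice: simulated null strains sit at ratio $1.0 \pm 0.05$, so
1.5 is far outside the null spread while any biologically meaningful
recruitment in the simulations at least doubles the score.

Degenerate inputs are handled at the screen level: when both groups have
zero variance (e.g. literally identical images in both conditions) the
standalone test refuses, and the screen assigns $t = 0,\ p = 0.5$ for
equal means -- no evidence either way -- or $p =$ NA (never significant)
for unequal constant groups, with the strain flagged.

## The synthetic-microscopy generator

The generator emulates the study conditions: fields of yeast cells bearing
discrete cortical anchor puncta, imaged in two channels, nine fields of
view per strain and condition, 227 strains of which exactly six (the
exocyst subunit preys Sec3, Sec5, Sec6, Sec8, Sec15, Exo84) are planted
interactors.

Cells are solid disks (radius $18 \pm 2$ px at the default 256 x 256 field
scale) placed by rejection sampling so interiors do not interpenetrate.
Anchor puncta (mean 4 per cell) sit on the cell perimeter at
jittered-regular angles -- eisosome-like sites are quasi-regularly spaced
along the membrane, which also keeps planted puncta optically resolvable.
The prey occupies the cytosol (soft-edged disk: the analytic Gaussian blur
of a step edge) and, for preys that natively form cortical patches, a
configurable number of perimeter puncta placed independently of the anchor
sites so chance colocalization is represented. Under $+$RAP, an interactor
relocates a fraction `recruitment_efficiency` of each cell's cytosolic
photons to that cell's anchor sites, split equally -- relocation is
photon-exact, so the expected total prey signal per cell is invariant to
the efficiency, a property the test suite asserts on noise-free renders.

Optics and detection follow the standard widefield CCD model: Gaussian PSF
($\sigma = 1.2$ px; spots are rendered as truncated, renormalized Gaussian
patches), Poisson shot noise on photons, linear gain, camera offset, and
Gaussian read noise:
$\mathrm{ADU} = g\,\mathrm{Pois}(\lambda) + b + \mathcal{N}(0,\sigma_r^2)$.

No quantitative expression levels or recruitment efficiencies were
published for any strain, so all generator magnitudes are artifact
choices, fixed once at values a practitioner would call realistic
(cytosolic prey 600 photons/px; anchor puncta 20,000 photons; gain 0.25
ADU/photon; offset 100 ADU; read noise 2 ADU; interactor recruitment
efficiency 0.8) and documented here rather than tuned per experiment.
Determinism is strict: a field is a pure function of its configuration and
seed, and screen fields draw from per-field streams derived by hashing
(master seed, strain, condition, field), so any subset of a screen can be
regenerated in isolation.

What the generator does *not* emulate -- and therefore what passing tests
do not demonstrate about real data -- includes cell-cycle and
morphological variation, vacuoles and other organelle texture, uneven
illumination, focus drift, spectral bleed-through, and any optical rigor
beyond a Gaussian PSF. One emergent artifact is worth noting because it is
useful: the cytosolic prey creates a weak bright rim just inside the cell
edge under the local-mean threshold (the neighborhood of an edge pixel
includes dark exterior), giving null strains a nonzero, condition-balanced
baseline colocalization with the perimeter-dwelling anchors. The screen
statistics never rely on the baseline being zero -- only on its symmetry
between conditions, which the type-I-error calibration checks.

## FRAP quantification

A FRAP measurement yields three raw traces: mean intensity over the
bleached-spot ROI, over a cell-free background ROI, and over the whole
field. The generative model for a simulated spot is

$$I(t) = B(t)\,\Big[(1 - d) + d\,m\,\big(1 - e^{-k_\mathrm{off}(t - t_b)}\big)\Big],\qquad t \ge t_b,$$

relative to the pre-bleach plateau, with bleach depth $d$, mobile fraction
$m = 1 -$ `immobile_fraction`, exchange rate $k_\mathrm{off}$, and the
whole-field acquisition-bleaching envelope
$B(t) = e^{-\beta t}$. Only the mobile part of the bleached signal
recovers; with $k_\mathrm{off} = 0$ the post-bleach trace is flat, the
no-exchange behavior of the anchor--bait pair itself. The bleach lands
exactly at the first post-bleach frame, so that frame reads $1 - d$ and
recovery time is measured from it.

Normalization is the double-normalization convention with full-scale
rescaling, chosen because the source experiments specify only that movies
were corrected for photobleaching: the background-subtracted spot trace is
divided by the background-subtracted whole-field trace (cancelling
$B(t)$ exactly), then affinely mapped so the pre-bleach mean is 1 and the
first post-bleach point is 0. On this scale the noise-free curve is
$m\,(1 - e^{-k_\mathrm{off} t'})$ -- independent of bleach depth -- the
asymptote is the mobile fraction, and the two pinned points are exact by
construction (asserted in the tests). The alternative convention without
full-scale rescaling would read $(1-d) + d\,m(1-e^{-kt'})$; full-scale is
the default because it makes curves with different bleach depths directly
comparable.

Replicates on a common time grid aggregate pointwise as mean and sample SD
(no resampling across grids is attempted; mismatched grids are an error).
The post-bleach curve is fit by bounded least squares to
$m(1 - e^{-k t'})$ with $m \in [0,1]$ and $k \in [0, 10]$ /s
(Levenberg--Marquardt, with a grid-plus-L-BFGS-B fallback because a flat,
no-exchange curve makes the rate unidentifiable and defeats gradient
fits). A single-exponential reaction-limited model is the only one
offered: the anchor platforms are static, so diffusion-coupled FRAP models
are out of scope, and $k_\mathrm{app}$ should be read as an apparent
exchange rate, an in-vivo proxy for the complex's dissociation rate.

Defaults frame a 7.5-minute observation window (the span over which the
stable pair shows only minor exchange) at 1.5 s per frame, 310 frames,
bleach at frame 10, 90% bleach depth, and the demonstration analyses use
n = 8 (stable) and n = 12 (transient) replicates, the sizes of the two
published reference experiments.

## Numerical and design notes

* **Problem sizes.** Tests and the demonstration analyses run the full
  227-strain screen at 256 x 256 px fields (a few minutes on one core);
  oracle-equivalence checks use random images up to 64 x 64 where
  brute-force double loops are exact and fast; the type-I-error
  calibration simulates 5,000 null preys at the score level, where image
  rendering would add cost but no information about the test's level.
* **Determinism.** All randomness flows from integer seeds through a
  polynomial rolling hash (modulo $2^{31}-1$, exact in doubles); reruns
  are byte-identical, which the suite asserts on written TIFFs and CSVs.
* **Degenerate inputs.** Empty red mask: error (the normalizer is gone).
  Empty green patch set: the patch-colocalization fraction is undefined,
  deliberately distinct from 0. Zero-variance groups, zero vehicle mean,
  flat FRAP curves: see above.
* **16-bit I/O.** Images are held in ADU in memory and written as 16-bit
  grayscale TIFF (values scaled by 1/65535), so a disk round-trip
  quantizes to 1 ADU; screen statistics are insensitive to this, and the
  test suite exercises both the in-memory and on-disk paths.
* **Known limitations.** The negligible-recruitment rescue is a numeric
  surrogate (`min_ratio`) for what was originally a visual judgment; the
  adaptive-threshold variant and sign convention, and the exact historical
  rolling-ball dialect, are stated assumptions (configurable), not
  certainties; and all claims validated on the generator transfer to real
  images only to the extent the generator's idealizations hold.
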