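---
title: "Automated spinal curvature estimation: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated spinal curvature estimation: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinaxis)
```

## The problem

Idiopathic scoliosis is assessed on standing antero-posterior (AP)
radiographs by measuring the lateral curvature of the spine. All the
standard measurements — Cobb, Ferguson, the Greenspan index, the Diab
construction — hinge on identifying three anatomical landmarks per curve:
the superior end vertebra (SEV), the inferior end vertebra (IEV) and the
apical vertebra (AV). Manual landmark selection is the dominant source of
inter- and intra-observer variability, so `spinaxis` automates the whole
chain: it extracts the spinal column from the image, derives the medial
axis (MA, the curve through the vertebral body centroids) and the central
sacral line (CSL, the vertical global-axis reference), detects curves and
their landmarks from the MA–CSL displacement signal, and reports all four
curvature measures with a severity grade.

Pixels are 0-based, row 0 at the superior image edge, x increasing to the
right. Displacement is signed in image coordinates; the package makes no
claim about patient left/right.

## Pipeline stages and their assumptions

1. **Segmentation.** The radiograph is binarized at the optimum global
   threshold — the cut maximizing between-class variance of the 256-bin
   histogram (ties resolved toward the lower cut, so the result is unique
   and histogram-determined). The binary image is morphologically closed
   with a disc (radius 5 px at the 925×475 working scale) to bridge
   inter-vertebral disc gaps, and the largest 8-connected component is kept
   as the column envelope. Original intensities are masked back onto the
   envelope. The stage assumes the vertebral column is the brightest large
   structure; a brighter, larger off-column object would defeat the
   largest-component rule.
2. **Boundary description.** The envelope's border is the morphological
   inner gradient: mask minus its erosion by a disc of radius 1, which
   equals the set of foreground pixels with an 8-neighbour outside the
   mask. Out-of-image pixels count as background (the erosion is computed
   on a zero-padded frame). The largest border component is traced into an
   ordered closed contour by Moore-neighbour tracing, clockwise from the
   topmost-then-leftmost pixel, and the contour coordinate sequences are
   circularly smoothed with a Gaussian (σ = 3 px) and re-quantized.
3. **Axes.** For each row of the contour's vertical extent the MA point is
   the mean of the outermost left/right boundary crossings; rows without a
   crossing are filled by linear interpolation. The CSL is vertical by
   definition; since a vertical line through both the C1 and S1 centres is
   over-determined, it is anchored at the inferior (S1-end) MA sample by
   default, with `top` and `mean` anchors available (`csl_anchor`). The
   displacement signal is d(row) = MA_x − CSL_x.
4. **Landmarks.** Curves are maximal excursions of |d| above a tolerance
   `epsilon` (2 px): the SEV row is the last row before the exceedance, the
   IEV row the next row back inside the band, and a sign change of d splits
   an S-curve into two segments. Segments spanning fewer than `min_span`
   (30) rows are discarded; a curve still open at the column end is closed
   there and flagged `truncated`. The AV is the row of maximal |d| within
   the segment.
5. **Curvature.** Four constructions per segment, all MA-based:
   * *Cobb* — angle between the extreme MA tangent directions over the
     segment, `max θ − min θ` with `θ = atan(dx/drow)`. This is the
     centreline equivalent of the classical endplate construction: the end
     vertebrae of a curve are by definition its most tilted ones.
   * *Ferguson* — 180° minus the interior angle at the AV between rays to
     the SEV and IEV centres.
   * *Greenspan index* — `Σ|d| / L` over the segment, `L` the distance
     between the segment's MA end points. Dimensionless; no severity band.
   * *Diab* — 180° minus the interior angle at the AV between rays to the
     mean MA points of the three vertebra-height bands at each curve end.
   Severity follows the clinical bands: `< 10°` normal, `[10, 20)` mild,
   `[20, 40)` moderate, `≥ 40°` severe (closed on the left: a curve of
   exactly 20° is moderate).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `closing_radius` | 5 | px | disc radius bridging disc gaps |
| `erosion_radius` | 1 | px | boundary band thickness |
| `boundary_sigma` | 3 | px | contour Gaussian smoothing |
| `fft_factor` | 1 | – | Fourier densification of the MA series |
| `csl_anchor` | bottom | – | where the vertical CSL is pinned |
| `epsilon` | 2 | px | MA–CSL "overlap" tolerance |
| `min_span` | 30 | rows | minimum curve extent (≈ 1.5 vertebrae) |
| `tangent_half_window` | 36 | rows | least-squares tangent window |
| `diab_band_height` | auto | rows | vertebra proxy = MA extent / 17 |
| `disp_smooth_halfwidth` | 25 | rows | running mean before detection |

Two of these deserve their rationale spelled out.

**Tangent half-window (36 rows).** The extracted MA scallops with the
vertebra pitch (column extent / 17 ≈ 50 rows at the working scale):
within a vertebral body the boundary follows the body, not the midline.
A least-squares slope over half-window *w* acts as a low-pass filter on
the slope field whose first null falls at wavelength `2πw / 4.493`;
`w = 36` puts that null at one vertebra pitch, cancelling the scalloping
almost exactly while attenuating the anatomical curve (wavelengths of
hundreds of rows) by under 1%. Slopes near segment boundaries are computed
with windows drawn from the full MA so every segment row gets a two-sided
window; clipped one-sided windows would let the scalloping through.

**Displacement smoothing (half-width 25 rows).** Curve detection and apex
localization run on the displacement signal after a running mean whose
window (51 rows) matches one vertebra pitch, again cancelling
pitch-periodic ripple. The apex is then refined by fitting a parabola to
|d| over ±40 rows around the argmax and taking its vertex — the top of a
scoliotic curve is locally quadratic and flat, so the raw argmax is the
least stable landmark. Angle computation uses the unsmoothed MA.

## The phantom generator

Real scoliosis radiographs with ground-truth geometry are not publicly
available, so validation runs on a synthetic family with analytic ground
truth. A phantom is a 925×475, 256-grey-level image: 17 rectangular
vertebral bodies (12 thoracic + 5 lumbar, intensity ≈ 200, width 60 px)
centred on a parametric midline at evenly spaced rows, each rotated to the
local midline tangent, separated by darker disc gaps, over an intensity-60
background with additive Gaussian noise (σ = 10 by default), clipped to
[0, 255]. The midline is a vertical baseline plus one raised-cosine bump
per curve — smooth, compactly supported, with closed-form derivative — so
every geometric quantity is known exactly. The default baseline is the
image centre column, which makes the left–right mirror relation exact:
negating all amplitudes mirrors the noise-free image bit for bit.

A phantom "with Cobb angle θ" is calibrated in closed form: the extreme
tangents of a bump of amplitude A and half-span s enclose
`2·atan(Aπ / 2s)`, so `amplitude_for_cobb()` inverts this exactly. The
analytic oracle (`analytic_angles()`) evaluates the same estimators the
pipeline uses on the exact midline; with the default tangent window it
reports ≈ 1% below the closed form (the filter attenuation), which is the
like-for-like reference the pipeline is compared against. Ground-truth
segment bounds are the epsilon-crossings of the analytic displacement —
the same convention the detector uses — because the bump's support edges
are not observable at any finite tolerance.

What the phantom does **not** emulate: ribs, pelvis and soft-tissue
shadows; exposure gradients; vertebral rotation and endplate wedging;
varying vertebra heights; real film noise (the synthetic Gaussian noise at
σ ≤ 30 never flips a pixel across the 140-grey-level object/background
separation, so the segmentation is effectively noise-free). Passing the
validation suite therefore demonstrates the geometric correctness of the
chain, not robustness to clinical image quality.

## Numerical choices and degenerate inputs

* Otsu ties break toward the lower threshold; a constant image raises an
  error rather than returning an arbitrary cut.
* Components are 8-connected throughout; component-size ties break toward
  the component whose topmost-leftmost pixel comes first in raster order.
* Moore tracing is clockwise from the topmost-then-leftmost pixel; the
  walk is a deterministic map on (pixel, backtrack) states and stops when
  a state repeats, so the trace is reproducible and terminates on any
  input, including bands with spurs.
* Rows crossed more than twice by the contour (concavities) use the
  outermost crossing pair.
* The apex tie rule is the smallest row; `apical_vertebra()` exposes the
  raw rule, the pipeline adds the parabolic refinement.
* A method inapplicable to a segment (Diab on a curve shorter than six
  vertebra bands) reports `NA` in `measure_curvature()`; called directly,
  the operation raises a typed error.
* A straight spine is a report with zero segments and an explanatory note,
  never an error; stage failures are prefixed with the stage name.
* `fft_interpolate()` splits the Nyquist bin symmetrically for even-length
  inputs so the resampled series stays real; it is exact on band-limited
  signals. It is off by default (`fft_factor = 1`) because the MA is
  already sampled at every row; the switch remains for sparser data.

## Validation problem sizes

The test-suite and the acceptance script generate all inputs
programmatically: five straight phantoms (noise σ ∈ {0, 5, 10}); fifteen
single-curve phantoms (nominal Cobb {15°, 25°, 40°} × five seeds,
σ = 10); three S-shaped double-curve phantoms; a mirror pair; a noise-free
amplitude ladder {10, 20, 30, 40} px at half-span 250 rows (chosen so the
smallest curve still admits the Diab anchors); 100 random rater-label
pairs against a brute-force kappa oracle and 1000 null-kappa simulations
at n = 50. On these, the pipeline's Cobb estimate tracks the analytic
oracle to a mean absolute error well under 1° and the apex to a few rows.

## Known limitations

* The severity of a measurement error near a band edge is inherent to hard
  banding: an estimate 0.2° below 40° grades moderate.
* Vertebral level labels (T1…L5) come from 17 equal-height bands, an
  admitted simplification used only for agreement bookkeeping.
* The Diab construction follows the automated MA/CSL reading (three-band
  centroid anchors); the corner-based manual variant is out of scope.
* Only unweighted Cohen's kappa for exactly two raters is provided.
* Truncated curves (running off the lumbar end) are closed at the last row
  and flagged; clinical handling of such curves is unresolved upstream.
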