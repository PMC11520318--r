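---
title: "Electro-optical deformability cytometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electro-optical deformability cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deformacyte)
```

## The measurement

A shear deformability cytometer pushes cells suspended in a weakly
viscoelastic carrier through a narrow rectangular channel (40 × 30 µm by
default). Viscous shear elongates each cell along the flow axis. The
instrument quantifies that shape change twice, on the same cell:

* **Electrically.** Two differential electrode configurations probe the
  cell along two orthogonal projections. At low frequency a cell is
  essentially insulating, so each configuration's differential current
  amplitude reflects the cell's cross-section seen from that direction.
  The ratio of the two amplitudes, normalised so that rigid calibration
  beads read exactly 1, is the *electrical deformability* (ED).
* **Optically.** The configuration-1 signal also measures the cell's
  velocity, from which the instrument predicts when the cell reaches an
  imaging window 350 µm downstream and fires a 2 µs LED flash. The frame
  is segmented, the outline is fitted with a moment-based ellipse, and
  the major/minor axis ratio is the *optical deformability* (OD). Rigid
  spheres again read 1.

The package implements the complete computational chain — a ground-truth
simulator, the impedance event detector, the image measurement, the
event-frame correlation with coincidence accounting and lateral-position
gating, and the population statistics up to three-parameter Hill
dose-response fits — with every stage testable against simulated truth.

## Signal model

A particle transiting one differential electrode configuration produces an
anti-symmetric double Gaussian: a positive lobe as it passes the first
electrode pair and a mirrored negative lobe at the second,

$$ s(t) = A\left[e^{-(t-t_0)^2/2\sigma^2} -
          e^{-(t-t_0-\Delta t_1)^2/2\sigma^2}\right], $$

where the transit time $\Delta t_1 = D_1 / v$ spans the electrode spacing
$D_1$ (40 µm) and $\sigma$ is the electrode half-width (10 µm) divided by
the velocity. The configuration-1 amplitude follows the Coulter volume
law, $A_1 \propto d^3$, anchored so a 10 µm bead has unit amplitude. The
configuration-2 amplitude uses an identity shape-factor link,
$A_1/A_2 = \text{deformability}$: strictly increasing, trivially
invertible, and exactly 1 for spheres. This link is a modelling
convenience that makes ground-truth recovery checkable; it is not a
dielectric model of the cell interior, which is out of scope.

Traces are sampled at 87 ksps. A guard rejects configurations whose
central ±2σ Gaussian lobe would span fewer than 8 samples — the fastest
admissible particles at the highest study flow rate (15 µl/min, up to
0.43 m/s) sit exactly at that limit.

### Event detection

Detection runs on a lightly smoothed copy of channel 1 (Gaussian,
σ = 3 samples) so that noise cannot split a crest, with a prominence
threshold defaulting to 5× the robust noise SD (from the MAD of first
differences). Peaks pair greedily with the next valley of comparable
magnitude (ratio within 0.5–2) inside the transit time of a 0.01 m/s
particle. Extremum positions are then refined on the *raw* trace by an
iterated least-squares parabola whose window matches the crest width
(~0.8σ): at 87 ksps a crest spans only 8–25 samples, and a 3-point
interpolation would otherwise let single-sample noise dominate the
velocity estimate. Amplitudes come from matched bi-Gaussian template
least squares — exact on noise-free signatures, near-optimal under white
noise, and insensitive to baseline offset because the template is
zero-mean. The configuration-2 amplitude reuses the same template at the
delay predicted by the event's own velocity, scanning a few samples of
shift to absorb the propagated timing error.

Measured performance on simulated cohorts (fixed seeds, see the test
suite): noise-free transit times within 0.15 sample, median velocity
error below 1% at amplitude SNR 20, bead ED spread below 0.01 at SNR 50.

## Optical model

Frames show dark cells on a light background in a window spanning 34 µm
along the flow and the full 40 µm channel width, at 0.63 µm/pixel
(the scale implied by the ±10 px ≈ ±6.3 µm gate). Cell outlines are

$$ r(\theta) = r_0\, e(\theta)\, \bigl(1 + s\,[(1+\cos\theta)/2]^2\bigr), $$

with $e(\theta)$ an area-preserving ellipse stretching the flow axis by
the cell's optical deformability and $s$ a one-sided tear-drop tail.
The tail factor was chosen deliberately: the superficially simpler
limaçon $r_0(1+s\cos\theta)$ leaves the total flow-axis extent unchanged
($r(0)+r(\pi) = 2r_0$) and provably *lowers* the moment-fit axis ratio of
an already-elongated cell, which is the opposite of the near-wall
artefact being modelled — tear-drops must *inflate* the measured long
axis. The one-sided tail does, strictly and monotonically (verified for
axis ratios 1–1.3 in the test suite). Edges are anti-aliased by
signed-distance coverage, motion blur is a 1-D box convolution of length
velocity × pulse along the flow, and Gaussian pixel noise is added at a
configurable fraction of contrast (default 5%).

### Segmentation and the moment ellipse

Images are contrast-enhanced by 1st–99th percentile rescaling and
converted to grayscale. Edges come from a Sobel gradient magnitude with
hysteresis thresholds set from a robust noise estimate (MAD of the
gradient, floored at 25% of the maximum gradient so noise-free images
threshold sensibly); the edge ring is closed morphologically, filled,
and refined to the half-contrast level — the unbiased boundary for a
symmetrically blurred dark object. Components below 20 px or touching
the lateral frame edges (cells partly outside the window) are discarded;
multi-component frames are routed to coincidence handling, never
silently measured.

The ellipse fit uses normalized second-order central moments with the
1/12 per-pixel correction; axis lengths are $4\sqrt{\lambda_\pm}$ of the
2 × 2 moment matrix — the convention under which a solid disk returns
its diameter. Conventions differ between libraries by factors of two, so
this is fixed explicitly and property-tested against a brute-force
pixel-cloud covariance analysis on random blobs.

The optical diameter is the area-equivalent $\sqrt{\text{major} \times
\text{minor}}$, rescaled so the bead median equals 10 µm; bead
referencing makes the result insensitive to the axis-mean convention.
The pixel scale itself is calibrated as 10 µm over the median bead
mean-axis in pixels.

## Trigger, coincidence, and the Y gate

An event's trigger time is the configuration-1 midpoint crossing plus
$D_2/v$. $D_2$ is device-specific and configurable (default 350 µm);
every stage reads it from the geometry object. Trigger latency jitter is
a free simulator knob set to 20 µs: that keeps the illumination-position
spread under ~6 µm SD at the fastest study flow rate, so ≥95% of cells
appear inside the 34 µm window at every flow rate used — matching the
qualitative behaviour of the real trigger chain.

Frames are matched to events through `floor(t_trigger × frame rate)` on
the shared clock; events landing in one camera frame are flagged
coincident and excluded from population statistics by default (the
instrument design aims for one cell per frame). The coincidence rate is
reported as the percentage of frames with ≥2 objects among frames with
≥1 (53 two-cell frames among 2844 give 1.9%), with the all-frames
denominator available as an option; Poisson arrival statistics govern
its dependence on the event rate and are checked against the exact pmf.

Cells sheared near a wall develop the tear-drop asymmetry that inflates
OD but barely perturbs the impedance ratio, so ungated OD rises
quadratically with |y| while ED stays flat. The lateral gate retains
only cells within ±6.3 µm of the midline (±10 px at the default pixel
scale). Gating changes membership only — it never alters measured
values — and the retention report formats counts per group
("672/1430 (47%)" style).

## Population statistics and dose-response

Group summaries report mean, SD and SEM of ED and OD. Between-modality
agreement uses least squares with R² always computed against the mean
model, including for through-origin fits, so variants are comparable.
Treated-vs-untreated comparisons use Welch's t-test (Satterthwaite df);
no multiplicity correction is applied by default, matching how such
panels are conventionally starred, and `stats::p.adjust` composes
trivially where a user wants Holm.

Dose-response uses the three-parameter Hill curve with unit slope,

$$ y(c) = y_{max} + (y_{min} - y_{max}) \frac{c}{EC_{50} + c}, $$

the conventional parameterisation for a saturating fall from an
untreated plateau to a rigid-sphere floor near 1. The zero-dose anchor
is handled exactly ($y(0) = y_{max}$), never log-transformed. Fitting is
Levenberg–Marquardt with a multi-start over a log-spaced EC50 grid
spanning the positive dose range; flat responses return
`converged = FALSE` with a diagnostic rather than a spurious estimate.
The EC50 confidence interval is a percentile bootstrap resampling within
concentration levels. Scale equivariance (doses ×10 ⇒ EC50 ×10) and the
noiseless round trip (EC50 within 1%) are tested.

A note on attainable precision: with the study's five dose levels, three
replicates, and replicate noise of SD 0.02 on a response range of ~0.16,
the *global* least-squares optimum recovers EC50 within 25% in only
about half of simulations — roughly 0.13 decades of intrinsic
uncertainty. Expecting ~90% within 25% under those conditions would
require noise below ~0.0075. The package reports the estimator honestly
rather than regularising it toward the truth; the corresponding
stress-test in the acceptance suite documents this floor.

## The simulator as study design

Generator defaults are the study conditions, chosen once:

| Parameter | Default | Basis |
|---|---|---|
| cell diameter | 12 ± 1 µm | HL60-scale promyelocytes |
| bead diameter | 10 µm, CV 1% | polystyrene calibration beads |
| deformability mean (untreated) | 1.10 / 1.16 / 1.22 at 5/10/15 µl/min | 1.16 anchored to the printed 10 µl/min value |
| deformability population SD | 0.06 | printed normal-fit spread |
| lateral focusing SD | 7 µm | partial viscoelastic focusing, some cells near walls |
| height (z) SD | 5 µm | same mechanism, narrower dimension |
| wall OD gain κ | 0.5 | reproduces the parabolic ungated OD rise |
| wall skew gain | 0.3 | visible tear-drops near walls |
| event rate | 10 s⁻¹ | ~10⁵ cells/ml at study flow rates |
| trigger jitter | 20 µs | see above |
| trace SNR / image noise | 20 / 5% contrast | realistic electronics and camera noise |

Cells carry two shape truths: `deform_true`, the flow-axis elongation
the impedance ratio probes, and `deform_opt = deform_true ×
(1 + κ(2|y|/w)²)` with the tail skew, the shape actually rendered. The
wall amplification is deliberately optical-only: the near-wall artefact
inflates the *measured* long axis while the impedance ratio is nearly
position-independent, and wiring κ into the electrical truth would
contradict both that behaviour and the gate's purpose. Arrival times are
a Poisson process; velocities come from the Newtonian rectangular-duct
series solution (cross-checked against a finite-difference solve to
<0.1%), whose 5 µl/min centre-line maximum, 0.144 m/s, is consistent
with the reported operating point.

What the simulator does *not* emulate: viscoelastic rheology of the
methylcellulose carrier (velocities are Newtonian), electric-field
inhomogeneity and z-dependent impedance sensitivity, optical
point-spread functions beyond motion blur, debris and doublets, and
drift between runs (calibration is single-session, so no block-wise bead
drift correction is implemented). Passing recovery tests therefore
demonstrates the correctness of the analysis chain under the stated
statistical structure, not instrument-level accuracy on real cells.

## Numerical choices and degenerate inputs

* Duct series: 101 odd terms, cosh ratios computed in overflow-safe
  form; positions outside the channel are errors.
* Trace synthesis touches only a ±5σ window per Gaussian, so cost is
  linear in particle count; superposition is exact, so coincidences are
  representable.
* Sub-sample refinement clamps vertices to the search window and falls
  back to 3-point interpolation if the local quadratic is not concave.
* Constant images, empty masks, single-pixel masks, empty traces,
  bead-free cohorts, flat dose-responses: all rejected with explicit
  errors or `converged = FALSE`, never silent.
* Medians (not means) calibrate both chains, for outlier robustness.
* A single master seed fans out to per-stage seeds by a fixed hash, so
  every stage is independently reproducible and identical seeds give
  byte-identical tables.

## Problem sizes used in the checks

The test suite runs cohorts of 50–520 particles per trace (up to ~60 s
of simulated acquisition), frame stacks of a few hundred 54 × 63 px
images, 200-blob property sweeps, and 200-replicate dose-response Monte
Carlo — sizes at which every recovery statistic above is stable under
seed changes while the whole suite stays fast on a single CPU. The
acceptance study totals ~500 cells and ~100 beads across three flow
rates.
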