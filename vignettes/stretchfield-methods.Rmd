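---
title: "Methods: strain mapping and cell readouts for membrane-stretching microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain mapping and cell readouts for membrane-stretching microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stretchfield` analyzes time-lapse microscopy of cells cultured on a
pneumatically stretched elastomeric membrane. This vignette documents the
models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic-data validation does and does not
demonstrate.

## Coordinate and unit conventions

Images are numeric matrices indexed `[y, x]`, origin at the top-left
pixel, x rightward, y downward, pixel centers at integer coordinates.
Physical calibration is micrometres per pixel; strain is dimensionless;
pressures are absolute (1 bar = atmosphere), so v% vacuum is
(1 − v/100) bar. Deformation centers default to the image center, where
a pneumatically stretched membrane has zero displacement.

## Displacement estimation (DIC)

A relaxed/stretched image pair is correlated window-by-window. Each
stretched frame is paired with the relaxed frame of its own stretch
period, so slow drifts of the speckle pattern (particle loss, membrane
creep) never accumulate across periods — this is also why a constant
cyclic deformation produces a flat strain series.

**Preprocessing.** Both images pass through CLAHE (tile size 64 px,
clip limit 4), which equalizes speckle contrast across the field. A
constant image is returned unchanged (nothing to equalize); a tile larger
than the image degrades to a single-tile equalization with a warning.

**Pass schedule.** Interrogation windows of 320, 160 and 80 px, each with
step = window/2 (50% overlap); the final step sets the output grid. Per
window the zero-mean normalized FFT cross-correlation is computed, the
admissible shift is capped at window/3 to exclude circular-wrap aliases,
and the integer peak is refined per axis by a 3-point Gaussian fit
(log-parabola), falling back to a parabolic fit when a neighboring
correlation value is non-positive. Between passes the deformed image is
warped by the current field (bicubic interpolation of the image, bilinear
interpolation of the field with linear extrapolation beyond the grid) —
the "window deformation" scheme — and one extra refinement iteration is
run at the final pass.

**Vector validation.** Two tests run per pass. (1) Peak ratio: the
highest correlation peak must exceed 1.3 times the second peak (outside a
3 px exclusion zone). This criterion gates *final* validity only: at
coarse passes the peak is legitimately smeared by in-window strain (an
8% strain across a 320 px window spreads particle displacements over
±13 px), and discarding those vectors would collapse the predictor.
(2) A normalized median test (threshold 2.0, regularization 0.1 px)
against the 8 neighbors of a full 3×3 block clamped inside the grid —
clamping matters because corner points judged against 3 neighbors divide
by a vanishing median absolute deviation on smooth gradient fields.
Rejected vectors are replaced by the local median for the next pass but
are flagged invalid in the output, never exported as measurements.

**Predictor smoothing.** The field passed from pass to pass is smoothed
with a 3×3 moving average. Window-averaged correlation cannot observe
error modes alternating at the grid scale, so without smoothing such
modes persist through all passes; with it, the multi-pass chain converges
to a few hundredths of a pixel on noiseless fixtures.

**Coverage.** Where the predictor maps window content outside the
recorded frame (material that left the field of view under large
stretch), windows with less than 60% in-frame coverage are flagged
invalid. At 8% strain this removes the border ring — physically, data
that does not exist — which is why border crops are applied before
strain averaging.

## Green–Lagrange strain

Displacement gradients are formed by central differences on the
calibrated grid (one-sided at edges), and
E = ½(∇U + ∇Uᵀ + ∇Uᵀ∇U) = ½(FᵀF − I). The quadratic term matters at the
strains of interest: an 8% stretch gives E = 0.0832, not 0.08. Because
gradients are taken in physical units, strain is independent of the
pixel calibration. Grid points carrying invalid vectors become `NA`, and
a default crop margin of one grid point removes the border artifacts
inherent to windowed correlation (the amount is a package choice; wider
margins are available through `crop_margin`). `crop_and_average()` then
averages each component over an optional rectangular region of interest,
ignoring `NA`s; a user-supplied exclusion mask (e.g. defocused regions)
can be passed to `green_lagrange()`.

Strain series are normalized per component to their first time point, so
the normalized series starts at exactly 1; normalization refuses a zero
baseline rather than producing infinities. Stability is summarized as
max |norm(t) − 1| per component plus the maximum absolute change of the
averaged strains. The shear component is averaged but not normalized —
its baseline is near zero by symmetry and a ratio to it is meaningless.

## Cell readouts

**Kinematics.** Mean cell speed uses single-pass correlation of
consecutive *unstretched* phase-contrast frames (32 px windows, 16 px
overlap, 2 min default interval), so stretch displacement never
contaminates motility. Two measures specific to single-pass subpixel
work are applied: Hann apodization of the interrogation windows (hard
truncation at the window edge is a static feature that correlates at
zero lag and biases small displacements toward zero) and a Gaussian
high-pass prefilter (σ = window/4) that removes intensity structure
larger than the window, whose correlation envelope otherwise dominates
the peak. Windows failing the peak-ratio test are excluded from the
field-of-view average.

**Fluorescence.** Junctional fluorescence is integrated over the field
of view after rolling-disk background subtraction (grayscale opening
with a flat disk, default radius 100 px; negatives clipped to zero) and
normalized to the first frame. Structures narrower than the disk — the
junction ridges — survive subtraction; backgrounds varying on scales
larger than the disk are removed up to edge effects within one radius of
the border. A radius at least the image size degrades to global-minimum
subtraction with a warning.

**Morphometrics.** Cell label masks are an input contract (segmentation
itself, e.g. by a learned segmenter, is out of scope; the synthetic
generator supplies ground-truth masks). Per cell and frame the package
reports area, perimeter, circularity 4πA/P² and shape factor P/√A.
Perimeters use a Crofton (intercept-count) estimator over four line
directions — boundary-pixel counting overestimates smooth perimeters —
with a single multiplicative calibration (0.995) fitted against analytic
perimeters of rasterized disks of radius 30–80 px; disks then measure
circularity within [0.98, 1.02]. The estimator underestimates the
perimeter of axis-aligned polygons by a few percent (4-direction Crofton
quadrature); per-cell normalized series are unaffected. Tracking links
frames by minimal centroid distance under a 15 µm/frame gate, ties
broken by smallest relative area change; cells touching the image border
are not tracked and a track ends when its cell is no longer fully
contained. Per-cell series are normalized to the first frame, and tracks
absent at the first frame are excluded (with a warning) from the
population mean ± SEM; the SEM of a single cell is reported as 0.

## Pneumatic model

Set-point waveforms start each period relaxed at 1 bar and switch to the
vacuum plateau at half period (50% duty); rectangular transitions are
ramped at the finite slope of the control hardware (default 17.5 bar/s,
sampled at 10 ms), so a 0.35 bar step spans two samples. The valve and
vacuum line are modeled as a linear time-invariant lag: first order, or
an underdamped second-order system (ω = 1/τ, damping ζ < 1) when the
measured response overshoots. The true plumbing dynamics are unknown;
the second-order stand-in is constrained by two published figures —
evacuation to 35% vacuum in ≈300 ms and settling within the target band
by 1.5 s — via `fit_response_params()`, which bisects on τ at fixed
ζ = 0.6 so the simulated ramped step first crosses the target at 0.3 s
(τ ≈ 0.105 s) and verifies 2% settling by 1.5 s. Integration is
classical Runge–Kutta at the sample rate with the set point interpolated
piecewise-linearly; ζ ≥ 1 yields a monotone response (asserted
numerically in the tests).

Pressure-change rates use central differences (one-sided at the trace
ends). Rate peaks are extracted per period — most negative rate during
evacuation, most positive during venting — and summarized as mean ± SEM
over complete periods; segmentation accepts a phase offset `t0` so that
each segment contains one evacuation and one venting event. The implied
strain rate assumes the measured linear strain–vacuum relation:
(strain/vacuum depth) × pressure rate, reported rounded to integer %/s to
match common reporting.

## Synthetic data: what it emulates, and what it does not

The speckle generator renders a Poisson number of Gaussian spots
(default density 5 × 10⁻³ px⁻², σ = 1.5 px, 8-bit range) at continuous
positions with additive clipped Gaussian noise. The density is chosen for
correlation robustness — several tens of particles per final 80 px
window — not to match a particular bead dilution, which is unreported
for the tracer protocols the generator emulates. Deformations are
homogeneous (affine; equibiaxial "radial" stretch is F = (1+ε)I about
the stretching center), applied by inverse mapping with bicubic
interpolation (nearest-neighbor for label masks, so labels stay
integral; out-of-frame content is filled with background or label 0).
The ground-truth displacement U(x) = (F − I)(x − center) is exact and
queryable at any point.

The monolayer generator tessellates drifting seed points (Voronoi; the
label mask covers every pixel), renders junction fluorescence in a fixed
half-width band around cell boundaries scaled by a per-frame amplitude
schedule, and gives the phase channel nucleus-like blobs, junction
lines, and material-attached cytoplasmic granules. The granularity is
deliberate: real phase-contrast epithelium is granular, and without
sub-window texture any fixed-window correlator biases subpixel
displacements toward zero. Stretched frames are the relaxed rendering
warped by the frame's deformation, exactly as a membrane-borne monolayer
deforms.

None of this emulates real optics: there is no point-spread function,
no photobleaching, no out-of-plane defocus, no segmentation errors, and
deformations are perfectly homogeneous. Passing the validation suite
therefore demonstrates that the *analysis* is correct and
self-consistent at realistic noise levels — not that it is robust to
every artifact of real microscopy. Conversely, the biological effect
sizes observed on real cells (speed dips, junctional intensity rises)
are represented only as controllable generator parameters whose
*recovery* is tested.

## Problem sizes and tolerances

The validation suite exercises the full chain at 1000 × 1000 px with the
320/160/80 px schedule, where homogeneous 8% equibiaxial and 12%/−4%
uniaxial warps are recovered within 0.005 absolute strain, and uses
512 px or smaller fixtures with proportionally scaled windows elsewhere.
The experiment runners default to 512 px images with a 128/64 px
schedule, a 2 h stability run at 10-min pairs, and one analyzed pair per
mode segment, so each runs in minutes on one CPU; full-scale protocols
are reached by setting `image_size`, `dic_windows`, `duration` or
`pairs_per_segment` in the config. All randomness flows from the single
config seed, and identical configs reproduce outputs bit-for-bit.

## Known limitations

* Strain accuracy degrades within one window of the image border (data
  loss under stretch); the crop margin and validity flags handle this,
  but very small fields leave few interior points.
* The correlation engine assumes mostly-monotone texture motion between
  passes; discontinuous displacement fields (tears, folds) violate the
  smoothing assumptions of the predictor.
* The Crofton perimeter is calibrated on disks; strongly anisotropic,
  axis-aligned shapes carry a few percent perimeter bias.
* The pneumatic model is a two-parameter LTI stand-in constrained only
  by rise and settling times; it does not model compressible flow,
  valve hysteresis, or line resonances.
* The tracking gate is a hard threshold with greedy assignment; densely
  packed fast-moving cells may swap identities where gates overlap.
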