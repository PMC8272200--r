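---
title: "presscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{presscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presscope)
```

## The problem

Prolonged interface pressure between the body and a support surface occludes
blood flow and causes pressure injuries (bedsores), preferentially over bony
prominences — the head, shoulders, sacrum and heels. Sensor mattresses
record the interface pressure as a low-resolution image (here 64 × 32
sensels, 0–1000 mmHg, 1 Hz), which in principle lets a monitoring system
locate high-pressure regions and follow them over time. Two things get in
the way: pillows and wedges placed on the mattress distort the recorded
field with broad artefacts, and the maps are noisy and low-resolution.
presscope implements a full pipeline against both: trend-based
external-object removal, smoothing, HOG-based posture classification, and
gradient-based detection, labelling and tracking of the high-risk regions.

## Savitzky–Golay trend decomposition

The core primitive is the Savitzky–Golay (SG) filter, implemented from its
least-squares definition rather than taken from a signal-processing library,
because the object-removal rule is built directly on its algebra. For a
window of $2M+1$ samples centred at $n=0$, fit a degree-$k$ polynomial
$p(n)=\sum_i a_i n^i$ by least squares. With $A$ the Vandermonde matrix on
abscissae $-M..M$, the coefficients are $a=(A^TA)^{-1}A^Tx$, and the fitted
value at the centre is a fixed linear combination of the window — the
impulse response $h$, the first row of $(A^TA)^{-1}A^T$. Useful properties,
all verified by tests:

* $\sum h = 1$ and $h$ is symmetric, so constants (and, in the interior,
  any polynomial of degree $\le k$) pass through unchanged;
* odd degrees add nothing at the centre of a symmetric window
  (degree 3 = degree 2);
* the convolution equals a per-window polynomial refit everywhere in the
  interior — the test suite checks this against a brute-force refit oracle
  at $10^{-9}$.

At the boundaries the edge window's polynomial is evaluated at the
off-centre positions instead of zero-padding. Zero padding would fabricate
large trend-minus-mean deviations at the bed edges, exactly where the
removal rule thresholds them.

## External-object removal

Bodies and external objects produce statistically different pressure
signals: bony prominences are narrow, high-amplitude bumps; pillows and
wedges are broad, low-relief plateaus. The removal rule unfolds the frame
into a 1-D signal, computes the SG trend $f(S)$, forms the deviation of the
trend from its mean, $S' = |f(S) - \mathrm{avg}(f(S))|$, and keeps only raw
samples where $S' > th$:

$$ b = S \odot (S' > th). $$

Design choices that required real decisions:

* **Line axis.** The default unfolds the frame row-major into a single
  2048-sample line. The window rule ties $M$ to the horizontal sensor count
  ($M = r/2$ with $r = 32$, so a 33-tap window spans about one mat row),
  which is only coherent when the fast axis of the 1-D signal is the
  horizontal direction. We also measured the alternative (one signal per
  column): a supine body occupies most of a column, so the column trend
  crosses its own mean *inside* the body and punches irreparable holes into
  the retained mask; no threshold separates wedge from body in that mode.
  Per-column processing is retained as an option.
* **Per-line mean.** $\mathrm{avg}(f(S))$ is computed per processed line,
  matching how the trend average is displayed against a single unfolded
  signal.
* **Threshold calibration.** The threshold is found by grid search on
  calibration scenes with ground truth. The objective is the supervised
  recovery goal itself: maximize the retained fraction of body-mask energy
  minus the surviving fraction of object-mask energy, with ties broken
  toward the smaller threshold. A plain mask-overlap F1 was evaluated first
  and rejected: empty mattress deviates from the line mean by
  $|0-\mathrm{avg}|\approx\mathrm{avg}$, so it stays retained for any
  threshold below the mean, and the F1 curve is monotone decreasing — its
  argmax is always 0, which keeps the wedge. Note that retaining
  empty-mattress sensels is harmless (their raw values are near zero); the
  method recovers the body *signal*, not the body mask. The threshold is a
  property of the scene ensemble (it depends on the type and number of
  objects present), so it should be calibrated per recording setup; without
  calibration scenes a documented default of 5% of the sensor range is
  used.
* **Window adjustment.** $M = r/2 \pm \epsilon$ leaves $\epsilon$
  unspecified beyond "small"; it is exposed as `eps_adjust` with default 0.

PSNR and RMSE quantify cleaning quality on the normalized (0–1) scale.
PSNR uses $20\log_{10}(\mathrm{peak}/\mathrm{RMSE})$ with peak taken as the
maximum of the normalized *reference frame*: the conventional MAX = 1 form
is inconsistent with the magnitudes this kind of cleaning evaluation
reports (a normalized RMSE near 0.10 alongside a PSNR near 16 dB implies a
peak near 0.65, not 1.0), so the frame's own dynamic peak is the convention
implemented and documented here.

## Enhancement

Two smoothers are provided: an isotropic Gaussian (σ = 1.4 sensels,
reflect boundary, radius ⌈3.5σ⌉ — it gives the cleaner silhouette) and a
separable 2-D SG filter (degree 2), which preserves local extrema and is
therefore preferred before quantitative detection. A "window size 6" cannot
be realized by a symmetric 2M+1 window, so even window requests are
normalized up to the next odd size (7, i.e. M = 3). The default enhancement
chain used before detection and classification is SG-2D (2, 7) followed by
the Gaussian. The SG kernel of degree ≥ 2 has zero second moment, so the
chain's effective blur is essentially the Gaussian's.

## Posture classification

Frames are classified into supine / left-lateral / right-lateral from
histogram-of-oriented-gradients descriptors of the enhanced frame, either
whole-body or restricted to the sacrum band (rows 45–65% of the grid
length, the pelvis region that stays in mattress contact in all three
postures). HOG hyperparameters are not dictated by the method, so standard
settings sized for this grid are used: ×4 bilinear upsampling, 8 unsigned
orientation bins, 8-px cells, 2 × 2-cell blocks with L2 normalization —
a 14,880-dimensional descriptor for a 64 × 32 frame. One numerical detail
matters: the block normalizer uses an epsilon tied to the frame's strongest
block. Without it, blocks over bare mattress contain only sensor noise and
are amplified to unit vectors, drowning the class signal in noise
dimensions; tying the epsilon to the frame (rather than an absolute
constant) keeps the descriptor exactly invariant to positive rescaling of
the frame, which the tests assert.

The training protocol is subject-wise throughout: a random 20% of subjects
is held out (no subject appears on both sides), 10-fold subject-wise
cross-validation runs on the training portion (fold count drops with a
warning when fewer training subjects exist), and the final model is
evaluated on the held-out subjects per class. Three classifiers are wired
in: an RBF SVM (kernlab), KNN with k = 10, and a 100-tree random forest
(ranger). Features are standardized with training statistics only.

## Region detection, labelling, tracking

High-risk regions are found from the spatial gradient field
$\nabla f = (\partial f/\partial x)\hat{i} + (\partial f/\partial y)\hat{j}$
(central differences inside, one-sided at edges). A sensel is a candidate
local maximum where both components change sign from + to − across it, with
at least one strict inequality per axis so flat background does not
qualify; plateau candidates resolve to their cluster centroid. Candidates
below `min_height` (default 20 mmHg) are ignored.

Regions grow from each maximum by relative-level flood fill: the
4-connected component above `rel_level` (default 0.5) times the seed value.
Maxima are sought on the *enhanced* frame, where noise cannot fabricate
spurious peaks, but regions grow on the *raw* frame: enhancement raises the
saddles between nearby landmarks relative to their peaks, so half-maximum
regions grown on the enhanced frame merge neighbouring landmarks that are
cleanly separated in the raw data. Growing on raw also makes the
half-maximum disc of an isolated bump match its analytic area, which the
tests exploit. Overlapping regions are merged with pooled seeds; every
region's mean pressure is the arithmetic mean of the *raw* frame over its
pixels, so tracked values stay in physical mmHg.

Cleanup mirrors clinical priorities: a 3 × 3 morphological opening erases
hand/elbow-scale contacts entirely (their half-max radius is ~1.5 sensels),
and regions below `min_area = 8` sensels are dropped — safely below the
smallest genuine landmark (a heel covers ~13 sensels at half maximum) and
above anything that survives of small decoys. When the posture is known,
regions whose centroid row falls outside every plausible band of a lying
body (head < 0.18 R, shoulders 0.15–0.35 R, sacrum 0.40–0.70 R,
feet > 0.80 R) are discarded.

Labelling uses spatial relations only, valid because the monitored
population cannot reposition themselves: topmost region = head; bottommost
(two for supine, split about the body axis; one for lateral, on the loaded
side) = feet, required to lie in the feet band so a missing foot cannot
pull the sacrum down-label; nearest to 0.55 R among the rest = sacrum;
remaining upper-band regions = shoulders. Left/right are image-frame —
the data do not say whether row 1 is the head or the foot end of the mat,
so the reader exposes a `flip_rows` flag rather than guessing, and labels
are relative to the image.

Tracking associates same-label detections across frames when the centroid
moves at most `gate = 5` sensels per frame (patients who need this
monitoring barely move); misses and gate violations are recorded as
explicit gaps with their timestamps.

## The synthetic bench

All tests run on a seeded synthetic generator, since the public recordings
the method targets cannot ship with the package. A scene is a body phantom
— one isotropic squared-exponential bump per landmark — plus optional
object plateaus with cosine-tapered edges and clipped Gaussian sensor noise
(sd 5 mmHg).

Supine landmark defaults (fractions of grid length; peaks in mmHg /
spreads in sensels): head 0.08 (220 / 2.5), shoulders 0.22 at ±0.22 of the
width (180 / 3.5), sacrum 0.55 (300 / 4), feet 0.92 at ±0.12 (150 / 2).
Lateral postures keep head, one loaded shoulder, the trochanter and one
foot on an axis offset ±0.12 of the width, with narrower, higher contacts
(shoulder 320 / 2.5, hip 380 / 3.0) — side-lying concentrates load on
smaller areas, which is also why lateral lying is riskier per unit time.
The labelled-dataset generator adds a persistent per-subject anatomy
(longitudinal shift sd 2.0; lateral shift sd 1.0 clamped at ±2 sensels,
since staff centre patients on the mat; peak scale sd 10%) and a per-frame
jitter (sd 1.2 sensels) emulating small in-recording movements.

What the phantom deliberately does **not** emulate: continuous torso/leg
contact, limbs, motion, and bed inclination. The blob phantom matches the
operating regime the removal method assumes — distinguishable trends. An
optional `ridge_amp` parameter adds a continuous trunk ridge; scenes built
with it probe the documented failure mode (a broad low body ridge is the
same kind of signal as a wedge, and no threshold separates them), so it is
off by default. Consequently, green tests here demonstrate correctness of
the algorithms under their stated assumptions, not performance on real
mattress recordings.

The standard bench wedge is a broad, low, laterally offset plateau
(25 × 13 sensels, 50 mmHg relief, 3-sensel taper). Bench sizes: the
removal criteria run 50 evaluation scenes against 10 calibration scenes;
the posture benchmark uses 200 frames per class over 13 synthetic subjects;
landmark recovery uses 100 scenes; tracking uses a 120-frame static
sequence. These sizes keep the full suite in the low minutes while leaving
the binomial noise on every asserted rate well below its margin.

## Numerical details and degenerate inputs

* `sg_smooth` requires the window to fit the signal and errors otherwise;
  `degree > 2M` is rejected as unsolvable.
* An all-zero frame decomposes to an empty mask; identical frames give
  RMSE 0 and PSNR +∞.
* Grid-search ties go to the smaller threshold (retain more body).
* `find_maxima` on a constant frame returns an empty list (the strictness
  condition); plateau maxima resolve to centroids.
* KNN tie-breaks are seeded from the model so prediction is deterministic;
  ksvm's kernel-width estimate and ranger's bootstrap are seeded the same
  way.
* A content-free frame still classifies to some label — the behaviour is
  defined (no crash) but the answer is meaningless, and documented as such.
* Frames violating the sensor contract (negative, NaN, above range) are
  rejected by every reader and constructor, never clamped.

## Known limitations

* The removal stage needs the body trend to be distinguishable: many
  objects, or objects overlapping the body's rows in the unfolded signal,
  defeat it. This is inherent to the single-trend model.
* Labelling assumes a stable, roughly axis-aligned lying body; it has no
  notion of prone posture or sitting.
* The PSNR convention (frame-peak over RMSE) is a documented reading, not
  a universal standard; compare PSNR numbers only within this convention.
* Tracking identity is label-based; if two same-label detections ever
  appear in one frame, only the first within the gate extends the track.
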