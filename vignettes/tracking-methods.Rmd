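---
title: "Keypoint-based Hough tracking: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keypoint-based Hough tracking: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The tracking problem

`ghtrack` tracks a rigid, textured target — typically the head of a surgical
instrument seen by an endoscope — through a video sequence, given nothing but
a bounding box on the first frame. Every frame is searched globally
(tracking-by-detection), so a failure in one frame cannot propagate: the
tracker either reports a pose $\lambda_{2D} = (u, v, \theta, s)$ — center in
pixels, in-plane rotation in radians (counter-clockwise positive in image
coordinates), cumulative scale relative to the first frame — or an explicit
no-detection. The recovered 2D pose can initialize an external full-3D
tracker through a pinhole camera model.

## The object model and annulus voting

The object is represented as a set of scale-space keypoints enrolled inside
the initial bounding box. For each model keypoint we store its descriptor,
its distance $d_i$ to the box center, and the angle of the keypoint-to-center
vector *relative to the keypoint's own orientation* — the classic R-table of
a Generalized Hough Transform, made rotation-covariant. Each keypoint also
carries a binary voting state $s_{i,t}$ (did it support the detected center
in frame $t$?); all states start positive at enrollment.

On a new frame, keypoints are detected over the whole image and matched to
the model (nearest neighbour with Lowe's ratio test at 0.8, one-to-one).
A matched keypoint knows $d_i$ but not the current rotation, so instead of
voting for a single displaced point it votes for the full ring of radius

$$ d_{i,t} = r_d \cdot d_i \cdot s_{t-1}, \qquad r_d = [0.95,\, 1.05], $$

centered on its own position. The rings of all correctly matched keypoints
intersect at the true center irrespective of in-plane rotation, and the ring
thickness absorbs the per-frame scale change and mild out-of-plane effects.
Scale and rotation are estimated only *after* the center is found, from the
positive keypoints: $s_t$ as the median ratio of current to template center
distance, $\theta_t$ as the circular median of the angle change of the
keypoint-to-center vector. Medians (rather than means) make both estimates
robust to the occasional misclassified positive; circular statistics avoid
wrap-around artifacts at $\pm\pi$.

Voting details that matter in practice:

* Each eligible keypoint deposits *total* mass equal to its segmentation
  weight, shared uniformly over its ring's integer cells. Without this
  normalization, keypoints far from the center (long perimeters) would
  dominate the accumulator.
* Rasterized ring membership uses an effective half-thickness of at least
  half a cell diagonal ($\sqrt{2}/2$ px). This guarantees that every cell
  the continuous ring passes through — in particular the cell containing
  the true center — receives the vote even when the ring is degenerate
  ($r_d = [1, 1]$).
* The accumulator (bin size 1 px) is smoothed with a Gaussian of
  $\sigma = 2$ px before the argmax: rings intersect in thin arcs, and the
  raw argmax is brittle against quantization. Ties break deterministically
  to the smallest $(v, u)$. A parabolic refinement adds sub-pixel precision.
* Whether votes are binary or carry the segmentation weight is a design
  choice; weighted votes are used, so cluttered regions with uncertain
  foreground support count less.

## Foreground/background segmentation

Vote weights come from a global colour model: HSV histograms with
$12 \times 12$ hue–saturation bins for chromatic pixels and 8 value bins for
achromatic ones (saturation $\le 0.1$ or value $\le 0.15$ of full range,
where hue is unreliable). The two blocks share one normalization, so each
class likelihood is a single 152-bin distribution. Pixels are *routed* to
one block or the other rather than scored by both; this is the natural
reading of that bin layout for the metallic-grey instruments and strongly
chromatic tissue this model is aimed at.

The per-pixel foreground probability is a two-class recursive Bayes filter:
the previous frame's posterior is propagated through a $2 \times 2$
transition matrix (stay-probability 0.6 for both classes — mild temporal
smoothing; results are not sensitive to this value) and combined with the
colour likelihood, normalized so foreground and background posteriors sum
to one. When both class likelihoods vanish (a colour never seen by either
histogram), the propagated prior is returned unchanged — this keeps the
complementarity invariant exact instead of letting a normalization guard
bias the posterior toward either class. All per-pixel math is double
precision with a $10^{-12}$ guard on the normalizer.

The foreground histogram is initialized from the convex hull of the positive
keypoints — not from the bounding box, which deliberately includes
background margin so boundary keypoints can be enrolled. The background
histogram comes from an annular frame between $1.25\times$ and $1.75\times$
the detected box. Both adapt each frame by exponential forgetting with
update factor $\delta = 0.1$, using the hull of the *current* frame's
positive keypoints, i.e. always the final detected pose of that frame. A
keypoint's weight is the mean posterior over a square patch of half-width
$\max(4, 1.5 \cdot \text{detector scale})$ px, clipped at borders; only
weights above 0.5 participate in voting.

## Model adaptation and reset

The model is only modified when the voted center falls outside the hull of
the positive keypoints — the signature of appearance change or of the object
leaving the view. The keypoints inside the detected box are then screened by
weight (threshold 0.5) into a candidate set, and:

* center inside the candidate hull and more than $\max(5, 10\%$ of model
  size$)$ candidates → the candidates are enrolled (distances de-scaled by
  $s_t$ so the model stays in template units; near-duplicates rejected) and
  features negative for 5 consecutive frames are removed — but never below
  half the enrollment size, which prevents model collapse during partial
  occlusion;
* center outside the candidate hull (or fewer than 3 candidates, so no
  hull exists) → the object is most likely gone: the tracker reports
  no-detection and enters **reset mode**;
* otherwise → the pose is kept but the model is left unchanged.

In reset mode model and segmentation are frozen (no trusted foreground
region exists) and each frame attempts a whole-frame re-detection; the
tracker returns to normal mode when at least 8 model keypoints match and
the accumulator peak reaches 25% of the template self-match peak. The count
threshold, removal policy and re-acquisition thresholds are engineering
choices (all configurable); their defaults were set once from the
behaviour they must produce — no update during absence, prompt
re-acquisition on full reappearance — and are exercised directly by the
out-of-view tests. A quality gate in normal mode (at least 4 vote-eligible
matches) prevents a handful of stray matches from fabricating a pose while
the object is gone.

## 2D to 3D lifting

With camera intrinsics and the metric depth $z_{\mathrm{ref}}$ of the object
on the enrollment frame, each 2D pose initializes a 3D pose
$(x, y, z, \phi, \psi, \hat\theta)$: the center is ray-cast at depth
$z = z_{\mathrm{ref}} / s$, $\hat\theta = \theta$ directly, and the two
out-of-plane rotations $\phi, \psi$ — unobservable in 2D — are retained from
the previous frame. The direction of the scale correction is a deliberate
choice: under a pinhole model apparent size is inversely proportional to
depth, so a larger $s$ means a nearer object; $s$ is cumulative relative to
the first frame ($s_1 = 1 \Rightarrow z = z_{\mathrm{ref}}$), not a
frame-to-frame ratio. Both conventions are stated here so downstream users
can invert if their scale definition differs. The external 3D refinement
stage is a pluggable hook (`refine_3d` in `run_sequence()`); the default
passes the initialization through unchanged.

## The keypoint detector

No feature detector was available in the supporting libraries, so the
package ships its own: difference-of-Gaussians extrema over a ladder of 7
smoothing scales ($\sigma = 1.3 \cdot 1.32^k$), with contrast (0.012) and
edge-curvature (ratio 10) rejection and parabolic sub-pixel refinement;
orientation from the smoothed 36-bin gradient-orientation histogram; and
the standard $4 \times 4 \times 8$ gradient-orientation descriptor sampled
in the keypoint's rotated, scale-normalized frame (Gaussian-weighted
trilinear binning, L2-normalized with 0.2 clipping). The scale ladder spans
a factor of ~5.4, enough for the cumulative scale changes the tracker is
specified for; descriptors tolerate the $1.32\times$ scale quantization.
Detection always runs on the full image; a region argument filters the
result afterwards, so enrollment descriptors are identical to what
whole-frame detection produces — this is what makes the template self-match
exact.

## The synthetic data generator

Real endoscopic benchmarks require robot kinematics for ground truth, so
the package ships a generator whose sequences have *exact* poses: a rigid,
corner-rich textured square (block mosaic plus contrast dots, guaranteeing
at least 30 enrollable keypoints) moves over a smooth blob-textured
background following an explicit per-frame pose program. Four presets mirror
the standard challenge regimes: occlusion by a second (achromatic,
instrument-like) patch, occlusion by a tissue-coloured blob, a full
out-of-view excursion of 30+ frames, and a 2000-frame slow drift in all of
$u, v, \theta, s$. Default conditions: $320 \times 240$ frames, an 80 px
target, additive Gaussian noise with $\sigma = 0.01$, and HSV-separable
palettes (tissue-red background near hue 0.03, instrument-blue target near
hue 0.58); a camouflage palette with overlapping hues exists for stress
testing. Rendering is bilinear, so recorded poses are exact up to ~0.5 px
of rasterization; evaluation tolerances must absorb that. Sequences are
deterministic given the config seed (textures from the seed, per-frame noise
from a seed derived from it), and frames are rendered on demand so long
sequences do not need to fit in memory.

What the generator does *not* emulate: specular highlights, smoke, motion
blur, articulation of the instrument tip, photometric drift. Passing the
synthetic suite therefore demonstrates the geometric and probabilistic
machinery — rotation/scale invariance, occlusion recovery, the Bayes
filter — not robustness to every photometric effect of real surgery.

## Evaluation

Center location error is the Euclidean distance to ground truth. Precision
curves report the fraction of frames within each threshold of a 0–50 px
grid (1 px steps; the grid is configurable and any monotone grid preserves
comparisons), with AUC the mean precision over the grid. Missed detections
are accounted for in both standard ways: as infinite error over the whole
sequence, or by restricting to the frames where all compared trackers
detect. Box statistics use quartiles with 1.5 IQR whisker fences, the
conventional reading of "most extreme points not considered outliers".

## Problem sizes and numerical checks

The shipped test-suite and acceptance-script runs use: 500 frames of
translation-only drift (mean center error, detection completeness), a
0–350° rotation sweep in 10° steps, a geometric scale ramp 1.0 → 1.5 over
200 frames, the 160-frame out-of-view preset, 50 random voting
configurations checked against an exhaustive dense accumulator scan, 100
random single-pixel cases against a scalar forward-filter implementation
(agreement to $10^{-9}$), 1000 random poses for pinhole round-trip
consistency ($10^{-6}$ px), and byte-identical repeated runs for
determinism. These sizes make the full suite complete in a few minutes on
one core while leaving every code path exercised.

## Known limitations

* The tracker assumes a rigid target; articulation is not modeled, and
  out-of-plane rotation is only absorbed (via the ring thickness and model
  adaptation), not estimated.
* One tracker instance tracks one target; a second instrument is simply an
  occluder.
* Histogram adaptation during long occlusions is frozen; if the scene
  illumination changes substantially while the object is absent,
  re-acquisition relies on the descriptors alone.
* The posterior is purely per-pixel; no spatial regularization is applied.
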