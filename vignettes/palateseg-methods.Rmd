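---
title: "Multiview segmentation of maxillary scans and rugae-anchored motion estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PalateSeg methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Orthodontic treatment planning needs two things from a textured intraoral
scan of the maxilla: a semantic segmentation that isolates every tooth and
the palatal rugae, and a way to measure how each tooth moved between a
pre- and a post-treatment scan. Direct global registration of the two
scans cannot measure tooth motion, because everything in the scan moved:
the teeth moved by treatment, and the mucosa deformed. The palatal rugae
are the exception — they are geometrically stable across treatment — so
they serve as the anchor: superimpose the two scans on the rugae patch,
then register each tooth individually, and the per-tooth residual
transform *is* the clinical tooth motion.

PalateSeg implements this pipeline end to end in R:

1. **Multiview projection.** A labeled, textured triangle mesh is rendered
   from ~100 random camera poses on an upper hemisphere into paired
   texture/label 2D images.
2. **2D semantic segmentation.** A SegNet-style encoder–decoder (with
   optional channel and spatial attention) labels every pixel.
3. **Label baking.** Per-pixel predictions from all views are
   back-projected onto mesh vertices and merged by majority vote, giving
   the 3D segmentation.
4. **Motion estimation.** Two-stage ICP — rugae first, then each tooth —
   yields one rigid transform per tooth, decomposed into three rotations
   and three translations.

Because clinical scan collections are not redistributable, the package
ships a synthetic dental-arch generator that produces labeled scans with
landmarks and *exact* ground truth, which is what the test-suite and the
verification experiments run on.

## Label scheme

The segmentation operates over 28 classes: 16 permanent teeth (including
third molars), 10 primary teeth, one rugae class, and one void class that
covers gingiva and image background alike. Void is black `[0,0,0]`; the
right central incisor is `[85,85,0]`. The remaining 26 palette colors are
a package convention: they are assigned deterministically from the
4-level lattice `{0,85,170,255}^3`, skipping the two reserved colors and
taking every other lattice point so consecutive classes are far apart in
RGB. Only two properties matter anywhere in the pipeline: the palette is
injective, and it is stable across versions. Label images are rendered
flat, unlit and without anti-aliasing, so decoding a label image is an
exact palette lookup — any off-palette pixel is a bug and raises an
error rather than being snapped to the nearest color.

## The synthetic arch generator

`generateArch()` emulates the geometry the pipeline cares about, not
dental anatomy. A polar-grid bowl forms the palatal vault; its anterior
midline region carries 3–5 transverse sinusoidal ridges (amplitude
0.5 mm by default) and is labeled *rugae* — the ridges give stage-1 ICP
non-trivial geometry to lock onto. Teeth are superellipsoid crowns placed
on a parabolic arch curve at equal arc-length slots sized proportionally
to per-class width presets (molars squat and wide, incisors blade-like),
so neighboring crowns do not interpenetrate. Each crown has an egg-shaped
cross-section (a 15% buccal bulge) and an offset apex: a plain
superellipsoid is invariant under a half-turn about its vertical axis,
which would make per-tooth rigid registration ambiguous — real crowns
have no such symmetry, and neither do these.

Texture is pink mucosa (`[225,130,120]`) and whitish enamel
(`[235,228,210]`) with per-vertex Gaussian noise (SD 6 on the 0–255
scale). Six landmarks are picked from actual mesh vertices (so they lie
on the surface exactly): the two most posterior tooth apices, the
central-incisor edge, and three median-raphae points of which the most
anterior is the incisive papilla.

Defaults are `nTeeth = 14` (full permanent dentition excluding third
molars), arch width 34 mm, depth 30 mm, ~4000 vertices — the scale of a
down-sampled clinical scan. The deliberate simplifications to keep in
mind when reading test results: crowns are smooth convex blobs (no
fissures, no contact-point anatomy), the mucosa has no texture detail
beyond noise, and scans of the same parameter set differ only by noise —
synthetic "patients" are far more alike than real ones. Passing tests
therefore validate the *pipeline machinery* (projection, baking,
registration, decomposition), not clinical-grade network accuracy.

`applyToothMotion()` displaces the vertex set of selected teeth by given
rigid transforms, never touches rugae (they are the stable reference by
definition), and can add a smooth radial-basis "mucosa wobble" to void
vertices, emulating soft-tissue change. `addScanNoise()` jitters along
vertex normals.

## Camera model and rendering

Cameras sit on a hemisphere of radius 2.5 bounding-sphere radii
(configurable), uniform in solid angle above a 15° minimum elevation,
optical axis at the scan center, roll uniform in [0, 2π). Both bounds are
package choices where the protocol is silent: below ~15° elevation the
projection degenerates to grazing slivers, and 2.5 radii keeps the whole
scan in frame at the default focal length of 0.85 × image width.
Per-view "perspective randomization" multiplies the focal length by a
uniform factor in `[1−j, 1+j]`.

Rendering is a software rasterizer (Rcpp): barycentric coverage tests
against pixel centers with a z-buffer, no back-face culling, affine
depth interpolation. A software renderer was chosen over OpenGL
deliberately — renders are bit-reproducible across machines, and the
texture and label images of a view share one rasterization pass, so
their coverage masks and pixel→face maps are identical by construction.
Texture shading is per-vertex (Gouraud) under three lighting modes: glow
(raw vertex color, shadow-free), ambient (Lambertian, one directional
light at infinity), and spot (Lambertian with inverse-square falloff
from two fixed positions, intensity randomized per render). Label images
are always flat and unlit; each covered pixel takes the palette color of
the *nearest vertex* (largest barycentric weight) of its front face, so
label boundaries are hard and no color mixing can occur. The default
image size is 256×256 (tests mostly run 64–128 to stay CPU-friendly).

## The segmentation network

The encoder is a chain of `conv(3×3) → batch-norm → ReLU → maxpool(2×2,
stride 2)` blocks; the decoder mirrors it with transposed-convolution
(2×2, stride 2) upsampling plus batch-norm and ReLU, additive skip
connections from the encoder feature of matching scale, a trailing 3×3
convolution per decoder level, and a 1×1 convolution + per-pixel softmax
head. The full-scale preset has the classic 13-convolution VGG-style
encoder (2+2+3+3+3 over five blocks); the desk-scale default is three
blocks of widths (12, 24, 48) at 64×64 input, trainable in minutes on
one CPU core.

Two attention placements are available. *Channel attention* is
squeeze-and-excitation: global average pool per channel → two-layer MLP
(reduction ratio 8) → sigmoid → per-channel gate. *Spatial attention*
pools the channel mean and maximum per position, convolves the two
planes with a 7×7 kernel, and gates every channel by the per-position
sigmoid map. `attention = "end"` applies both just before the softmax
head; `"center"` applies them at the encoder–decoder transition;
`"none"` is a strict subgraph of either. The attention internals
(reduction ratio, kernel size) follow the standard
squeeze-excitation/CBAM designs.

Everything — forward, backward, Adam — is implemented in R on BLAS
matrix products (im2col convolutions), with gradients verified against
finite differences in the test-suite to ~1e-10 relative error. With
batch size 1, batch normalization at train time normalizes each channel
over its spatial extent and maintains running moments for evaluation.
The loss is per-pixel cross-entropy; optional per-class weights (a
config toggle, off by default) counter the severe class imbalance
between the large void/rugae regions and the small tooth blobs. The
optimizer is Adam with a multiplicative per-epoch learning-rate decay —
"decay 0.995" is interpreted as `lr_epoch = lr0 · 0.995^epoch`.

Training data hygiene: samples are tagged with their scan id, and a scan
contributing images to more than one of train/validation/test is an
error — generalization is always measured on unseen scans.

## Metrics

For a class $c$, with prediction pixels $o_i$ and target pixels $y_i$,

$$\mathrm{IoU}_c=\frac{\sum_i [o_i{=}c] \wedge [y_i{=}c]}{\sum_i [o_i{=}c] \vee [y_i{=}c]}$$

summed over all pixels of one image (or all vertices of one mesh for the
3D variant). The mean IoU of an image averages over classes present in
the ground truth *or* the prediction; classes absent from both are
undefined and excluded (score tables print them as "-"). Dataset-level
scores are **averages of per-image means**, never pixel-pooled — the
test-suite asserts the distinction on a constructed counterexample.
Precision is the macro average over predicted classes of correctly
detected over predicted pixels. The *adult-teeth mean IoU* restricts the
class mean to permanent teeth, excluding third molars, primary teeth,
rugae and background.

## Label baking

Back-projection uses the saved camera poses. Two observation rules are
implemented:

* **Ownership (default).** The mesh is re-rasterized at the saved pose.
  Every covered pixel is *owned* by the nearest vertex of its front
  face — exactly the vertex whose label the ground-truth render would
  show at that pixel — and each vertex observes the majority predicted
  label over the pixels it owns in that view. The payoff is an exact
  closed loop: baking ground-truth label renders reproduces the
  ground-truth labels on every observed vertex, with no leakage across
  label boundaries, which the test-suite asserts at mean vertex IoU = 1.
* **Depth test.** The classic shadow-mapping rule — a vertex is visible
  iff its projected depth matches the view's depth buffer within a
  tolerance (default: 1e-3 of the scene diameter plus one pixel of
  surface-slope allowance), and it observes the predicted label at its
  pixel. This rule is kept because it needs only the depth buffer, but
  at practical resolutions a boundary vertex's pixel is often owned by a
  neighboring vertex across the label boundary, which caps achievable
  vertex IoU; the ownership rule removes exactly that error mode.

Votes accumulate over views into a per-vertex histogram
(`accumulateVotes()`: one observation per vertex per view, so the
visibility count equals the total vote count); `finalizeLabels()` takes
the per-vertex majority, breaking ties by the lowest label id so the
result is deterministic, and assigns void to vertices never observed in
any view. Nearest-label propagation along mesh edges for unseen
vertices was considered and deliberately left out of the default path:
unseen vertices are overwhelmingly on the mesh underside, where guessing
is worse than an explicit void. `segmentComponents()` splits the labeled
mesh into per-label submeshes, assigning each face to the majority label
of its corners (ties to the lowest id).

## Motion estimation

**Frame.** The occlusal plane passes through the two molar-cusp
landmarks and the incisor edge; the sagittal plane contains the
least-squares line through the median-raphae points and the occlusal
normal. The frame is right-handed with z normal to the occlusal plane
(away from the palate), x along the occlusal–sagittal intersection
pointing anteriorly, and origin at the normal projection of the incisive
papilla onto the occlusal plane.

**Two-stage ICP.** Stage 0 aligns the post-scan's anatomical frame onto
the pre-scan's (rough initialization). Stage 1 runs point-to-point ICP
(nearest neighbours → det-corrected SVD/Kabsch fit, iterated to a 1e-10
mm RMS-improvement tolerance) on the *rugae vertices only*; the
resulting transform aligns the entire post scan to the stable patch.
Stage 2 registers each tooth present in both scans, initialized at the
stage-1 transform plus a centroid shift. The world-frame motion of a
tooth is `H1 · H2⁻¹` (stage-1 global alignment times the inverse
per-tooth alignment), which cancels any common rigid motion of the two
scans — the reported parameters are invariant to how either scan sat in
world coordinates, and are expressed in the pre-scan anatomical frame
when landmarks are supplied.

Point-to-point ICP is a local optimizer, and compact near-prismatic
crowns offer shallow wrong basins. When a tooth's residual RMS exceeds
0.05 mm (far above machine precision for clean data, far below scanner
noise for real data), registration restarts from principal-axes
alignments (all four proper sign choices — exact up to sampling for
clean clouds) and a coarse grid of single-axis rotations about the
centroid, keeping the best residual. Optional trimming (dropping the
worst fraction of correspondences in each fit) robustifies the rugae
stage against mucosa deformation at the patch border; it is off by
default and exposed as `trimFraction`.

**Euler decomposition.** A motion is composed as
`H = Tz·Ty·Tx·Rz(α)·Ry(β)·Rx(γ)`. The package fixes the axis-rotation
sign convention — x- and z-rotations clockwise, y counter-clockwise
about right-handed axes — under which the inverse kinematics are exactly

$$\beta=-\sin^{-1}R_{31},\qquad
\gamma=-\tan^{-1}(R_{32}/R_{33}),\qquad
\alpha=-\tan^{-1}(R_{21}/R_{11}),$$

implemented with two-argument arctangents (the plain ratios lose the
quadrant whenever $R_{33}<0$ or $R_{11}<0$). The convention was chosen
by one requirement: `decomposeTransform()` must invert
`composeTransform()` exactly, which the suite verifies to 1e-9 over a
thousand random draws. The $|\beta|\le 90°$ branch is always selected —
a tooth rotating more than 90° is clinically implausible — and at gimbal
lock ($|R_{31}|=1$) only $\alpha \mp \gamma$ is determined, so γ is set
to 0, the residual folded into α, and a flag raised; reconstruction
remains exact there too. Angles are reported in degrees, translations in
millimetres.

**Verification experiment.** `motionVerificationExperiment()` applies a
distinct known rigid transform (axis–angle rotation ≤ 15° about the
crown centroid, translation ≤ 3 mm) to every tooth of a clean 14-tooth
synthetic arch, runs the full two-stage pipeline, and counts teeth whose
recovered rotation agrees within 0.1° (and translation within 0.01 mm).
On clean synthetic scans the recovery is exact to numerical precision
for all 14 teeth; `scripts/acceptance.R` re-runs exactly this.

## Numerical choices and degenerate inputs

* PLY I/O writes coordinates at full double precision (ascii `%.17g`,
  binary float64), so write → read roundtrips are bit-exact; reading
  accepts float or double, ascii or binary little-endian, triangles
  only, and requires per-vertex RGB.
* Rasterization skips degenerate (zero-area) triangles and any face with
  a vertex at or behind the camera; cameras orbit outside the scan so
  genuine near-plane clipping cannot occur.
* `buildFrame()` rejects collinear occlusal landmarks and raphae lines
  normal to the occlusal plane.
* ICP requires ≥ 3 non-collinear points per cloud.
* Vote ties and face-label ties break to the lowest label id;
  identical inputs always reproduce identical outputs.
* Every randomized routine takes an explicit seed; stage seeds in the
  pipeline are derived deterministically from one global seed.

## Problem sizes used by the test-suite

The suite exercises the study conditions at sizes a single CPU core
handles comfortably: synthetic arches of ~1200–4000 vertices; 100 views
at 128×128 for the baking closed loop and the dataset-count check (the
full 100-scan × 100-view dataset generation runs in minutes); the
14-tooth verification experiment at default resolution; and the network
smoke tests at 64×64 with the three-block encoder — single-image
overfitting plus a 20-pair training run under the reference
hyperparameters (learning rate 1e-4, decay 0.995, batch size 1) with a
held-out scan. The smoke-training protocol constrains camera poses to
anterior views (azimuth 80–100°, elevation 55–75°, roll ±20°, focal
1.15 × width): with unconstrained poses the tooth-identity task is
pose-invariant in a way a desk-scale network cannot resolve from 20
images, whereas the constrained protocol tests the same machinery —
rendering, augmentation, training loop, metrics — at a difficulty
matched to the compute budget. Inverse-frequency class weights
(normalized to pixel-mean 1) are switched on there for the same reason.

## Known limitations

* The synthetic generator does not model malocclusion, erupting or
  missing teeth (beyond omitting classes), scanner holes, or specular
  texture; conclusions about real-scan accuracy require real scans.
* The renderer has no texture atlas support (per-vertex color only) and
  no physically based shading.
* The network trains on CPU at desk scale; the 13-layer full-scale
  configuration is provided but is only practical with serious compute.
* Whether point-to-point or point-to-plane ICP better matches clinical
  metrology software is unknowable from the outside; point-to-point was
  chosen for robustness and simplicity, with restarts compensating for
  its narrower basins.
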