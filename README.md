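# PalateSeg

3D semantic segmentation of textured maxillary scans and measurement of
orthodontic tooth movement, in R.

Intraoral scanners produce textured triangle meshes of the palate and
teeth. Two questions drive orthodontic follow-up: *which vertices belong
to which tooth* (and to the palatal rugae), and *how far did each tooth
move* between a pre- and a post-treatment scan. PalateSeg answers both
with a multiview pipeline:

1. the labeled, textured mesh is projected into 2D images from ~100
   random camera poses on a hemisphere (software rasterizer, z-buffer,
   three lighting modes, randomized perspective);
2. a SegNet-style encoder–decoder — conv/BN/ReLU encoder with 2×2 max
   pooling, transposed-convolution decoder with additive skips, optional
   channel (squeeze-excitation) and spatial attention before the softmax
   head or at the bottleneck — labels every pixel with one of 28 classes
   (16 permanent teeth, 10 primary teeth, rugae, void);
3. per-pixel predictions are *baked* back onto the mesh: every covered
   pixel votes for the vertex that owns it, votes accumulate across
   views, and the per-vertex majority gives the 3D segmentation;
4. tooth motion is estimated by two-stage ICP anchored on the palatal
   rugae (the geometrically stable reference): rugae-patch alignment
   first, then per-tooth registration. Each tooth's rigid transform
   `H = Tz·Ty·Tx·Rz(α)·Ry(β)·Rx(γ)` is decomposed by inverse kinematics

   ```
   β = −asin(R31)   γ = −atan2(R32, R33)   α = −atan2(R21, R11)
   ```

   into three rotations (degrees) and three translations (mm), with the
   |β| ≤ 90° branch selected and gimbal lock handled explicitly.

Segmentation quality is scored with per-class intersection-over-union
(IoU), mean IoU over present classes, pixel accuracy, precision, and an
adult-teeth mean IoU restricted to permanent non-third-molar classes;
dataset scores are averages of per-image means, never pixel-pooled.

Clinical scans are not redistributable, so the package includes a
synthetic dental-arch generator (`generateArch()`): a palatal dome with
a ridged rugae patch, superellipsoid crowns on a parabolic arch with
per-class size presets, per-vertex labels, anatomical landmarks, texture
noise, known per-tooth motion (`applyToothMotion()`) and scanner noise
(`addScanNoise()`). All tests and verification experiments run on it.

## Worked example: known-transform motion recovery

```r
library(PalateSeg)

ex <- motionVerificationExperiment(seed = 1)
ex$nTeeth              # 14
ex$nRotationRecovered  # 14
max(ex$table$rotErrDeg)
# [1] 2.414837e-06
max(ex$table$transErrMm)
# [1] 2.4869e-14
```

A 14-tooth synthetic arch is generated; every tooth is displaced by a
distinct known rigid transform (rotation up to 15° about its centroid,
translation up to 3 mm) while the rugae stay fixed; the two-stage ICP
pipeline runs and each recovered transform is compared with its ground
truth. All 14 rotations are recovered to micro-degree accuracy and the
translations to machine precision — the motion machinery is exact on
clean data.

The segmentation loop in miniature:

```r
arch  <- generateArch(archParams(seed = 7))
bs    <- boundingSphere(arch$mesh)
poses <- sampleCameraPoses(100, seed = 3, radius = 2.5 * bs$radius,
                           center = bs$center, width = 128, height = 128)
obs   <- lapply(poses, function(p)
           bakeView(arch$mesh, p, labelImage(renderView(arch$mesh, p))))
tally <- accumulateVotes(obs)
lab   <- finalizeLabels(tally)
metrics3D(lab, meshLabels(arch$mesh),
          subset = tally$visibility > 0)$meanIoU
# [1] 1
```

Rendering 100 ground-truth label views and baking them back reproduces
the vertex labels exactly on every observed vertex (97–98% of the mesh;
the remainder is the unseen underside, which stays void).

For the full staged pipeline (generate → render → train → predict →
bake → evaluate → motion) see `cmdGenerate()` and friends, or the thin
CLI at `inst/cli/palateseg`:

```sh
Rscript inst/cli/palateseg all --workdir run1 --seed 7
Rscript inst/cli/palateseg motion --workdir run1 \
    --pre pre.ply --post post.ply \
    --pre-landmarks pre.txt --post-landmarks post.txt
```

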