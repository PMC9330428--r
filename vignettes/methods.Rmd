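---
title: "Coarse-to-fine kidney and stone segmentation: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine kidney and stone segmentation: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The segmentation scheme

`nephroseg` implements a dependent, two-stage 3D segmentation pipeline for
unenhanced abdominal CT. The premise: kidney stones are tiny hyperdense
objects and direct ("independent") 3-class segmentation of a whole abdomen
drowns them in background. The dependent scheme first localizes the
kidneys coarsely at reduced resolution, then segments kidney and stone
finely inside per-kidney crops, where the class balance is orders of
magnitude friendlier.

**Preprocessing.** CT intensities are clamped to the soft-tissue window
[−135, 215] HU (stones saturate at the top of this window, which is what
makes them maximally bright after normalization), z spacing is resampled
to 1.25 mm (linear for images, nearest for labels), and each volume is
min–max normalized. Order: window → resample → normalize → resize, so
outputs stay in [0, 1]. Normalization is per volume, not per cube or
dataset-global: per-volume is self-contained at inference and is the
standard choice once a fixed HU window has made the scale comparable
across scanners. A constant volume (a blank padding cube is the realistic
way to hit this) normalizes to all zeros with a warning rather than an
error.

**Stage 1.** The working volume is resized in-plane to (256, 256),
center-cropped to (192, 192) — a window that comfortably contains both
kidneys — and tiled along z into cubes of length 96 with stride 48. A
2-class network scores each cube; overlapping scores are fused by
averaging *before* the argmax. The averaging rule is a deliberate choice
(the stitching fusion is not dictated by the scheme itself); it is the
standard sliding-window practice and, unlike argmax-of-argmax, it is
exactly testable against a brute-force per-voxel oracle.

**Kidney separation.** The coarse mask, restored to the working
resolution by nearest-neighbor upsampling (nearest preserves the label
set; linear-then-threshold would need an arbitrary threshold), is split
into 26-connected components. Components below 2 cm³ are discarded as
speckle and the two largest survivors are kept. Each yields a ROI box:
full component z extent, in-plane (160, 160) centered on the component
centroid, clamped to the image when it fits and zero-padded when it does
not. Kidneys wider than 160 voxels in-plane are truncated rather than
rescaled — fidelity to the fixed stage-2 input shape — and this is a known
failure mode for pathologically enlarged kidneys.

**Stage 2.** Inside each ROI, cubes of length 64 / stride 32 are scored by
a 3-class network; stitched predictions from all ROIs are overlaid with
precedence stone > kidney > background (numeric max over labels, so
overlap resolution is associative). The final mask is resampled back to
the input z grid. If stage 1 finds no kidney at all, the case returns an
all-background mask with a machine-readable failure flag — never an
exception — because a cohort evaluation must be able to count such cases
as failures rather than crash.

**One-stage baseline.** The independent arm uses the stage-1 geometry with
3 output classes. Several comparison designs are defensible; this package
takes the minimal-change one: identical preprocessing, crop, cube
geometry, budget and seeds, differing only in what the network must
predict.

## Backbones, implemented from scratch

This environment offers no neural-network framework in R or Python, so the
two reference backbones are built directly in RcppArmadillo:

* **3D U-Net**: depth-`d` encoder–decoder; each level is two 3×3×3
  convolutions with batch normalization and ReLU; 2× max-pooling down,
  nearest-neighbor upsampling with skip concatenation up; 1×1×1 head.
* **Res U-Net**: the same skeleton with residual units — the second
  conv-BN output is summed with a (1×1×1-projected) shortcut before the
  block ReLU.

Convolutions are implicit-GEMM: the volume is zero-padded once, each of
the 27 kernel taps becomes a single linear index shift, and work is chunked
over rows so the shifted operand stays cache-resident while `sgemm`
accumulates taps. No im2col matrix is ever materialized; one CPU core
sustains roughly 100 GFLOP/s on the desk-scale cubes. Batch normalization
uses per-cube statistics during training (gradient accumulation provides
the effective batch; with one cube per forward pass this behaves like
volume-wise instance normalization, the usual situation for patch-based 3D
segmentation at small batch) and running statistics (momentum 0.1) in eval
mode. Correctness is not taken on faith: the test suite contains a
double-precision pure-R replica of both architectures, and the compiled
forward pass and analytic gradients must match it to ~1e−5 (forward,
exact; gradients, against central differences of the replica).

Channel widths are free parameters here; the reference profile (depth 3,
base 8 at full scale; depth 2, base 8 at desk scale) was chosen once as
the smallest configuration that trains stably on CPU.
Any externally registered scorer satisfying the cube→scores contract plugs
into the pipeline unchanged; interchangeability is a tested property.

## Training recipe

AdamW (β₁ 0.9, β₂ 0.999, decoupled weight decay 0.001 applied to
convolution weights only), initial learning rate 0.001, combined loss
`softDice + crossEntropy` with equal weights and Dice smoothing constant 1
(the combination is given; the weights and smoothing are this package's
choices — equal weighting is the common default and smoothing 1 makes the
empty-class case exact), ReduceLROnPlateau (factor 0.1, patience 10,
min 1e−5 — plateau parameters unpublished, so defaults are exposed in
config), best checkpoint by minimum validation loss. Splits are always at
case level — a 7:3 train/test split with 5-fold cross-validation over the
training pool — so no volume can contribute cubes to both sides; the
leakage property is asserted in tests.

Augmentation applies only to labeled cubes (cubes containing foreground),
because its stated purpose is positive/negative balance: random in-plane
rotation of 0 ± 10°, horizontal inversion with probability 1, and their
composition. "Horizontal" is interpreted as the internal x axis and is
configurable, since the anatomical meaning depends on the source data's
orientation convention. The affine is restricted to rotation (only an
angle is specified; translation/scale/shear are not used). By default
augmentation runs on the fly — each labeled cube receives one uniformly
chosen variant (none/affine/flip/flip+affine) per epoch — with
`make_augmented_set()` available to materialize the fixed ×4 expansion.
Stage-2 training crops come from ground-truth kidney ROIs; inference uses
stage-1 predicted ROIs. Training on predicted ROIs would compound stage-1
noise into the stage-2 objective; the cost is a train/test mismatch that
the end-to-end test quantifies implicitly.

## The synthetic phantom world

The generator emulates exactly what the pipeline's geometry needs: an
elliptic soft-tissue body (−80 HU, fat-like) surrounded by air (−1000 HU),
two disjoint kidney-shaped ellipsoids (35 HU) at lateral offsets from the
midline, and rasterized spherical stones (600 HU) placed strictly inside a
kidney, non-overlapping, with additive Gaussian noise (sd 10 HU). The
desk profile is 64×96×96 voxels at (1.25, 1, 1) mm — the stage-1 working
resolution of the CPU-scale acceptance run — with kidney semi-axes
z ∈ [14, 18], y,x ∈ [10, 13] mm placed so both kidneys fit the 64-crop the
way real kidneys fit the 192-of-256 crop; the paper-scale profile is
512×512 in-plane with clinical spacing ranges. Stone diameters {3, 6, 9}
mm span the three volume classes (small < 28 mm³ ≤ medium < 315 mm³ ≤
large). Truth volumes are rasterized volumes (voxel count × voxel volume),
not analytic sphere volumes, so tests compare like with like; size classes
are derived from the rasterized volume for the same reason.

What the phantom deliberately omits: other organs and bone, partial-volume
blur, beam hardening, streaks, motion, anisotropic in-plane spacing
variation within a case, and stones touching the collecting system or
kidney boundary. Consequently a green end-to-end test establishes that the
*pipeline* — geometry, training loop, loss, ROI logic, stitching,
evaluation — works and that the dependent scheme's mechanism operates; it
does not establish clinical performance: Dice values attainable by
GPU-scale training on real clinical cohorts are not reproduction targets
at desk scale.

The diameter-based class labels commonly quoted alongside these volume
thresholds (0–6, 6–20, >20 mm) are not sphere-consistent with
them; the volume thresholds are authoritative here (a voxel
pipeline measures volumes), with half-open boundaries [0,28), [28,315),
[315,∞).

## Numerical and degenerate-case choices

* Cube tiling is end-aligned: starts at multiples of the stride, with a
  final cube at `Z − L` when the last stride-aligned cube would overrun,
  and zero-padding when `Z < L`; every slice is covered for every `Z ≥ 1`
  (property-tested exhaustively for Z ∈ [1, 300]).
* Stitching averages scores; voxels covered once carry their score
  unchanged.
* Empty-vs-empty Dice is 1.0 and zero-denominator sensitivity/specificity
  are 1.0, so stone-free cases with correctly empty predictions are not
  penalized.
* Per-stone Dice for the size-stratified table uses greedy
  maximum-overlap matching between truth and predicted stone components
  (instance matching is otherwise undefined); unmatched truth stones score
  0.
* The per-case success criterion behind success-rate reporting has no
  single canonical definition; the threshold (default Dice ≥ 0.5) is
  always reported alongside the rate and never hard-coded.
* NIfTI volumes are reoriented on read to a canonical internal (z, y, x)
  frame using the sform (preferred) or qform; the reorientation is logged
  so coordinates can be replayed to the source frame. The package's own
  writer emits axis-aligned canonical files. No orientation convention is
  assumed beyond the header, since none is promised for external masks.

## The scaled comparison experiment

The dependent-vs-independent ordering experiment at its stated size
(10 seeded runs, ~1–2 h) exceeds a per-commit CPU budget; the suite runs
it scaled down: 3 seeds, 8 phantoms of 48×80×80 carrying 2–3 stones of
5–8 mm each, 16 epochs, identical budget and seed across arms, pass rule =
two-stage mean stone Dice ≥ one-stage in at least 2 of 3 seeds (the
majority, same direction as the full-size criterion). Earlier, smaller
scalings (48×64×64, 8 epochs, 1–3 stones of 3–6 mm; then 10 epochs) were
discarded because *neither* arm learned stones at all there — both arms
scored ≈ 0 and the comparison was vacuous (stage 2 received an order of
magnitude fewer optimizer updates than the working desk run); the world
was re-sized to the smallest setting where the two-stage arm demonstrably
learns stones, and then frozen. At this scale the one-stage arm still
learns kidneys well — the stones, not the organ, are what the
coarse-to-fine cascade rescues.

## Known limitations

* The backbones are compact reference implementations; SegNet,
  DeepLabV3+ and UNETR enter only through the registry contract and are
  not reimplemented.
* Stage-1 failure handling is all-or-nothing per case; there is no
  fallback localization.
* The implicit-GEMM engine is single-threaded float32; reproducibility is
  bitwise for fixed BLAS and thread count.
* CSV/NIfTI are the only interchange formats; DICOM ingestion is out of
  scope by design.
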