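---
title: "Dilated dense U-nets for hippocampal subfield segmentation: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dilated dense U-nets: models, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Hippocampal subfields (CA1, CA2/3, subiculum, CA4/dentate gyrus, uncus) are
small, thin, mutually adjacent structures whose tissue contrast on MRI is
weak — especially in infants, where myelination is incomplete and the
anatomy changes rapidly. `ddunet` implements a family of 3D fully
convolutional networks for voxel-wise multi-class labeling of such
structures from co-registered multi-modality volumes (typically T1w + T2w),
together with the full pipeline around them: localization and intensity
preprocessing, patch sampling, optimization, overlapped sliding-window
inference with majority-vote fusion, connected-component false-positive
removal, and Dice/ASSD evaluation.

# Models

All three variants share a U-net skeleton with exactly three 2×2×2 max
poolings (stride 2) on the contracting path and three 4×4×4 transposed
convolutions (stride 2) on the expanding path. Every resolution level holds
a pair of padded 3×3×3 convolutions, each followed by batch normalization
and a ReLU; a final 1×1×1 convolution emits `K` score maps (background
included). Padding keeps spatial dimensions fixed, so the output grid
equals the input grid, and the 4×4×4/stride-2/padding-1 transposed
convolution doubles dimensions exactly — which is what lets skip
connections concatenate without cropping.

The classification rule is the maximum-posterior label
`L(x) = argmax_k p_k(x | theta)` where `p_k` is the softmax of the final
score maps.

**Dilated convolution.** The `l`-dilated convolution of a signal `F` with a
cubic filter `h` on `[-r, r]^3` is `(F *_l h)(p) = sum_{s + l t = p}
F(s) h(t)`; `l = 1` recovers ordinary convolution. A stride-1 stack with
kernel sizes `k_i` and rates `l_i` has cubic receptive field of side
`1 + sum_i l_i (k_i - 1)`: rates 1, 2, 4 over 3×3×3 kernels give side 15
without a single pooling, i.e. context grows exponentially while the
spatial resolution stays full. `dilated_conv3d()` implements this sum
literally as a reference; the network layers use an im2col+GEMM backend
(C++ for the unrolling, BLAS for the multiply) that is tested against the
reference — the backend follows the cross-correlation index convention, so
the equivalence tests mirror the kernel.

**Dilated dense block.** `L` stride-1 dilated 3×3×3 convolutions (rates
1, 2, 4 by default), each followed by BN, ReLU and dropout. Layer `i`
receives the channel concatenation of the block input and all previous
layer outputs; the block output is the concatenation of the input with
every layer output, so `C` input channels become `C + L·g` with growth `g`.
The block thus aggregates features at several receptive-field scales at
full resolution.

**The three variants.**

* `unet3d` — the plain skeleton: all three skip connections concatenate
  directly.
* `dunet` — identical except that the *middle* skip (the maps before the
  second pooling) passes through the dilated dense block before
  concatenation. The first and third skips concatenate directly. The
  rationale: the mid-level contracting features are semantically far from
  the expanding-path features they join; multi-scale re-encoding bridges
  that gap.
* `resdunet` — `dunet` with every pair of path convolutions wrapped in a
  post-activation residual unit: `ReLU(BN(conv2(ReLU(BN(conv1 x)))) +
  shortcut(x))`, the shortcut being identity, or a 1×1×1 projection when
  the channel counts differ.

Because the dense block adds parameters, counts order as
`resdunet ≥ dunet > unet3d` at identical channel schedules — a structural
invariant the tests assert.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `base_channels` | 32 | kernels at level 1; schedule doubles per level (32/64/128, bottom 256) |
| `dense_layers` L | 3 | dilated convolutions in the dense block |
| `dilation_schedule` | 1, 2, 4 | per-layer rates; receptive field side 15 |
| `growth` g | level-2 channels | channels added per dense layer |
| `dropout_rate` | 0.5 | after each dense-block convolution, training only |
| patch size R | 24 (32 high-res preset) | training/inference window side, voxels |
| train stride | 2 | candidate-patch lattice |
| inference stride | 8 | sliding-window overlap |
| margin | 32 voxels | bounding-box safety margin |

The per-level kernel counts are printed inside figure rectangles in the
source publication and are not recoverable from its text; the doubling
schedule above is the standard U-net convention and is fully configurable
(`channel_schedule`), which is sufficient for ablation comparisons since
those only require identical schedules across variants. Two further
under-specified points were resolved as: no transition convolution after
the dense block (its raw concatenation joins the expanding path), and the
dense-block output is concatenated alongside the up-sampled features,
mirroring the other skip levels.

# Training

The loss is the multinomial softmax cross-entropy summed over voxels,
computed with a log-sum-exp stabilization. Optimization is Adam with batch
size 5, base learning rate 1e-4 decayed by γ = 0.1 every 10,000 iterations,
weight decay 5e-4 and "momentum" 0.9, stopping at 60,000 iterations — the
published schedule, which `default_config("paper")` encodes. Two choices
need interpretation: with Adam, "momentum 0.9" maps onto the first-moment
coefficient β₁, and weight decay is coupled classically as an L2 term added
to the gradient (the semantics of the Caffe solver generation these
settings come from). Batches are uniform random draws with replacement
across all subjects' patch sets; weights are He-normal initialized,
seedable. When the training-Dice monitor is active, `train_network()`
keeps a snapshot of the best-monitored weights and can additionally
perform deterministic random restarts: an attempt that exhausts its
per-attempt iteration allowance without reaching the target is abandoned,
the weights are re-drawn from the running RNG stream, and optimization
starts over within the same overall budget; the returned network is the
best-monitored state across attempts. Small networks on small cohorts
occasionally initialize into a basin that never leaves the dominant
classes; fresh starts are the cheap, classical cure (the `nstart` idea),
they preserve seeded reproducibility, and they are off by default so the
full-scale schedule is untouched.

Patch extraction follows the published recipe exactly: slide an R³ window
with stride 2 over the cropped volume, keep every window containing at
least one labeled voxel, number the candidates in raster order, permute
them randomly, and keep the first half (`floor(n/2)` for odd `n`; the
source is silent on parity). Patches are sampled once per subject, not
re-drawn per epoch, matching the text's description; each subject's
permutation seed is derived from the global seed so runs are reproducible
under subject reordering.

# Preprocessing

The foreground bounding box is the min/max voxel extent of the training
labels plus a 32-voxel margin per direction, clamped to the grid; it is
computed once from the training subjects and applied unchanged at
prediction time (the assumption — that it also covers unseen subjects — is
tested to hold by construction on the phantom cohorts). All volumes are
cropped to it. Intensities are histogram-matched per modality to the first
training subject (by sorted ID; the reference subject is not named in the
source) by a monotone quantile mapping. The pipeline default uses 11
landmark quantiles (deciles plus the extremes, the classic MRI
intensity-standardization practice) rather than a dense map:
`histogram_match()` supports any knot count, but a dense quantile map is
brittle when subjects differ in tissue *proportions* — the map then splits
a minority tissue's intensity plateau across two reference plateaus,
breaking the class/intensity correspondence across subjects. Few-landmark
matching keeps the transfer piecewise-affine and tissue-preserving; on the
phantom cohorts this is the difference between a learnable and an
unlearnable training set. Training volumes are
left-right flipped to double the subject list; subfield class IDs are
side-agnostic (one ID covers the left and the right instance), so no
relabeling occurs on flip — an explicit assumption. No z-scoring or bias
correction is applied here: inhomogeneity correction and registration are
upstream concerns.

# Inference and post-processing

Prediction slides an R³ window with stride 8; windows are forwarded in
eval mode (frozen batch-norm statistics, no dropout), each window's argmax
labels cast one vote per voxel, and the final label is the vote plurality.
Ties break to the smallest class index, which also means background wins
any tie it participates in — the conservative direction for false
positives. Voting operates on hard labels, the literal reading of majority
voting; probability averaging would be a different fusion rule and is not
what this pipeline does. When `dim − R` is not a stride multiple an
end-aligned window is added so every voxel is covered at least once.

Patch-trained networks only ever see local context, so structures that
locally resemble a subfield (e.g. parts of the caudate) can surface as
small isolated islands far from the hippocampi. The post-processing step
binarizes the foreground, labels connected components (26-connectivity by
default; the source's "non-zero neighbors" is ambiguous, 6 is available),
and keeps the two largest — left and right hippocampus — zeroing the rest.
Size ties at the cut break deterministically toward the component with the
smaller first linear voxel index. `n_keep` is configurable since a crop may
contain a single hippocampus.

# Evaluation

Per class: Dice `2|A∩B| / (|A| + |B|)` and the average symmetric surface
distance, the symmetrized mean of nearest boundary-to-boundary Euclidean
distances. The defining formulas leave the discretization open; here a
boundary voxel is a foreground voxel with at least one background
6-neighbor (the outside of the grid counts as background), and distances
are between voxel centers in physical units (index × spacing, mm by
default; pass `spacing = c(1,1,1)` for voxel units — the source does not
state its unit). A class absent from both volumes has undefined Dice; a
class empty in either has undefined ASSD; both are reported as missing and
excluded from the unweighted class average rather than coerced to 0. The
production ASSD uses a compiled nearest-distance kernel and is tested
against a pure-R double loop over boundary voxels.

# The phantom generator

`generate_phantom()` builds what the pipeline assumes of real data, at desk
scale: a 52×44×36 grid (1 mm isotropic) with two mid-sagittally mirrored
ellipsoids (semi-axes ≈ 6×11×5.5 voxels) partitioned into K−1 contiguous
compartments, two intensity channels, and small isolated distractor
structures. Default K = 6 mirrors the five-subfield infant labeling; a
4-class preset mirrors the adult labeling. The default partition slices
each ellipsoid into equal bands along its long axis — anatomically the
subfields are arranged largely along the hippocampal long axis, with the
uncus anterior-most — which yields compartments thick enough that
per-class Dice is a meaningful learning signal; a concentric-shell
partition is available as an option. Modality 1 separates all class means;
modality 2 is deliberately partially degenerate (several classes share a
mean), so the value of a second modality can be probed qualitatively.
Voxels get class mean + Gaussian noise (SD 4) under a smooth multiplicative
quadratic bias field (±10%). Distractors are small spheres carrying a
mid-subfield intensity profile but background labels, placed at least 10
voxels from the hippocampal foreground — bait for the false-positive
filter. Cohorts jitter geometry and intensity means per subject under
derived seeds.

What the phantoms are *not*: MRI. There is no k-space model, no partial
voluming, no anisotropic point-spread, and the compartment geometry is far
cleaner than real subfield boundaries. Tests passing on phantoms establish
that the machinery is correct and learnable, not that any particular Dice
level transfers to real cohorts.

# Numerical choices and degenerate inputs

* Convolution padding is `rate·(k−1)/2` per side so stride-1 layers
  preserve dimensions; inputs must be divisible by 8 (three poolings).
* Loss uses log-sum-exp; labels outside `1..K` and non-finite scores are
  errors, and a non-finite training loss aborts with a diagnostic rather
  than continuing.
* Histogram matching collapses duplicated quantile knots before
  interpolation; a constant moving image is shifted to the reference
  median with a warning.
* Argmax ties (labeling and voting) always resolve to the smallest class
  index; component-size ties to the smallest first voxel index. Both are
  deterministic by construction.
* Batch-norm in eval mode uses running statistics (momentum 0.1), so
  prediction is deterministic and independent of window batching — a
  tested invariance.

# Problem sizes used by the test suite

The correctness tests run the full-size architecture (base 32, 24³ and 32³
inputs) only through single forward passes. Learning-dependent properties
use a reduced configuration chosen after a pilot run: ResDUnet with
`base_channels = 8`, 16³ patches, batch 4, learning rate 1e-3, training
Dice monitored every 50 iterations with early stopping at 0.90, up to two
plateau-triggered restarts, budget 2,000 iterations — on two phantom
subjects this typically converges within 300–500 iterations of a
successful start. The end-to-end smoke chain uses `default_config("smoke")`
(base 4, 50 iterations). These sizes are the package's desk-scale test
conditions; the published full-scale schedule remains available as
`default_config("paper")`.

# Known limitations

* The convolution backend is single-threaded im2col+GEMM: correct and
  adequate at desk scale, not competitive with GPU frameworks; full-scale
  60,000-iteration training is out of reach here and the published
  cohort-level Dice tables are not reproduced by this package.
* Batch-norm statistics are per-batch with small batches, which adds
  noise early in training.
* One dense block at one skip level, as specified; no deep supervision,
  Dice-style losses, class-weighted sampling, test-time augmentation or
  model ensembling.
* The phantom generator is a pipeline test instrument, not an MRI
  simulator.
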