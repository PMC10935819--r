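---
title: "Methods: synthetic pages, adapter segmentation, and mask refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic pages, adapter segmentation, and mask refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chemseg extracts individual molecular-structure depictions from document
page images. The system has three layers: a synthetic page/mask generator
that manufactures training and evaluation data; an adapter-augmented
vision-transformer (ViT) segmentation model that predicts per-pixel
structure probabilities; and a deterministic pixel-level refinement stage
that turns a coarse probability map into exact structure masks and crops.
This vignette is the package's account of each layer: the model and its
assumptions, the tunable parameters and their defaults, the numerical
choices, and what the tests do and do not establish.

## The synthetic data generator

Real annotated corpora of page-level structure masks are scarce, so the
generator manufactures them. A page is synthesized as follows:

1. **Base page.** A white 512 × 512 canvas (configurable, larger allowed),
   optionally carrying paragraph-like text bands near the top and bottom,
   rendered as rows of dark dashes. A user directory of real molecule-free
   page scans can replace this synthetic base.
2. **Molecules.** On the *single-molecule route*, 1–6 drug-like molecules
   with 15–28 heavy atoms are drawn per page; on the *cluster route*
   (probability `cluster_prob`, default 0.2) a multi-fragment record with a
   total atom count of 250–300 (hydrogens included) emulates the tightly
   packed multi-structure figures of patents. These atom-count bands, the
   1–6 molecules-per-page range, and the 0–30° rotation range are the
   study conditions the generator is built to emulate.
3. **Rendering.** 2D coordinates come from OpenBabel; rasterization is
   done in-package: bonds as thick black segments (stroke thickness
   sampled from `thickness_range`, default 2–4 px), double/triple bonds as
   a main atom-to-atom stroke plus shortened parallel strokes, heteroatoms
   as filled discs. Drawing in-package is deliberate: it yields a
   pixel-exact ink mask, which *is* the ground truth.
4. **Rotation.** Each depiction is rotated by an angle drawn uniformly
   from 0–30°, with bilinear interpolation and a white fill. The rotated
   bitmap is quantized (grey ≥ 128 becomes white) and the ink mask is
   re-derived as `bitmap < 128`, so the ink/bitmap correspondence stays
   exact after rotation. Resampling can cut 1–2 px breaks into thin
   strokes; a targeted repair adds only those morphological-closing pixels
   that reconnect two separate ink components, leaving the ink count
   essentially unchanged (within roughly ±10% of the unrotated count).
5. **Placement.** Assets are placed at random positions, accepted only
   where the page is white under the padded bounding box. This enforces
   both the non-overlap constraint and placement "against a white
   background"; overlap is tested on axis-aligned padded bounding boxes, a
   conservative simplification for rotated content. Placement margins
   (default 16 px) also guarantee that molecule ink never touches text,
   grid lines, or negatives — which the exactness results below rely on.
6. **Distractors.** With probability `grid_prob` a table-style rectangle
   is drawn around a molecule (grid geometry is unspecified in the
   source problem, so a padded 1–2 px box is used); with probability
   `negative_prob` synthetic non-molecular figures (bar charts, line
   charts, blot-like blobs, text boxes) are placed. Neither enters the
   ground-truth mask.

Masks are written as 8-bit 0/255 PNGs next to their pages with a JSONL
manifest of placements (0-based, half-open boxes). `(cfg, seed)` fully
determines the output bytes.

**Cluster ground truth.** A cluster is one placed asset but several
structures; the manifest records one molecule box per fragment, because a
segmentation system should recover the individual structures, not the
cluster as a unit.

**What the generator does not emulate.** Element symbols are drawn as
discs, not glyphs (headless font rasterization is not portable); there is
no scan noise, JPEG artefacts, skew, or colored backgrounds; negatives are
synthetic stand-ins rather than harvested figures. Passing the synthetic
round-trip tests therefore demonstrates the correctness of the mask
machinery and the trainability of the model, not real-document accuracy.

## The segmentation model

The architecture follows the promptable-segmentation pattern: an image
encoder, a prompt encoder, and a mask decoder.

* **Encoder.** The image is patch-embedded and processed by `n_blocks`
  transformer blocks. Each block carries two bottleneck adapters
  (down-projection, ReLU, up-projection, residual): the first after
  multi-head attention, the second before the MLP sublayer. The final
  embedding applies two 1 × 1 convolutions, each followed by layer
  normalization (the "regularization" read as layer norm is an
  assumption). The adapter is residual (`x + up(ReLU(down(x)))`); with
  zero-initialized up-projections the encoder reproduces its backbone
  bit-for-bit, which is both standard adapter practice and a tested
  invariant.
* **Prompts.** Dense prompts: a prior mask pooled to the token grid and
  linearly embedded, or a learned no-mask embedding broadcast over the
  grid. Sparse prompts: points/box corners via random Fourier positional
  features plus learned type embeddings. Free-text prompts raise an
  "unsupported" error — no text encoder is bundled. The pipeline runs in
  no-prompt mode; points and boxes are exposed but unused.
* **Decoder.** The dense embedding is summed element-wise with the image
  embedding; a learned output token (pooled with the embedding, in place
  of a full two-way attention decoder — a deliberate simplification at
  this scale) passes through an MLP to produce a dynamic per-pixel linear
  classifier; two k=2/s=2 transposed convolutions upsample 4×; sigmoid
  outputs give probabilities in [0, 1] plus a predicted-IoU scalar from a
  separate small head (the predicted-IoU reading of the source
  description is itself flagged as an assumption).

No pretrained weights are assumed: models build at any size from random
initialization. The default configuration is deliberately tiny (64-px
input, patch 8, 2 blocks, 48-dim embeddings) so that training and
inference run in seconds on one CPU; `encoder_config_base()` records the
full-scale configuration (512-px input, 12 blocks, two adapters per
block). All configurations obey the same shape algebra — token grid
`image_size/patch_size` per side, decoder output 4× the grid — which the
tests check explicitly.

The model and its training loop are implemented directly in R matrix
algebra with hand-derived reverse-mode gradients, verified against finite
differences in the test-suite.

### Training

`train_adapters()` updates only the adapters, the mask decoder, and the
dense prompt embedding; every backbone parameter stays frozen (certified
by checksum equality in the tests). The optimizer is SGD with momentum
0.9, learning rate 0.001, and four images per batch. The loss is
pixelwise binary cross-entropy on the sigmoid outputs, summed over pixels
per image and averaged over the batch; a global gradient-norm clip
(default 50) keeps that scaling stable. The per-pixel-*mean* reduction is
mathematically equivalent up to a constant factor, but with the fixed
learning rate it makes desk-scale overfitting runs impractically slow,
and the unclipped summed loss can diverge — the sum-plus-clip combination
is the package's design choice.

Targets are built by occupancy (max) pooling the ground-truth mask to the
decoder output grid: at the tiny configuration's output stride, plain
subsampling would erase 1–2 px strokes entirely. The model therefore
learns blob-level localization; pixel exactness is restored downstream by
refinement, mirroring the division of labour the refinement stage is
designed for. The training sanity check — a tiny model overfitting 10
synthetic pages to mean IoU ≥ 0.5 within 200 steps — runs in well under a
minute on one CPU.

## Mask refinement

Refinement is deterministic pixel arithmetic. The fixed pipeline order
is: threshold the probability map (default 0.5, "≥" keeps the boundary);
remove long straight lines from the seed; dilate the seed; binarize the
page; remove long straight lines from the ink; flood-fill update; filter
small regions; extract regions and crop. Line removal is applied to both
the image and the predicted mask *before* the update, since the update
step is what propagates ink into the output.

* **Binarization** marks a pixel as ink iff it is strictly darker than
  the page mean — a data-dependent threshold that absorbs non-white
  backgrounds. A constant page gives an all-zero ink map by convention.
* **Line removal** is a restricted Hough transform over angles within ±2°
  of horizontal and vertical. Along each candidate line, only maximal
  runs with internal gaps ≤ 3 px and extent ≥ 0.5× the page dimension are
  erased, so short co-linear strokes (bonds, text) survive. These
  parameters are unpublished in the source problem; the defaults are the
  package's choices.
* **Dilation** uses a square kernel with side `max(3,
  round(0.01 · max(H, W)))` (5 at 512), bumped to odd so the element is
  centred. It closes gaps between atom symbols and adjacent bonds before
  flood fill.
* **Flood-fill update** formalizes mask addition/deletion: the output is
  the union of all ink connected components (8-connectivity by default —
  bond strokes are often diagonal) that intersect the seed; seed pixels
  unsupported by ink are deleted. The operation is idempotent and is
  tested for exact equality against a brute-force labelling oracle. The
  deletion rule ("mask pixels further away") is formalized as
  non-membership in any touched component, since no distance metric is
  published; dilation-added halo pixels around true ink are likewise
  *not* retained — only ink-supported pixels survive. An optional
  `gap_bridge_px` evaluates connectivity on dilated ink (closing
  symbol/bond gaps in scanned material) while still restricting output to
  true ink; it defaults to 0 because the synthetic renderer keeps symbols
  attached to bonds.
* **Small-region filtering** removes components below 400 px at
  512 × 512, scaled by area ratio at other sizes
  (`round(400 · H·W / 512²)`); a component exactly at the threshold is
  kept.
* **Cropping** takes each region's bounding box, scales it back to page
  resolution when the mask was computed at the model size, pads by
  `crop_pad` (default 4 px) and clips; crops keep the original page
  pixels, colours included.

On synthetic pages these pieces compose into two exact statements, both
tested: with the ground-truth mask as seed, the refined mask equals the
ground truth (minus sub-threshold floaters such as detached double-bond
strokes); and the full pipeline achieves completeness 100% / redundancy
0% on 20 generated pages, also after deleting a random 30% of seed
pixels — recovery through flood fill is what the update step exists for.

## False-positive filtering

The upstream system used an in-house learned classifier whose training
data is unavailable; the shipped default is a documented closed-form
heuristic over the crop's ink density `d` (fraction of pixels darker than
the crop mean — the classic "feature density" of rule-based structure
finders) and aspect ratio `a = H/W`:

`score = exp(−(d − 0.12)² / (2 · 0.12²)) · exp(−max(0, |log a| − log 3))`

with score 0 for crops carrying no ink. The density band is centred on
what rendered structures occupy across the generator's stroke-thickness
range; solid regions, near-empty regions, and extreme aspect ratios score
low. The decision threshold defaults to 0.5. This heuristic separates
structures from solid blots and empty crops but is *not* a learned
filter: busy line-art such as dense charts can score inside the band. A
pluggable scaffold (`make_learned_scorer()`) exposes the same tiny-ViT
encoder as a trainable classifier for users with labelled crops.

## Evaluation

`evaluate_segmentation()` matches predicted and ground-truth boxes
greedily by descending IoU (one-to-one). Completeness is the percentage
of ground-truth structures matched; redundancy the percentage of
predictions unmatched. The IoU threshold defaults to 0.5, the package's
choice where "accurately segmented" is not defined numerically; with zero
predictions, redundancy is reported as 0 with an explicit flag.

## Document ingestion and interface

PNG, JPG and TIFF pages load natively; SVG rasterizes through the rsvg
package when installed. PDF needs an external rasterizer that this build
does not bundle, so PDF input raises an informative error directing the
user to pre-convert pages. Page failures during segmentation are isolated:
a failing page yields an error record, not a crashed run. A thin CLI
(`inst/cli/chemseg.R`; subcommands synthesize/train/segment/eval) wraps
the same functions.

## Problem sizes used by the test-suite

The suite runs the update-oracle equivalence on 200 random 64 × 64
instances, the synthesis invariants on 100 seeded pages, the end-to-end
round trip on 20 pages (exact and 30%-eroded), and the 200-step overfit
check on 10 pages with the tiny configuration — sizes chosen so the whole
suite completes in a few minutes on one CPU while still exercising every
contract at the scale it is stated for.

## Known limitations

* Structures that physically touch in one ink component are not
  separated; nothing vectorizes bonds or reads labels.
* The flood-fill update inherits binarization errors: ink missed by the
  mean threshold cannot be recovered.
* The heuristic filter is a stand-in; its discrimination is coarse.
* Training at the full 512-px configuration is possible but slow in pure
  R; the package's training claims are desk-scale by design.
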