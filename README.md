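# chemseg

Chemical-structure segmentation from document pages, in R.

Patents and papers bury thousands of drawn molecular structures inside
page layouts full of text, tables, charts and labels. Before any optical
chemical-structure recognition (OCSR) engine can translate a drawing into
a molecule, each structure must first be cut out of the page as a clean,
single-structure image. chemseg implements that segmentation step for
cheminformatics practitioners: it finds the structures, repairs the
masks at pixel level, and crops each structure from the original page.

The package provides four cooperating components:

* **Synthetic page generator** — renders molecules from SMILES (OpenBabel
  2D layout, in-package rasterization) onto document-like pages and emits
  pixel-exact ground-truth masks: 1–6 single molecules per page with
  15–28 heavy atoms, or multi-molecule clusters totalling 250–300 atoms
  (H included), rotated 0–30°, with variable stroke thickness, table grid
  lines, paragraph text, and non-molecular negative figures.
* **Adapter-augmented ViT segmentation model** — a promptable
  encoder/decoder in pure R matrix algebra: transformer blocks each carry
  two bottleneck adapters (after attention, before the MLP), the mask
  decoder upsamples 4× with two transposed convolutions, and sigmoid
  outputs give per-pixel structure probabilities in [0, 1]. Training
  (SGD, momentum 0.9, lr 0.001, batch 4, pixelwise binary cross-entropy)
  updates only adapters, decoder and prompt embeddings; the backbone
  stays frozen.
* **Mask refinement** — deterministic post-processing: binarization at
  the page mean, Hough-based removal of long horizontal/vertical table
  lines, scaled square dilation, flood-fill mask addition/deletion
  against the page ink (the output is the union of ink connected
  components touched by the seed mask), a 400-pixel small-region filter
  (area-scaled from 512×512), and colour-preserving crops.
* **Pipeline and evaluation** — document ingestion (PNG/JPG/TIFF/SVG), a
  heuristic false-positive filter labelling non-molecule segments, JSONL
  manifests, and completeness/redundancy scoring by greedy one-to-one
  IoU matching.

## Worked example

Generate a small dataset, overfit the tiny default model on it, and
segment the same pages:

```r
library(chemseg)

dir <- file.path(tempdir(), "demo")
cfg <- synthesis_config(n_pages = 8, seed = 42)
manifest <- generate_dataset(cfg, dir)

pages <- lapply(sort(list.files(file.path(dir, "pages"), full.names = TRUE)),
                read_page_png)
masks <- lapply(sort(list.files(file.path(dir, "masks"), full.names = TRUE)),
                read_mask_png)
pairs <- Map(function(p, m) list(page = p, mask = m), pages, masks)

model <- build_model(encoder_config(), seed = 0)
ck <- train_adapters(pairs, model, train_config(steps = 200, seed = 1))
cat(sprintf("training loss: %.1f -> %.1f\n", ck$history[1], tail(ck$history, 1)))
cat(sprintf("mean training IoU: %.2f\n", mean_train_iou(ck, pairs)))

res <- segment_document(pages, ck)
ev <- evaluate_segmentation(res, manifest)
cat(sprintf("completeness %.1f%%, redundancy %.1f%%\n",
            ev$completeness, ev$redundancy))
```

Output from this run:

```
training loss: 488.9 -> 5.7
mean training IoU: 1.00
completeness 100.0%, redundancy 16.0%
```

The tiny model memorizes its 8 training pages (IoU 1.00 at the decoder
grid) and the refinement stage recovers every placed molecule
(completeness 100%); the redundancy comes from text blocks the overfit
model also marks, which the heuristic filter does not fully reject.
Injecting the ground-truth masks as seeds isolates the refinement stage:

```r
res_gt <- segment_document(pages, seed_masks = masks)
ev_gt <- evaluate_segmentation(res_gt, manifest)
# completeness 100.0%, redundancy 0.0%
```

`write_outputs(res_gt, out_dir)` then writes one PNG crop per kept
segment (source colours preserved) plus a JSONL manifest of boxes,
scores and non-molecule labels.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/chemseg.R synthesize --n-pages 20 --seed 1 --out data/
Rscript inst/cli/chemseg.R train --data data/ --steps 200 --out model.rds
Rscript inst/cli/chemseg.R segment page.png --checkpoint model.rds --out segs/
Rscript inst/cli/chemseg.R eval --pred segs/ --truth data/
```

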