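---
title: "Methods: automated primordial follicle detection and counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated primordial follicle detection and counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The ovarian reserve of a mouse is carried by its primordial follicles
(PMF): an oocyte arrested in meiotic prophase, wrapped in a single layer
of flattened granulosa cells. Estimating the reserve means counting PMF
on serially sectioned, hematoxylin-eosin-stained ovaries — classically a
manual, microscope-based procedure that takes hours per ovary, is
operator-dependent, and is the dominant source of the order-of-magnitude
disagreements between published counts. Digitised whole-slide images make
the task automatable: each slide holds 7–8 sections of one ovary, and a
specialised operator's clicks (one per follicle, with a Pedersen class)
provide point ground truth.

`follidetect` implements the full automated counting pipeline as a
two-stage detector:

1. a binary convolutional patch classifier is trained to say whether a
   fixed-size square frame contains a PMF;
2. a sliding window scans every isolated section with half-window
   overlap, each window is scored by the classifier, low-probability
   windows are discarded, and greedy non-maximum suppression (NMS) keeps
   one frame per cluster of adjacent positives.

A hard-negative-mining (HNM) round then collects the detector's false
positives on a dedicated mining slide set, forces them into the training
set as negatives, rebalances, and continues training — trading a little
recall for a large precision gain. Finally an operator-focus correction
models the expert review of surviving false positives: confirmed misses
of the manual count move from FP to TP and join the ground truth.

## Preprocessing

Slides are read from TIFF (LZW or uncompressed), converted to grayscale
with Rec. 601 luminance weights (the pipeline is contrast-driven; colour
carries little information for this task), and optionally block-averaged
down by an integer factor. Section isolation runs contour/component
detection on a further-downsampled (default extra factor 4) Otsu-binarised
mask; each component above a minimum area (default 0.5% of the slide)
becomes a bounding box, expanded by a margin (default 2% of the box
diagonal), merged with any box it then overlaps, and cropped. Every
annotation is checked against the crops; a click that no section contains
triggers a warning naming the orphan — the guard that no real follicle is
cropped away by preprocessing.

Numerical choices: Otsu was chosen because it is parameter-free; the
minimum-area and margin defaults were set once so that synthetic sections
(and any reasonably scanned slide) survive intact, and are config keys.
Coordinates follow a single convention everywhere: 0-based, x = column
rightward, y = row downward, frames half-open `[x, x+w) × [y, y+h)`,
annotations stored at full resolution and rescaled on the fly.

## The patch dataset

Positives are frames of constant side `frame_size` (default 64 px at the
synthetic working resolution; ~128 px is suggested for ~1 µm/px real
scans) centred on primordial clicks; border frames are padded with the
section's median intensity. Each positive yields the original, its seven
non-identity dihedral variants (three right-angle rotations, both
reversals, both diagonal reflections) and two seeded random translations —
geometric distortions produce images that could equally have been
observed, photometric ones are deliberately not applied. The translation
range is a quarter of the frame, and that number is not free: with
half-overlapping windows the best-placed detection window can still hold
the follicle up to stride/2 = frame/4 off-centre, so the classifier must
be trained to accept follicles across exactly that offset range. (A
smaller budget — e.g. a tenth of the frame — trains a centre-only
classifier that visibly halves detection recall while patch accuracy
stays perfect.) Negatives are sampled uniformly over the section with centres at
least `min_dist` (default one frame) from every annotation of any class,
so no mislabelled negative can contain a follicle. The training set is
balanced to `neg_pos_ratio` (default 1) negatives per positive by a
seeded subsample, and any train/test split is by whole ovary, never by
patch, so appearance statistics of one ovary never leak across the
split.

## The classifier

The classifier is a small VGG-style stack: blocks of 3×3 'same'
convolutions with ReLU, each block closed by max-pooling; then flatten,
optional dropout, one hidden fully-connected ReLU layer, and a 2-way
softmax. Two presets ship: `tiny` (one 8-filter block, 4×4 pool, 32
hidden units — trains in minutes on a CPU and is the default for the
synthetic benchmark) and `vgg-small` (32/64/128-filter blocks with 2×2
pools, 128 hidden units, dropout 0.5). Training minimises categorical
cross-entropy by mini-batch (default 32) gradient descent under Adadelta
(rho = 0.95, epsilon = 1e-6, the method's published defaults; Adadelta
was chosen because it needs no learning rate). All randomness — weight
initialisation, shuffling, dropout, subsampling — is seeded, and
inference disables dropout, so training and prediction are exactly
reproducible.

Two numerical details matter on this optimiser. Adadelta normalises each
parameter's step by its own gradient history, which makes early steps
nearly sign-only; with strictly positive pixel inputs the per-unit
gradient components share signs, and a coherent drift can silence an
entire ReLU layer irrecoverably. The package therefore centres the input
patch around zero at the network entry and initialises the hidden dense
bias at +0.1, the standard guards against dead ReLU units. The `tiny`
preset uses no dropout: a one-block network trained on thousands of
patches is under- rather than over-parameterised, and regularising it
only slows convergence. Softmax is computed after max-subtraction, so
extreme scores (±1e4) cannot overflow.

## Detection, NMS and evaluation accounting

Windows have the classifier's input size and stride = half a window, the
overlap that guarantees a follicle split across one window boundary is
whole in a neighbouring window; interior pixels are covered by at least
four windows, and a final flush row/column is added when the grid does
not reach the image edge. The probability threshold (default 0.15) is
deliberately low — the design keeps recall high and lets HNM deal with
the false positives — and is surfaced in every report. NMS is greedy:
repeatedly emit the highest-probability remaining frame (ties broken by
(y, x) order, for reproducibility) and discard every remaining frame
adjacent to it. Greedy suppression rather than cluster-transitive
suppression is a genuine open choice; the greedy form is the standard
one and reproduces the published three-frame illustration (middle frame
kept) exactly.

Two adjacency rules are provided. `any_overlap` (frames sharing at least
one pixel) is the detector's own default and the simplest reading of
"adjacent positive frames". The pipeline, however, defaults to the IoU
rule (`iou > 0.25`), and that choice is forced by geometry: with 64-px
windows on a 32-px stride, a kept frame overlaps — and under the pure
overlap rule suppresses — every covering frame of any follicle closer
than about one window side, while the benchmark sections legitimately
pack follicles 50–75 px apart. Under `any_overlap` the second follicle
of such a pair loses all its frames and detection recall is capped near
85–90% no matter how good the classifier is (probing confirms the missed
follicles' best windows all score far above threshold). The IoU rule
keeps suppressing the stride-1 duplicates of one follicle (IoU = 1/3
for a one-stride shift) while letting a neighbouring follicle's frame
survive (IoU ≈ 0.14 at a diagonal-stride shift, ≤ 0.1 beyond). A
surviving diagonal duplicate that still contains the same click is
merely an extra TP frame — the found-follicle count is deduplicated per
follicle by construction.

Evaluation matches detections to ground truth by point-in-frame
containment of the click — the only localisation the annotations carry.
A retained frame containing at least one click is one TP frame; a frame
with two follicles counts as two *found follicles* but one TP frame, and
a follicle covered by several retained frames counts once, which keeps
frame-level precision and follicle-level recall mutually consistent.
Recall = found/real follicles; precision = TP/(TP+FP) frames; TN = total
scanned windows − TP − FP, matching the published table's arithmetic.
Reported percentages are rounded half-away-from-zero to two decimals.
The operator-focus correction with `m` confirmed misses maps
(TP, FP, found, real) to (TP+m, FP−m, found+m, real+m); it can never
lower recall and strictly raises precision for m > 0.

One documented discrepancy: feeding the module the published phase-II
counts (FP = 949, corrected precision 65.69% ⇒ TP = 1278) yields a
phase-II precision of 57.39%, one hundredth above the printed 57.38%,
and no integer TP reproduces 57.38 exactly; the module always reports
its own self-consistent percentages.

## The synthetic benchmark

No slide corpus is deposited with the original study, so the package
ships a seeded generator whose output exercises every stage with known
ground truth. A synthetic slide is a bright field (intensity ~230 on an
8-bit scale) carrying darker textured section ellipses (stroma ~150,
scattered stromal nuclei ~75), laid out on a jittered grid of cells so
they can never overlap. A planted PMF is a pale oocyte disc (~200) with
a single dark nucleolus dot and a ring of small elongated dark nuclei
(~60) — the flattened granulosa layer; the annotation sits at the oocyte
centre. Distractors are solid dark blobs, partial granulosa arcs without
an oocyte, and pale discs without ring or dot: none completes the full
follicle template, so ground truth is unambiguous. Follicle centres come
from a jittered hexagonal grid guaranteeing at least 1.5× the maximum
diameter between any two, except when `allow_pairs` plants partners
closer than half a frame to exercise the two-follicles-in-one-frame
rule. Gaussian noise (sd 8) is added last and clipped.

The default study conditions are desk-scale: 1024×1024 slides, 4
sections each, 5–15 follicles and 10–30 distractors per section,
diameters 18–30 px; the default corpus is 4 training slides, 1 mining
slide and 2 test slides (each synthetic slide standing in for one
ovary), with `tiny` trained for 6 epochs and continued for 4 after one
mining round. These sizes let the whole pipeline run in a few minutes on
one CPU while keeping hundreds of follicles in play. What the generator
deliberately does not emulate: staining variability, out-of-focus blur,
tissue folds, touching sections, and the morphological continuum between
primordial and primary follicles. Passing the synthetic benchmark
therefore demonstrates that the machinery — isolation, dataset
construction, training, detection, mining, accounting — is correct and
reproducible, not that the classifier's accuracy transfers to real
H&E slides.

## Reproducibility

One master seed fans out deterministically (a small hash) to per-stage
seeds: corpus, initialisation, shuffling, negative subsampling, mining
continuation. Two runs from the same configuration produce byte-identical
metric reports, and the run manifest records the resolved configuration,
seeds, per-stage counts and artifact paths, so any single stage can be
re-executed from it.

## Known limitations

Only the binary primordial/background decision is modelled; primary,
secondary and antral classes are carried through the annotation schema
but not trained on. Counting is per-section 2D with the nucleolus-click
convention inherited from the manual protocol; no 3D reconciliation
across serial sections is attempted. The pure-R training loop is sized
for desk-scale corpora — a GPU-scale reimplementation would change the
engine, not the contracts.
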