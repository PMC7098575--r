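---
title: "Gene-expression images, treemap layouts and transfer learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-expression images, treemap layouts and transfer learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bulk RNA-seq cohorts pair tens of thousands of gene-expression features with
a few hundred patients, so directly training flexible models on the raw
vectors overfits badly. Convolutional networks are attractive feature
extractors, but they presume *spatial coherence* — neighbouring pixels that
share information — and a gene-expression vector has none: adjacent entries
are arbitrary. `gximage` implements a remedy with two parts:

1. **Gene-expression images.** Each sample's expression vector
   $\mathbf g_i \in \mathbb R^n$ is rearranged into an image
   $\mathbf G_i \in \mathbb R^{r\times c}$ whose pixel positions are fixed by
   a functional hierarchy: genes with related molecular function (same KEGG
   BRITE functional hierarchy) become neighbouring pixels, giving
   convolutional filters genuine local motifs to exploit.
2. **Transfer learning.** A CNN is pre-trained on a large *base* collection
   of tumor samples of many types and fine-tuned on the small *target*
   cohort of interest, both phases optimizing the same fixed-time
   progression-free-interval (PFI) objective.

The prediction task is fixed-time PFI classification: did the patient have a
new tumor event within $t$ days of diagnosis?

## From hierarchy to template image

The layout is computed once, from two sample-independent ingredients: the
annotated functional-hierarchies tree and the per-gene mean expression.

**Tree construction.** The BRITE reference file gives functional categories
and hierarchies; a link table attaches KEGG human gene ids to each
hierarchy; the KEGG gene list maps KEGG ids to HUGO symbols; and the HGNC
complete set maps symbols to the ENSEMBL ids used by expression exports.
Composing these (all relations may be many-to-many) and intersecting with
the expression matrix's genes yields a three-level tree: root → categories →
hierarchies → gene leaves. A gene annotated under several hierarchies
appears as several leaves, so the tree typically has more leaves than
distinct genes. Hierarchies with no mapped genes and categories with no
hierarchies are pruned.

**Treemap layout.** The tree is drawn as nested rectangles on an $r \times
c$ canvas. Every leaf receives the same nominal area $a = rc / D(\text{root})$,
and every node's rectangle has area $A(rec) = D(rec)\cdot a$ where $D$ is
its descendant-leaf count. Categories within the root and hierarchies within
each category are laid out with the ordered *pivot-by-size* treemap: the
largest sibling (the pivot) splits the list into (L1, pivot, L2, L3); L1
fills a strip before the pivot, the pivot and L2 share a middle strip with
L2 chosen to make the pivot's rectangle as square as possible, L3 fills the
rest; strips run along the longer side of the current rectangle, so reading
order approximately preserves sibling order. Sibling order is the order of
first appearance in the BRITE reference file (the source material never
specifies an ordering criterion among categories or hierarchies, so a
deterministic convention is required).

Inside each hierarchy rectangle the gene leaves are sorted in ascending
order of mean expression across all samples and laid out with an ordered
*equal-area row-strip* rule: the rectangle is cut into $k \approx
h/\sqrt{a}$ rows, leaves are spread over the rows as evenly as possible in
order, and each row is split uniformly. Each leaf cell has area exactly $a$
and stays close to square. We deliberately do not reuse pivot-by-size here:
with thousands of equal-weight leaves the "largest sibling" pivot is
degenerate (any leaf qualifies), and in experiments at a realistic scale
(~18,000 leaves on 175×175, about 1.7 px per leaf) pivot-by-size leaves a
handful of cells with a side below one pixel that vanish at rasterization.
The row-strip rule preserves everything that matters — exact areas, reading
order, determinism — and matches the grid-like appearance of published
hierarchy-layout images, while guaranteeing in practice that every leaf
survives rasterization at the reference resolution.

**Rasterization.** Coordinates use a top-left origin with half-open
intervals; each leaf rectangle maps to the integer pixel block
$[\mathrm{round}(y_0), \mathrm{round}(y_1)) \times
[\mathrm{round}(x_0), \mathrm{round}(x_1))$ with round-half-away-from-zero.
Because adjacent rectangles share boundary coordinates exactly, rounding
creates neither gaps nor overlaps between blocks; disjointness is verified
anyway. If any leaf block is empty the resolution is too low for the tree
and rasterization aborts with instructions to enlarge the canvas. There are
no reserved border pixels; canvas pixels not covered by any block (rounding
slack) carry the background value.

**Rendering.** `render_sample()` writes each gene's *continuous* expression
value into all of its pixel blocks (multiply-annotated genes occupy several
positions); background pixels take the global minimum of the training
matrix — the darkest gray under the "lighter = higher" convention, the least
informative choice for a value the layout says nothing about. Models always
consume the continuous grids; 8-bit PNG export exists for inspection only,
so no information is lost to color quantization. Two ablation layouts
accompany the hierarchy layout: $\mathbf M_i$ places one pixel per gene in
ascending order of mean expression (row-major), and $\mathbf R_i$ places one
pixel per gene in a seeded random order shared by all samples. Both are
plain orderings of distinct genes, so they use one pixel per gene rather
than the multi-locus leaf expansion; this is a documented convention, not a
switch the layouts share with $\mathbf G_i$.

## Labels, imbalance, evaluation

**Fixed-time binarization.** With event indicator $e$ and observed time
$T$: $e=1, T<t$ → positive; $T \ge t$ → negative regardless of $e$; $e=0,
T<t$ → excluded, because censoring before the horizon leaves the class
undetermined. "Before $t$" is read strictly, so $T = t$ is negative and
retained. Records with missing outcome values are flagged separately. The
default horizon is $t = 230$ days (about 7.67 months), the operating point
that retains many samples while keeping the positive class around 9–12%.

**Class imbalance.** Random oversampling (exact duplication of minority
rows until 1:1) is used with the neural models in both transfer phases;
SMOTE (convex combinations $x + u(x_{nn} - x)$, $u\sim U(0,1)$, between
minority nearest neighbours) is used in the classical ML baselines,
applied after the dimensionality-reduction step. Both touch training folds
only.

**Cross-validation.** `repeated_cv()` runs stratified R-repeated F-fold CV
(10 × 5 at reference scale, i.e. 50 fold records). Every fitted component —
reducer, oversampler, model, and the decision threshold — sees training
folds only. The threshold maximizes Youden's J (sensitivity + specificity −
1) on training-fold scores; among ties the lowest threshold wins. Fitting
the threshold on validation scores is available as an explicit switch but
is not the default, since it leaks validation information into the reported
confusion-matrix metrics. AUC is computed threshold-free by the rank
(Wilcoxon) definition with midranks for ties; MCC is defined as 0 whenever
a denominator factor vanishes; the F-measure is 0 when precision and recall
are both zero.

**Model comparison.** Fold-wise AUC vectors are compared pairwise with the
one-sided paired Wilcoxon signed-rank test (normal approximation; identical
vectors return p = 1) and the family of p-values is adjusted with the
Hochberg step-up procedure.

## Models

The CNN and MLNN are implemented natively: valid convolution (im2col),
ReLU, non-overlapping max-pooling, dense layers, inverted dropout, batch
normalization (batch statistics in training, running statistics at
prediction), a sigmoid output with binary cross-entropy, and Adam. The
engine is deliberately small — the images this package produces are a few
tens of pixels per side at test scale, where base R with BLAS is entirely
adequate — and fully deterministic given seeds. Weight initialization is
He-scaled; all seeds (initialization, batch order, dropout, resampling) are
explicit inputs recorded in the model specification.

`pretrain_finetune()` trains the model on the oversampled base set with the
pre-training learning rate and batch size, then continues training (same
weights, same optimizer family) on the oversampled target training folds
with the fine-tuning parameters. Zero fine-tuning epochs return the
pre-trained model unchanged. Inputs are standardized per feature (per
pixel) with training-fold statistics, applied identically to base,
training and validation data.

Hyper-parameters are searched jointly — architecture plus both phases'
learning rates and batch sizes — by sequential model-based optimization:
a maximin Latin-hypercube initial design, a random-forest surrogate, and
expected-improvement acquisition (uncertainty from the spread of tree
predictions). The default budget is 10 evaluations; the reference protocol
uses 100, and the budget is a plain argument. The classical baselines cover
the 3 × 4 grid of {ANOVA top-k, PCA, RBF kernel PCA} × {logistic
regression, SVM, shallow neural network, random forest}.

## The synthetic-data generator

All tests and the acceptance analyses run on data from
`synthetic_config()` / `simulate_dataset()`, which emulates the study
conditions in miniature:

* a 4-category tree (4 hierarchies per category, 30 genes each, 480 genes;
  10% of genes annotated under a second hierarchy);
* 4 cohorts of 120 samples sharing one outcome mechanism, so transfer from
  the base cohorts to a target cohort is beneficial by construction;
* per-gene baseline means drawn once (giving a non-trivial mean-expression
  ordering), Gaussian noise of SD 1, and a latent high-risk state
  (prevalence 0.3) that adds +1 log-unit to all genes of the first two
  hierarchies — the outcome signal is *hierarchy-localized*, which is
  exactly the structure the hierarchy layout converts into contiguous
  image blocks and a random layout destroys;
* exponential event times (baseline rate 3×10⁻⁴/day, hazard ratio 4 for
  high risk) with independent uniform censoring whose upper bound is solved
  analytically to hit the target censoring fraction (0.3). At the 230-day
  horizon this yields roughly a 9–12% positive class among retained
  samples, matching the imbalance regime the method targets;
* a 64 × 64 default canvas for model-fitting work; the 175 × 175 reference
  resolution is exercised by the layout validation on trees of ~18,000
  leaves, the full-scale geometry, without requiring full-scale training.

What the generator does **not** emulate: TCGA's empirical expression
distributions, inter-gene correlation beyond the block signal, batch
effects, or cohort-specific biology. Passing tests therefore demonstrate
that the machinery is correct and that the layout/transfer mechanisms work
when their assumptions hold — not that any particular AUC will be achieved
on real tumor data, and the reference study's full-scale performance
figures are out of reach at desk scale by design.

## Numerical choices and conventions

* Continuous layout areas are exact up to floating error; tests require
  $|A(rec) - D(rec)\,a| < 10^{-9}$.
* Rounding at rasterization is half-away-from-zero; ties in gene ordering
  break by gene id; sibling order is first appearance.
* MAD is the raw `median(|x - median(x)|)` without the 1.4826 consistency
  factor; "constant gene" means population SD exactly zero; both are
  unsupervised and deterministic.
* The KEGG gene-list description field is parsed by taking the first
  comma/semicolon-delimited token as the HUGO symbol (the file format
  leaves this unspecified).
* Expression input rows are treated as atomic features; no transcript-level
  to gene-level collapsing is attempted (the upstream export's business).
* Degenerate inputs fail loudly: all-constant matrices, single-class label
  vectors, kernels larger than their input, canvases too small for the
  tree.

## Problem sizes used by the test suite

The suite runs the full geometry at reference resolution (175 × 175,
~18,000 leaves) but keeps model training at desk scale: 64 × 64 images,
≤ 480 samples, CNNs of one conv block (8 filters, 5 × 5, 4 × 4 pooling) and
a 16-unit dense layer trained for a few epochs, 10 × 2 CV in the layout
ablation, and 10 paired seeds in the transfer comparison. These sizes were
chosen so the whole mechanism — simulation → tree → template → images →
labels → CV → paired tests — demonstrates its properties in minutes on one
CPU while leaving every contract at full strength.

## Known limitations

* The stochastic acceptance analyses are miniatures; they reproduce the
  *direction* and *significance* of the layout and transfer effects under
  the generator's assumptions, not any real-data effect size.
* The treemap is the ordered pivot-by-size family only; squarified or
  slice-and-dice variants are out of scope, as is interactive rendering.
* Only human gene annotation is supported, and only the functional
  hierarchy (no pathway ingestion).
* Continuous-time survival modelling (Cox, time-to-event losses) is out of
  scope; the label is a fixed-horizon binarization by design.
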