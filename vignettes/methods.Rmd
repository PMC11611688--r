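---
title: "Aligning and translating unpaired single-cell multiome data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning and translating unpaired single-cell multiome data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The statistical problem

scRNA-seq yields a cell-by-gene count matrix and scATAC-seq a cell-by-peak
accessibility matrix, usually from *different* cells of the same tissue.
Without shared barcodes there is no supervised signal linking an RNA cell
to an ATAC cell; the only structure shared across modalities is
distributional — cell types occupy matching regions of their respective
feature spaces. scxlate exploits exactly that: it assumes cell-type labels
are available for both modalities (from upstream clustering and
annotation, which are inputs here, not computed), and uses them as weak
supervision for adversarial alignment. Nothing in training ever sees a
cell-to-cell correspondence.

## Model

Two autoencoders produce modality-specific embeddings of common dimension
`k` (default 20). The RNA side is an ordinary MLP (hidden widths 256/64,
mirrored decoder, linear output). The ATAC side is chromosome-masked: each
chromosome's peaks feed a private sub-network with hidden widths
128/64/32; the 32-unit blocks are concatenated and projected linearly to
the latent. The decoder mirrors this in reverse with a sigmoid per peak,
so ATAC decoding returns Bernoulli probabilities. Because the
sub-networks are per chromosome, inter-chromosomal weights are
*structurally* absent — `masked_weight_matrix()` materializes the
equivalent block-diagonal matrix and its off-blocks are exact zeros at
initialization and after any number of optimizer steps. This mirrors the
biology (regulatory interactions concentrate within chromosomes) and cuts
the parameter count of the widest layer by the number of chromosomes.

Whether the 128/64/32 widths are shared or per chromosome is genuinely
ambiguous in the underlying description; we use per-chromosome
sub-networks (the widths are arguments of `build_model()`, so the other
reading is one call away).

The full objective is `L = L_Rec + γ·L_Adv + λ·L_Con`:

* **Reconstruction** — MSE over RNA entries plus BCE over ATAC entries,
  both mean-reduced. Mean (not sum) reduction keeps `γ` and `λ`
  scale-comparable across dataset sizes.
* **Confounder penalty** — for each nuisance covariate (categorical batch
  as-is; numeric depth binned into quartiles), each stratum of cells is
  moment-matched to a diagonal Gaussian and penalized by its KL divergence
  from the pooled Gaussian of the batch. The loss is zero exactly when
  every stratum matches the pooled moments — an embedding carrying no
  first- or second-moment information about the confounder. This is a
  deterministic, closed-form surrogate for the mutual-information bound it
  stands in for; it is pluggable should a different MI estimator be
  preferred. Strata with fewer than two cells contribute zero (their
  moments are undefined), with a warning.
* **Adversarial + cycle** — one discriminator pair `(D_A^t, D_R^t)` per
  cell type scores whether an embedding in the respective latent space is
  genuine or cross-mapped. The discriminator step maximizes the standard
  (naive, non-Wasserstein) GAN log-likelihood summed over types; the
  generator step minimizes per-type terms `-log D` on mapped embeddings
  (non-saturating) plus the cycle terms `MSE(g(f(z_R)), z_R)` and
  `BCE(f(g(z_A)), z_A)`.

The BCE cycle term requires targets in `[0, 1]`, so the ATAC latent uses a
sigmoid output activation and the mapper `f` (into the ATAC latent) ends
in a sigmoid as well; `g` and the RNA latent are unbounded. This is the
only reading under which the BCE round-trip is well posed.

### Numerical conventions

* Probabilities are clamped to `[1e-7, 1 - 1e-7]` before any logarithm.
* Hidden activations default to `tanh`. The choice is deliberate:
  integrated-gradients attribution integrates the model's gradient along
  an input path, and with piecewise-linear activations the integrand has
  kinks that make the midpoint quadrature error `O(1/n)` and
  non-monotone. With smooth activations the error is `O(1/n²)`, the
  completeness gap falls monotonically as steps double, and 64 steps
  suffice for sub-1% completeness. ReLU remains available
  (`hidden_act = "relu"`).
* Gradients are the exact backprop of the stated losses, with two
  standard stop-gradient conventions: the cycle targets (`z_R` in the MSE
  term, `z_A` in the BCE term) and the pooled moments inside the
  confounder penalty are treated as constants. Both are the usual
  practice for cycle and moment-matching penalties; all gradient blocks
  are verified against central finite differences in the development
  checks, and ascent/descent directions are asserted in the tests.
* Feature selection tie-breaks are by ascending feature index, making
  `select_hvg()` and `tfidf_select_peaks()` fully deterministic. HVG
  ranking uses the variance of log-normalized expression; TF-IDF uses
  term frequency = count / cell total and
  IDF = `log(1 + n_cells / (1 + n_cells_with_peak))`, with a peak's
  informativeness the sum of its TF-IDF weights. Both statistics stand in
  for external tools the original pipeline delegated to, and both are
  pluggable. The log-normalization library-size target is the median
  per-cell total (the scale constant is not pinned down anywhere
  authoritative; it is exposed as `scale_factor`).

## Training schedule

Phase 1 trains the autoencoders on `L_Rec + λ·L_Con` only; phase 2
alternates one discriminator ascent step with one generator descent step
per minibatch (`d_steps_per_g_step` configurable). Defaults: Adam at
`lr = 1e-3` with standard moment parameters, batch 64, 30 pretraining and
60 adversarial epochs — on the desk-scale preset below this converges in
about a minute and a half on one CPU core. Early stopping ends a phase
when the relative change of the total loss over 10 epochs falls below
`1e-4`. Epoch counts are exposed, not asserted: the underlying method
statement does not fix them, and the tests assert *improvements over an
untrained model*, not absolute loss values.

`grid_search()` follows the two-stage protocol: a uniform grid over
`(γ, λ) ∈ [0.1, 2]²`, then — with the winners fixed — a grid over the
learning rate (`[1e-5, 1e-3]`, uniform in log space, since learning rates
act multiplicatively) and batch size (`[16, 256]`). Each point trains a
fresh model and the configuration with the lowest converged total loss
wins; at resolution 1 the midpoint of each range is returned.

## What the synthetic generator emulates — and what it does not

`simulate_multiome()` draws one latent program per cell type, separated
by `type_separation` in units of the within-type latent radius (at 2,
types are cleanly separable from the true latent — the preset value), and
one latent vector per cell. RNA counts are negative binomial around
softmax-normalized per-cell abundances scaled by lognormal library sizes;
ATAC is Bernoulli over a logit linear in the latent. Both modalities get
per-batch feature shifts, giving the confounder penalty something real to
remove. Generic peak loadings are deliberately weak (most real peaks are
broadly accessible and only mildly type-specific); a **planted link**
makes one peak a marker enhancer of a driving type (logit shifted by
`±2·effect`) and couples the linked gene's log-mean to that peak's
accessibility program, scaled so `effect = 1` equals the strength of the
gene's own type structure. The desk-scale preset — 600 cells per
modality, 300 genes, 1000 peaks on 3 chromosomes, 4 types, 2 batches, one
planted link at `effect = 3` — trains in minutes and is the fixture for
the end-to-end tests.

Because training is unpaired, only distribution-level structure can
transfer between modalities: the model can learn that *type-1 cells* have
open marker enhancers and high marker-gene expression, but it cannot
learn within-type cell-to-cell covariation that no loss function can see.
Planted-link recovery by attribution therefore requires the enhancer to
be distinctly more type-discriminative than ordinary peaks — which is
also the realistic regime. The generator does not emulate read-level
noise, fragment lengths, doublets (the flag is an input), peak co-firing
beyond the shared latent, or sequence content; passing tests say the
method recovers the structure the generator encodes, not that it meets
any particular benchmark on real tissue.

The test design around the stochastic end-to-end criterion is: alignment,
both translation directions and their baselines are asserted on each of
three seeds; planted-link top-5 attribution recovery is asserted on a
majority of the three, as the one sub-property whose seed-to-seed
variance is genuinely irreducible at this data size.

## Evaluation metrics

* **Modality mixing score** — for each cell type, sample a cell, take its
  1000 nearest neighbours by cosine distance in the joint embedding, and
  compute `m = 1 − |c_A/(c_A + c_R) − 0.5|`; balanced neighbourhoods score
  1, single-modality neighbourhoods 0.5. The printed form of this formula
  in the source material is typographically garbled; this reading
  reproduces its stated perfect-case value of 1. Scores are averaged over
  50 seeded draws (the single-draw variant is reported alongside), since
  the one-draw estimator is high-variance.
* **Global homogeneity** — mean silhouette width on cosine distance
  against the labels, plus ARI and AMI between the labels and a k-means
  clustering of the embedding (the clustering is pluggable). ARI and AMI
  are computed from the contingency table; ARI is cross-checked against
  an independent implementation in the tests.
* **Translation** — AUROC of RNA→ATAC probabilities against the observed
  binary matrix (per entry, overall and per type; the probability matrix
  is always returned because ROC needs it, sampling is opt-in), and
  squared Pearson correlation of per-feature mean signals for the
  regression view.
* **Motif activation score** — weighted mean accessibility of peaks
  within 750 kb *upstream* of a TSS (strand-aware; unstranded genes fall
  back to a symmetric window, logged). The per-peak weights are not
  specified by the source; the default is uniform, with an exponential
  distance decay behind a flag.
* **Peak-to-gene linkage** — Pearson correlation (with test p-value,
  flagged at 0.05) between per-cell-type mean accessibility and mean
  expression for peaks within 100 kb of the gene. Per-cell binary
  accessibility makes per-cell correlations degenerate, so links are
  computed on pseudo-bulk — an interpretation, stated as such.

## In-silico perturbation

`integrated_gradients()` attributes one gene's *translated* expression
(the deterministic ATAC→RNA map — Bernoulli sampling never enters
attribution, since gradients of sampled outputs are undefined) to every
peak, via a midpoint Riemann sum along the straight path from a baseline.
The default baseline is all-zeros, i.e. fully closed chromatin; a
cell-type-mean baseline is available. Completeness
(`Σ IG = F(x) − F(baseline)`) is computed on every call and attached to
the result. `group_attribution()` averages per-cell attributions within
groups (a pseudo-bulk-profile attribution is the natural alternative; the
per-cell mean is the default because it weights cells, not accessibility
mass) and reports each group's top peaks with their mean observed
accessibility in *every* group — the in-group versus out-group contrast
used to sanity-check a candidate regulatory peak.

## Known limitations

* Alignment quality degrades for cell types with few cells — the
  per-type discriminators see few examples (the same failure mode the
  method's own benchmarks show on rare types).
* The confounder penalty matches first and second moments per stratum;
  higher-order dependence on a confounder is invisible to it.
* Everything runs on dense BLAS after the sparse first encoder layer; the
  implementation targets desk-scale and atlas-subset problems, not
  million-cell atlases.
* Cell-type labels are trusted inputs; label noise propagates into the
  adversarial supervision unexamined.
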