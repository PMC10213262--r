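---
title: "Classifying tumor-microenvironment subtypes from bulk expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumor-microenvironment subtypes from bulk expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmetyper)
```

## The model

Two biological programs dominate the tumor microenvironment (TME) of solid
tumors: pathological angiogenesis and immune activity. Placing a tumor on
those two axes partitions cohorts into four phenotypes — Angiogenic (A;
angio-high, immune-low), Immune Active (IA; immune-high, angio-low),
Immune Desert (ID; both low) and Immune Suppressed (IS; both high) — and
each phenotype suggests a therapy class through its mechanism of action
(MOA): anti-angiogenic agents for A + IS, immune checkpoint inhibition for
IA + IS, TLR9-agonist combinations for IS.

`tmetyper` implements that idea as a shallow multilayer perceptron. For a
panel of $G$ genes with normalized expression $x \in \mathbb{R}^G$, each of
two hidden neurons computes

$$h_i = \tanh(w_i \cdot x + b_i), \qquad i = 1, 2,$$

and the output layer assigns softmax probabilities over the four subtypes,

$$p_k = \mathrm{softmax}_k(V h + c), \qquad k \in \{A, IA, ID, IS\}.$$

The called subtype is the argmax (ties broken in class order A, IA, ID,
IS; no minimum probability is required). The pair $(h_1, h_2) \in (-1,1)^2$
is the model's *latent space*: in a trained model the neurons track the
immune and angiogenesis axes, confident calls sit near the corners, and
ambiguous samples near the center, so the latent plot mirrors the quadrant
phenotype diagram.

Training minimizes the multi-class cross-entropy plus a small L2 penalty
$\tfrac{\lambda}{2}(\lVert W \rVert^2 + \lVert V \rVert^2)$ with the
L-BFGS solver. The two-neuron bottleneck is deliberate: it forces the
network to compress the panel to exactly the two biologies the panel was
designed around, which is what makes the hidden layer interpretable.

## The pipeline

1. **Panel curation** (`transferability_scores()`, `filter_panel()`): score
   each candidate gene's cross-dataset consistency and drop unstable genes.
2. **Training labels** (`axis_scores()`, `quadrant_label()`): a
   population-dependent preliminary model — per-gene z-scores across the
   cohort, axis scores as means over each axis's weighted genes, subtype =
   quadrant of the axis-score pair.
3. **Frozen-reference normalization** (`fit_reference()`,
   `map_to_reference()`): freeze the training distribution once; map any
   new cohort onto it without re-estimating anything.
4. **Classifier** (`train_model()`, `predict_subtypes()`,
   `cross_validate()`): the MLP above.
5. **Biomarker logic** (`biomarker_call()`): MOA rules over subtype
   probabilities, giving B+/B− status and a signed score.
6. **Evaluation** (`confusion_metrics()`, `auroc()`, `orr_enrichment()`,
   `baseline_null()`): predictive performance of any binary biomarker
   against RECIST response.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `train_config(tolerance)` | 1e-4 | minimum loss improvement counted as progress |
| `train_config(patience)` | 10 iterations | how long training tolerates no progress |
| `train_config(max_iterations)` | 1000 | hard cap on L-BFGS iterations |
| `train_config(l2)` | 1e-4 | L2 strength; exposed in the CV grid |
| `train_config(cv_repeats, cv_folds)` | 3, 10 | repeated stratified k-fold CV |
| `biomarker_rule(combined_threshold)` | 0.5 | B+ cutoff on combined probability |
| `high_confidence_summary(threshold)` | 0.8 | probability bar for a high-confidence call |
| `transferability_scores(threshold)` | 0.7 | keep/drop score cutoff |
| `transferability_scores(floor_frac)` | 0.1 | dispersion floor, as a fraction of the median panel dispersion |

### Stopping rule

Training stops once the loss fails to improve by at least `tolerance` over
`patience` consecutive iterations, or at `max_iterations`. `stats::optim`
exposes no per-iteration callback, so the implementation runs L-BFGS in
chunks of `patience` iterations and stops when a whole chunk improves the
loss by less than `tolerance`: if no single iteration in the chunk improved
by `tolerance`, the chunk cannot have, so the rule is enforced at chunk
granularity. The model records iterations run, the final loss and the
stopping reason.

## Frozen-reference normalization

The production constraint is that a locked model must classify new cohorts
from other platforms without touching the training data again. The mapping
is two-stage and per-sample:

1. each sample's expression profile is replaced by reference quantiles at
   the sample's own plotting positions $(r - 0.5)/G$ (midranks for ties,
   linear interpolation, clamped at the extremes), so the sample's pooled
   distribution becomes the training distribution while within-sample
   ordering is preserved exactly;
2. the panel genes are extracted and z-scaled with the reference's frozen
   per-gene mean and standard deviation (computed on the quantile-mapped
   training matrix, so train- and predict-time features share a scale).

The map is monotone per sample, invariant to any strictly increasing
per-dataset transformation, and estimates nothing from the new cohort —
deliberately unlike batch-correction methods that refit on incoming data.

Two practical points. First, the reference is pooled over **all** genes of
the training matrix, not just the panel: the background genes anchor each
sample's panel amplitudes. If the mapping used panel genes alone, a sample
in which *every* panel gene is elevated (an IS tumor) would be
indistinguishable after rank-mapping from one in which every panel gene is
low (an ID tumor), since only within-sample ranks survive. Second, the
map's rank resolution is $1/G$, so per-gene fidelity of the mapped values
improves with the number of genes supplied; with transcriptome-scale input
the self-map is near-identity, while panel-only input is coarse. Supply
the same kind of matrix (panel plus background) at fit and at map time.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the classifier
assumes, so the whole pipeline is testable without any external data:

- two latent activities per sample (immune, angiogenesis), either a
  two-point low/high mixture at ±1 z-units (default; quadrant truth is
  unambiguous, which makes label-recovery checks crisp) or continuous
  standard normals (for boundary behavior);
- subtype = quadrant of the latent pair; subtype proportions configurable
  (default equal quarters — across real cohorts each subtype is reported
  at roughly 15–40%);
- axis genes respond to their axis with a mean shift of `loading_effect`
  (default 2 log2 units between low and high) plus i.i.d. Gaussian noise
  (`noise_sd`, default 1); per-gene baselines are uniform on 4–12 log2
  units; background "noise genes" carry no signal but anchor the
  normalization;
- optional `cross_loading` makes each axis gene respond to the *other*
  axis at a fraction of its own loading, emulating immune–vascular
  crosstalk;
- RECIST best responses are Bernoulli draws with subtype-dependent rates;
  the default response model encodes an immune-therapy mechanism (34.4%
  ORR in IA/IS vs 4.9% in A/ID, a 7-fold enrichment);
- `simulate_multidataset()` adds per-dataset platform perturbations
  (per-gene location and scale jitter) and can designate "unstable" genes
  whose loading sign flips and whose baseline is displaced with
  alternating sign across datasets — the signature of a probe that fails
  on some platforms. A sign flip alone would leave a gene's median (and
  so its rank) untouched, which no rank-based score could or should
  detect; the displacement is what platform failure actually looks like.

What the generator does **not** emulate: negative-binomial count noise,
tumor purity and copy-number confounding, correlated gene-gene residuals,
and real cross-platform nonlinearities. Green tests on synthetic cohorts
therefore demonstrate correctness of the machinery and recoverability
under the model's own assumptions, not clinical performance on real data.

## Feature transferability

The score is a declared surrogate for the unpublished production metric,
built to match its stated purpose (drop genes whose expression is too low,
too high or too variable across platforms). Within each dataset every
candidate gene receives the normalized rank (in $[0,1]$) of its median
expression among the candidates; the score is $1 - $ mean absolute rank
difference over all dataset pairs. Rank-based means platform-monotone
transformations cannot move it. Genes absent from a dataset, or with
dispersion (MAD across samples) below the floor in any dataset, are
flagged and scored 0.

The floor defaults to `0.1 ×` the median panel dispersion per dataset. A
percentile-based floor was considered and rejected: the bottom decile of a
healthy panel always exists, so a percentile floor permanently flags ~10%
of perfectly fine genes per dataset (and the union across datasets grows),
contradicting the flag's purpose of catching absent or constant probes. A
fixed fraction of the typical dispersion trips only for genes an order of
magnitude quieter than the panel norm.

## Interpretability: neuron–axis alignment

`neuron_axis_alignment()` quantifies whether the trained hidden layer
rediscovered the panel's two axes. The sign-alignment of an axis on its
assigned neuron is the fraction of panel genes with the expected weight
sign: positive for the neuron's own axis, negative for the other axis (a
contrast that reads one biology and nets out the other). Because negating
a hidden neuron's weights together with its outgoing output weights leaves
the network's function unchanged, a neuron's orientation is pure gauge;
the assignment search therefore covers both neuron–axis permutations and
both orientations per neuron and reports the maximizing assignment. Under
random (permuted) axis annotations the expected alignment is exactly 0.5.

When does the contrast structure emerge? If training labels are quadrants
of axis scores computed from the same features, the loss-optimal hidden
weights put all the mass on the own-axis genes and exactly zero on the
cross-axis genes — the labels are linear functionals of the features, so
nothing needs to be netted out, and cross-axis signs are noise. The
contrast structure appears when the features are cross-contaminated
relative to the labels: with immune–angiogenesis crosstalk in the genes
(`cross_loading > 0`) and labels that reflect the *purified* biologies
(in simulation, the generating truth; in practice, training labels derived
from external curated signatures rather than panel averages), reading out
one pure axis requires subtracting the other, and the optimum is
own-positive/cross-negative for both neurons. The packaged
interpretability study therefore uses continuous latents with
`cross_loading = 0.6`, ground-truth labels, $n = 400$ and a stronger L2
($\lambda = 0.3$, which shrinks the noise component of the weights faster
than the signal); these conditions were fixed from this mechanism analysis.

## Numerical and policy choices

- **Boundary policies.** Axis scores exactly at a quadrant threshold are
  "low" (deterministic, measure-zero for continuous data). A combined
  biomarker probability exactly at the threshold is B+, consistent with a
  signed score $s = 2p_{B+} - 1$ whose decision boundary is $s \ge 0$.
  Argmax ties in prediction go to the first class in (A, IA, ID, IS).
- **Missing values.** Genes with more than 20% missing values are dropped
  with a warning; remaining gaps are imputed with the gene's median (the
  classifier needs complete vectors). Unevaluable (NE) responses are
  excluded from all response metrics with an audit count.
- **Rounding.** All rates are stored as exact fractions of integer counts;
  presentation rounds half-up to 2 decimals (1 for fold enrichment).
- **Initialization.** Hidden and output weights start uniform on
  $\pm\sqrt{6/(\text{fan-in} + \text{fan-out})}$, scaled by `init_scale`
  and drawn under the configured seed, so training is bit-reproducible.
- **Baseline null.** The no-biomarker reference predicts "responder" with
  probability equal to the observed prevalence $p$; analytically its
  expected sensitivity, PPV and F1 are $p$, specificity and NPV $1-p$,
  accuracy $p^2 + (1-p)^2$. The Monte-Carlo mode averages the same metrics
  over simulated prediction vectors (replicates with undefined PPV are
  dropped from that metric's mean).
- **AUROC** uses the Mann–Whitney midrank formulation; tied scores count
  one half. An all-tied score vector returns 0.5 with a warning.
- **Problem sizes.** The packaged tests and the acceptance script use
  cohorts of 100–400 samples with 12–62 genes per axis (10,000 samples for
  rate-convergence checks, ~1,500 background genes for the
  transcriptome-scale normalization check, 20 seeded trainings for the
  alignment study) — large enough for stable estimates at these effect
  sizes while keeping a full run to a few minutes.

## Known limitations

- The transferability score and the reference mapping are surrogates for
  unpublished production procedures; they match the stated purposes and
  constraints, not necessarily the proprietary formulas.
- The published 124-gene panel and production weights are proprietary;
  this package provides the machinery, not the clinical assay.
- Quadrant labels from population-dependent z-scores shift with cohort
  composition by construction; only the frozen trained model is
  population-independent.
- AUROC confidence intervals and survival endpoints are out of scope.
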