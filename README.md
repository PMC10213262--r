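# tmetyper

Classify bulk tumor expression profiles into four tumor-microenvironment
(TME) subtypes and evaluate them as predictive biomarkers of therapy
response.

Solid tumors differ not only in their cancer cells but in their stroma.
Two programs dominate that stroma — pathological angiogenesis and immune
activity — and their intersection defines four phenotypes: **A**
(Angiogenic: angio-high, immune-low), **IA** (Immune Active: immune-high,
angio-low), **ID** (Immune Desert: both low) and **IS** (Immune
Suppressed: both high). Each phenotype suggests a therapy class through
its mechanism of action (MOA): anti-angiogenics for A+IS, immune
checkpoint inhibitors for IA+IS, TLR9-agonist combinations for IS.
`tmetyper` is for computational oncologists and biomarker teams who want
that subtyping as transparent, testable code: a classifier, the
normalization that lets a frozen model score new cohorts, the biomarker
logic, and the evaluation statistics — plus a synthetic cohort simulator
so every stage can be exercised without access to clinical data.

## The model

A multilayer perceptron with two tanh hidden neurons and a softmax output
over the four subtypes. For normalized panel expression *x*:

    h_i = tanh(w_i · x + b_i),      i = 1, 2
    p   = softmax(V h + c),         p over (A, IA, ID, IS)

trained by minimizing multi-class cross-entropy (plus a small L2 penalty)
with L-BFGS, stopping when the loss stops improving by 1e-4 over 10
iterations (at most 1000). The subtype is the argmax probability; the
hidden pair (h1, h2) is a latent map of the cohort in which the two
neurons track the immune and angiogenesis axes and call confidence grows
toward the corners. Biomarker status B+/B− follows an MOA rule: e.g. for
immunotherapy, B+ when P(IA) + P(IS) ≥ 0.5, with signed score
2·(P(IA)+P(IS)) − 1.

## Worked example

Simulate a 200-sample cohort with the package's latent two-axis generative
model, label it, train, classify, and evaluate the immunotherapy
biomarker:

```r
library(tmetyper)

sim    <- simulate_cohort(sim_config(n_samples = 200, seed = 7))
labels <- label_cohort(sim$expression, sim$panel)
ref    <- fit_reference(sim$expression, sim$panel, seed = 7)
model  <- train_model(map_to_reference(sim$expression, ref), labels,
                      train_config(seed = 7), reference = ref)
model
#> TME subtype classifier: 124 genes -> 2 tanh neurons -> 4 subtypes (A, IA, ID, IS)
#>   trained 40 iterations (patience), loss 2.00776 -> 0.00710, seed 7
#>   reference distribution: 28800 pooled values (training)

calls <- classify_samples(model, sim$expression)   # normalize + predict
bm    <- biomarker_call(calls, moa_rule("immune")) # B+ = IA + IS
confusion_metrics(bm, sim$clinical)
#> TME biomarker metrics (n = 200 evaluable, 0 NE excluded)
#>   counts: TP 34  FP 59  FN 6  TN 101
#>   ACC 0.68  F1 0.51  sens 0.85  spec 0.63  PPV 0.37  NPV 0.94
#>   ORR(B+) 0.37  ORR(B-) 0.06  enrichment 6.5-fold
auroc(bm$combined_probability, sim$clinical$responder)
#> [1] 0.75
```

Reading the output: of 200 evaluable samples, the B+ arm responds at 37%
versus 6% in the B− arm — a 6.5-fold enrichment, close to the 7-fold
response model the simulator was configured with. The baseline null
classifier (`baseline_null()`), which guesses from the 20% responder
prevalence alone, manages accuracy 0.68 but sensitivity only 0.20 against
the biomarker's 0.85. `plot_latent_space(model, calls, sim$clinical,
annotate = "bor")` draws the cohort on the hidden-neuron plane with
probability contours; `plot_score_distribution(bm)` shows the bimodal
signed biomarker score around the 0 decision boundary.

Other entry points: `transferability_scores()` / `filter_panel()` for
cross-platform panel curation, `cross_validate()` for hyperparameter
tuning, `neuron_axis_alignment()` for the hidden-weight interpretability
check, `subtype_transitions()` for matched pre/post treatment pairs,
`subgroup_metrics()` for MSI/PD-L1-style stratified evaluation, and
`save_model()` / `load_model()` for the versioned model JSON. A thin
command-line wrapper lives at `inst/cli/tme.R`
(`Rscript tme.R simulate|curate|label|train|classify|callbm|evaluate`).

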