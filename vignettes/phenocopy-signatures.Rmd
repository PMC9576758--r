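---
title: "Phenocopy signatures: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenocopy signatures: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Targeted cancer therapies are prescribed on driver-gene mutation status, yet
response is far from uniform: some mutation carriers harbor passenger
variants that never activate the pathway, while some mutation-negative tumors
activate it through other routes (copy-number gain being a prominent one) and
would plausibly benefit. Such tumors *phenocopy* the mutant transcriptional
state. This package implements a framework for (i) learning expression-based
classifiers of mutation status — phenocopy signatures — from pan-cancer
cohorts, and (ii) quantifying whether those predictions add information to
DNA mutation status in explaining drug response.

The key design point is indirect training: signatures are trained to predict
*mutation status*, never drug response. Any association between signature
calls and drug sensitivity therefore arises only through the biology the
signature captures, which also means cell-line and clinical drug-response
datasets remain untouched validation material.

## The model pipeline

1. **Mutation annotation** (`filter_protein_altering()`, `call_pathogenic()`,
   `build_labels()`). Only protein-sequence-altering variants count
   (missense, nonsense, frameshift, in-frame indels, start/stop changes);
   silent, splicing, intronic, upstream and downstream records are dropped.
   A record is *pathogenic* if any computational predictor (SIFT, PolyPhen-2
   HDIV, PolyPhen-2 HVAR, FATHMM) calls it damaging or ClinVar marks it
   pathogenic or likely pathogenic — an OR over evidence columns in which
   missing values never count as damaging. Per pathway, a sample's
   `any_mutation` label is driven by a configurable driver-gene set (e.g.
   PIK3CA/AKT1/AKT2 for PI3K–AKT); `pathogenic_mutation` additionally
   requires a consensus-positive record. Copy-number changes never enter the
   labels: thresholds for calling functionally relevant CNV are inconsistent
   across datasets, so CNV is used only as a descriptive comparison
   (`compare_cnv_rates()`).

2. **Expression preparation** (`intersect_genes()`,
   `normalize_expression()`, `restrict_to_pathway()`,
   `filter_training_cancer_types()`). Matrices are restricted to the genes
   shared by all datasets in play, then per-sample rank-normalized:
   each sample's values become fractional ranks in (0, 1] with average ranks
   at ties. Rank normalization is invariant to any strictly monotone
   per-sample transform and idempotent, which is what makes a signature
   trained on one platform applicable to RNA-seq-, array- and cell-line
   expression alike; the dialect is stored inside every signature so
   prediction always replays training normalization. Alternative dialects
   (per-gene z-score, none) exist but are not default. Features are then cut
   to the pathway's membership genes, and cancer types whose alteration rate
   falls strictly below 5% are removed from training (a type at exactly 5%
   stays). The rate uses `any_mutation`, matching training on all
   protein-coding alterations rather than the pathogenic subset.

3. **Signature training** (`train_signature()`, `predict_phenocopy()`).
   Gradient-boosted trees (xgboost) with a hinge loss predict the binary
   label from pathway expression. Tree depth and count are tuned by
   stratified 10-fold cross-validation; out-of-fold margin scores are pooled
   across folds and scored by ROC AUC (pooling, rather than averaging
   per-fold AUCs, keeps the estimate stable when folds carry few positives).
   Ties prefer fewer trees, then shallower trees. The winning configuration
   is refit on all samples and the signature *locked*: prediction is pure,
   serialization is two text JSON files, and re-training with the same seed
   reproduces byte-identical output (single-thread tree construction).
   Prediction thresholds the hinge margin at zero; feature genes absent from
   a validation matrix are imputed at the mid-rank value 0.5 — neutral under
   the rank dialect — with a hard error above 50% missingness.

4. **Drug-response evaluation** (`orient_response()`,
   `fit_nested_models()`, `fit_three_predictor_model()`, `adjust_fdr()`,
   `evaluate_drug_panel()`). Response metrics are first oriented so lower =
   more sensitive (activity area is negated; IC50 z-scores and dose-response
   AUC pass through), with an attribute guarding against double negation.
   Per drug and dataset, ordinary least squares fits a reduced model
   (intercept + mutation) and a full model (+ phenocopy call) on complete
   cases, compared by the Gaussian likelihood-ratio statistic
   $\chi^2 = n \ln(\mathrm{RSS}_0 / \mathrm{RSS}_1)$ with 1 degree of
   freedom. Negative coefficients mean association with sensitivity.
   Benjamini–Hochberg FDR is applied over the pooled family of all
   drug/pathway/dataset tests in a run (a per-dataset family is available);
   significance is declared at q < 0.05 directly rather than through a fixed
   $\chi^2$ cutoff, since any such cutoff is a function of one particular
   p-value family.

5. **Biomarker metrics** (`define_responders()`, `biomarker_panel()`).
   Responders are the most-sensitive quartile of a drug's oriented response,
   computed over *all* assayed samples before stratification; the cutoff is
   the $\lceil n/4 \rceil$-th smallest value and boundary ties are included.
   Sensitivity, specificity, PPV and NPV are then computed for five
   conditions: the phenocopy call within (1) mutation-negative,
   (2) pathogenic-mutation and (3) non-pathogenic-mutation samples — three
   strata that partition the cohort — and, over all samples, (4) mutation
   and (5) pathogenic-mutation status as the predictor. Zero denominators
   yield missing values, never zero, so summaries over drugs stay honest.

6. **Cohort comparisons** (`compare_cnv_rates()`,
   `compare_phenocopy_rates()`, `responder_stratified_rates()`). Group rates
   are compared with the two-proportion Pearson chi-square without
   continuity correction; pre/post-treatment arms are treated as unpaired
   aggregates. Small clinical responder tables use Fisher's exact test. A
   sample counts as CNV-changed if any pathway gene (driver or feature set)
   carries a non-neutral call.

## The synthetic-data generator

Downstream claims are only testable against known truth, so the generator
(`generate_cohort()`, `generate_paired_cohort()`) encodes exactly the causal
structure the analysis assumes, per sample:

$$\text{mutation} \sim \mathrm{Bern}(r_{\text{type}}), \quad
  \text{pathogenic} \mid \text{mutation} \sim \mathrm{Bern}(f), \quad
  \text{CNV} \sim \mathrm{Bern}(c),$$
$$\text{activation} = \mathrm{Bern}(\text{penetrance}) \cdot
  \mathbb{1}[\text{pathogenic} \lor \text{CNV}].$$

Activation shifts each of the signal genes by `signal_shift` (z-units) on
top of N(0, `expr_noise_sd`) noise, and shifts each on-target drug's
response by `-drug_effect` (lower = sensitive) on top of
N(0, `response_noise_sd`); off-target drugs are pure noise. Annotation
strings use the tools' own vocabularies (SIFT D/T, PolyPhen-2 D/P/B, FATHMM
D/T, ClinVar Pathogenic/Likely_pathogenic/Benign/VUS) and are consistent
with true pathogenicity except with probability `annotation_error_rate`;
mutation tables also carry silent/intronic driver records and passenger
records outside the driver set, so the filtering and consensus code paths
are exercised, not bypassed. Paired cohorts drop each activation-positive
sample from the post-treatment arm with probability
`treatment_selection_strength`, emulating selective elimination of
sensitive (phenocopy) tumors by therapy.

Default parameters describe a pan-cancer training-style cohort: 4 cancer
types × 250 samples with alteration rates (0.10, 0.20, 0.30, 0.04) — one
type deliberately straddling the 5% training floor — pathogenic fraction
0.7, CNV rate 0.15, penetrance 0.9, a 60-gene pathway with 30 signal genes
and 200 background genes, unit signal shift and unit noise, and a 10-drug
panel half of which is on-target. Effect sizes linking activation to
response are not published quantities; `drug_effect = 1` against
`response_noise_sd = 1` (a standardized unit effect) is this package's
calibration choice and is stated as such.

What the generator does **not** emulate: gene–gene covariance, batch
effects, tumor purity, subclonality, dose–response curve shape. Passing
tests therefore demonstrate correctness of the machinery under the assumed
causal model, not performance on real tumors.

## Study conditions used by the checks

The test suite and `scripts/acceptance.R` re-derive the package's headline
behavior at these problem sizes, chosen to make each check sharp:

* **Type-I calibration** — a null where drug effects are routed through
  mutation status only (`response_driver = "mutation"`), 1000 drugs at
  n = 300: the phenocopy term's p-values must be uniform and reject at
  ~5%.
* **Power** — CNV-driven phenocopies (CNV rate 0.15, penetrance 0.9, unit
  effect and noise) at n = 500 with 200 on-target and 200 off-target
  drugs: on-target rejection at q < 0.05 should be near-total while
  off-target rejections stay within the FDR guarantee.
* **Signature recovery** — a clean-label cohort (pathogenic fraction 1,
  penetrance 1, no CNV, error-free annotation, so labels coincide with
  latent activation) of 4 types × 500 samples at unit signal shift and
  noise; tuning grid depth {2, 3, 4} × trees {50, 100, 200}. Under the
  noisy-label defaults the cross-validated AUC is bounded well below 1 by
  label noise itself (passengers and CNV-driven activations), so classifier
  *recovery* is measured where the label is the truth. The 20 permuted-label
  null controls use a single grid point (depth 2, 50 trees): the null AUC
  does not depend on the grid, and replicating the full grid would add
  runtime, not information.
* **Biomarker strata** — the "strong-signal regime" (drug effect 2, response
  noise 0.5) where phenocopy status nearly determines responder status;
  condition-1 specificity and NPV are then expected at or above 0.9.
* **Clinical direction** — 200 paired cohorts of 500 pre-treatment samples
  at selection strength 0.5 (and 0 as a null).

In the statistics core, every nontrivial quantity is also checked against an
independent oracle: the LR statistic against `stats::logLik` differences,
BH q-values against a literal step-up, the two-proportion chi-square against
the expected-count formula, Fisher p-values against exhaustive
hypergeometric enumeration, and ROC AUC against pairwise concordance
counting.

## Numerical and degenerate-input policy

* The hand-written two-proportion chi-square sums only over cells with
  positive expected counts, so degenerate margins (e.g. both groups all
  negative) return statistic 0 and p = 1 instead of NaN.
* Nested-model fits flag rather than fail on degenerate designs: constant
  or mutation-collinear phenocopy vectors, or fewer than `n_min = 20`
  complete cases (the threshold is a guard of this package's choosing).
  Flagged rows are excluded from the BH family.
* In the three-predictor variant the LR part compares
  `~ mutation + pathogenic` against `~ mutation + pathogenic + phenocopy`
  (1 df): the question is still "does the phenocopy call add to all DNA
  information". When no pathogenic mutations are present the term is
  dropped and the row flagged.
* Quartile tie-break is inclusive; the cutoff rule (k-th smallest with
  k = ⌈n/4⌉) is recorded here because percentile-interpolation conventions
  differ across software.
* PolyPhen-2 "possibly damaging" (P) counts as damaging by default, as does
  "probably damaging"; the vocabularies are arguments, not constants.
* `save_signature()` writes doubles with 17 significant digits so metadata
  round-trips bit-exactly through JSON.

## Limitations

* Drug→pathway mapping is an input, not a curated resource.
* No hotspot-specific rules (e.g. BRAF V600 special-casing) — the consensus
  treats all protein-altering records alike.
* The nested models are linear in binary predictors; interaction and
  dose-response structure are out of scope.
* The exact normalization used by any particular external cohort is that
  cohort's business: results always carry the dialect actually applied, and
  cross-dialect application warns.
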