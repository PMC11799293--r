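---
title: "Methods: embedding age clocks and light-up attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: embedding age clocks and light-up attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

DNA methylation age clocks estimate chronological age from beta values
(methylation fractions β ∈ [0, 1]) of CpG sites. Penalised linear clocks use
a few hundred CpGs and discard the rest of the methylome; this package
implements the alternative of compressing all retained probes into a
low-dimensional autoencoder embedding, training neural age models on the
embedding, and interrogating the trained models with input perturbations to
recover CpG-level signatures of aging. Everything is exercised on synthetic
cohorts with planted, known age signal, so every stage of the stack is
testable end to end without array data.

## Models

### Preprocessing

Probes flagged as non-CpG, SNP-related, multi-hit, or not shared between
450K and EPIC manifests are removed; X/Y probes are kept only for
sex-chromosome-aware ("XY") models. Missing betas are imputed by k-nearest
neighbours with k = 10. The neighbour rule is fully specified so the result
is reproducible: distance is Euclidean over pairwise-complete observed
probes, donors must observe the missing probe, ties in distance break by
lexicographic sample id, and the unweighted donor mean is imputed (clipped to
[0, 1]). k-NN imputation is a convention for methylation arrays; published
pipelines delegate it to external packages whose metric and weighting are
unspecified, so the deterministic rule above is this package's own choice.

### Autoencoder

A feed-forward autoencoder with three hidden layers (default width 128 each;
the third is the latent code), leaky-ReLU activations (α = 0.3), a sigmoid
output layer so reconstructions stay in (0, 1), and MSE loss. The decoder
mirrors the encoder — the architecture description covers only the encoder
side, so the mirror is a design choice. Batch normalization and dropout
(p = 0.1) sit on every hidden layer, matching the supervised heads below.
Embeddings are the activations of the third hidden layer at inference
(dropout off, running batch-norm statistics).

### Supervised heads

Age regressors and single-year cutoff classifiers are three-hidden-layer
networks over embeddings, trained with Adam (learning rate 1e-4, β₁ = 0.9,
β₂ = 0.999, ε = 1e-7; inverse-time decay 1e-6 for regressors, exponential
schedule 0.95 per 1000 steps for classifiers), He-uniform initialisation,
dropout 0.1 and batch normalization (momentum 0.99, ε = 1e-3) per hidden
layer, and early stopping on an 80:20 validation split. The regressor
carries an L1 kernel penalty (λ = 0.01) on the third hidden layer and a
leaky-ReLU output over min–max-scaled ages (0 ↦ 0, 114 years ↦ 1); raw
predictions are unscaled back to years and may dip slightly below zero — they
are reported raw, with an optional clamp to [0, 114], to preserve the stated
architecture. The classifier carries an L2 penalty (λ = 1e-3) on the same
layer, a sigmoid output for P(age ≥ cutoff), binary cross-entropy loss, and
inverse-class-frequency sample weights. Classifier-array members derive
their seeds deterministically from (base seed, cutoff), so an array is
reproducible and each member coincides with direct training at that cutoff.

### Elastic-net clocks

CpG clocks minimise ½·MSE + λ(α‖w‖₁ + (1−α)/2·‖w‖₂²) with α = 0.5, fitted by
glmnet. When λ is not supplied it is selected by internal 5-fold CV over a
log-spaced grid [1e-4, 10]·λ_max. Retraining a published clock means fitting
this objective on that clock's probe set, with an intercept iff the original
had one. A constant response is handled, not rejected: the clock degenerates
to intercept = mean age with zero weights.

### Light-up attribution

Given a representative profile x (cohort mean by default; median available),
each probe j is perturbed one at a time toward hypermethylation (β = 1) and
hypomethylation (β = 0) and propagated through the chained encoder + head;
the delta is the change in the model outcome, in years for regressor chains
and on the probability scale for classifier chains. Perturbations are never
accumulated across probes: iteration is over probes, keeping deltas
independent of processing order. Both directions are always computed. The
default signature ranks probes by min(δ_hyper, δ_hypo) ascending — "most
negative first" — which captures age-lowering perturbations in either
direction; `most_positive` and `largest_magnitude` modes cover the other
readings of a ranked-δ selection, since the phrasing "increasing order of
negative δ" admits more than one. Ties break by probe id. For an affine
chain the implementation satisfies δⱼ = vⱼ(d − xⱼ) exactly, where v is the
end-to-end coefficient vector; this closed form is a property test.

### Benchmarking

Regression reports carry R², MAE, MedAE, RMSE, Pearson r and Spearman ρ.
Classification at a cutoff uses label 1 iff age ≥ cutoff; regressor outputs
are binarized with the same inclusive rule, while classifier probabilities
count positive only when strictly above 0.5 (the asymmetry is deliberate and
mirrored from the benchmarked convention). F1 is reported for the positive
class; `fpr_below` is the fraction of truly-old (≥ cutoff) samples predicted
below the cutoff, `fpr_above` the converse, `fpr_total` the overall error
rate — both error directions are "false positive rates" relative to the age
band they land in, which matches the narrative these metrics support (age
underestimation inflates FPRs below the threshold). AUROC is the midrank
Mann–Whitney statistic with half credit for ties. Wilson score intervals
cover classifier accuracies; the n entering the interval is always explicit.
Two five-fold schemes are provided: *young-age* (train on four young-age
folds, test on the fifth) and *complete-age* (train on four young-age folds
plus **all** auxiliary complete-age samples, test on the held-out young-age
fold). A leakage check — no test sample in its own training set — is part of
the test suite. Confidence intervals on fold-averaged metrics use a normal
approximation over fold values.

## The synthetic cohort generator

The generator emulates the structure of a whole-blood DNAm cohort: ages
drawn uniformly on a configurable range (default 0–100 years), a set of
informative probes whose logit-scale level moves with age, a majority of
noise probes, optional X/Y-labelled blocks with sex-dependent means, and
missing entries at a configurable rate. Signal lives on the logit scale —
β = logit⁻¹(b₀ + s·f(age) + ε) — so betas remain in (0, 1) without clipping
artifacts; linear-in-beta generation was rejected for that reason. `f` is
identity (linear trajectories) or τ(1 − e^(−age/τ)) with τ = 20 years
(saturating trajectories, emulating probes that change rapidly in youth and
plateau). Defaults: 500 samples × 2,000 probes with 100 informative CpGs,
per-year slopes 0.02–0.06 logit units with random sign, noise σ = 0.3,
baselines centred so informative probes stay in the responsive part of the
logistic curve. Slopes of a few hundredths of a logit unit per year and an
age-explained fraction dominating probe variance describe a strong, clean
aging axis; real arrays add batch effects, cell-composition drift and
technical noise that the generator deliberately omits. Passing tests
therefore demonstrate correctness and recoverability of planted signal at
favourable signal-to-noise, not expected performance on GEO-scale data.
Ages are uniform rather than matched to any empirical age histogram, which
makes regression metrics comparable across seeds.

## Numerical choices

* **Batch-norm running statistics are seeded from the first training
  batch** instead of (mean 0, variance 1). With the conventional
  initialisation, a (near-)constant input feature makes the
  training/inference normalisation mismatch *grow* through stacked BN
  layers (each divides by √(run_var + ε) → amplification up to 1/√ε), and
  since batch normalization of an exactly constant batch passes zero
  gradient to the weights below it, the mismatch can never train away.
  Warm-starting the statistics makes inference consistent with training
  from the first step and is negligible for non-degenerate data (the
  initial estimate decays with momentum 0.99 per step).
* **Fixed-λ elastic nets are reparameterised before calling glmnet.**
  glmnet standardises the gaussian response internally (population sd s_y),
  which makes its effective penalty λα‖w‖₁ + λ(1−α)‖w‖₂²/(2s_y) on the
  original scale. To honour the stated objective exactly at a user-supplied
  λ, the package calls glmnet with λ' = λ(α + (1−α)s_y) and
  α' = α/(α + (1−α)s_y); the mapping is verified against an independent
  coordinate-descent implementation in the test suite. CV-selected λ uses
  glmnet's own units (only the selected fit matters there).
* **Light-up deltas are computed in blocks with the unperturbed profile as
  the first row of every block**, so the baseline and the perturbed outputs
  share one batched matrix product. A no-op perturbation (probe already at
  the target value) and a disconnected probe (zero first-layer weights)
  then give deltas of *exactly* 0, not 1e-14.
* **k-NN imputation** computes all pairwise distances via three matrix
  cross-products over the observed-value masks; pairs with no shared
  observed probe get infinite distance, and a probe with no observing
  neighbour is an error rather than a silent fallback.
* **Degenerate inputs**: constant true ages make R² undefined (error);
  constant predictions make correlations undefined (NA, flagged); a cutoff
  producing a single class is an error naming the cutoff; F1 without
  positive-class samples is NA with an explicit `f1_defined = FALSE` flag,
  never a silent 0.
* **Determinism**: every training function takes an explicit seed, consumes
  it through a local RNG scope (the caller's RNG state is untouched), and
  derived seeds (validation split, shuffling, array members) come from a
  fixed integer hash kept below 2³¹.

## Desk-scale training budgets

The published training recipe fixes the learning rate (1e-4) and patience
(1000 epochs) but not the epoch budget, and its batch-size range (64–1024)
was tuned for cohorts of tens of thousands of samples. At the few-hundred-
sample scale of the test cohorts, an epoch contains only a handful of Adam
steps, and Adam moves each parameter by at most ≈ lr per step — so the step
*count*, not the epoch count, is what must be sized. The desk-scale
configurations used throughout the tests, the pipeline defaults and the
reproduction script therefore use batch 64 (regressors), the published
batch size 32 (classifiers), and epoch budgets of a few thousand, giving roughly
10⁴ optimiser steps; the autoencoder uses widths 64–32–16, learning rate
1e-2 and 250 epochs. Problem sizes in the suite: cohorts of 500 × 2,000
(parameter-recovery checks, three seeds), 300 × 800 (worked example), and
60–150 samples for unit-level properties. These are the package's choices
for small-n convergence; the full-scale defaults (width 128, batch 256)
remain the defaults of the specification objects
(`autoencoder_spec()`, `regressor_spec()`).

## Known limitations

* The network engine is plain R: ideal for the desk scale it targets
  (thousands of inputs, hundreds of samples), not for 384,629-probe arrays.
* Embeddings are computed once from a pretrained autoencoder; the
  cross-validation schemes retrain heads per fold but not the unsupervised
  compressor, mirroring the pretrained-compressor workflow.
* The generator omits batch effects, cell-type composition and array
  chemistry; enrichment inputs (GMT collections, gene maps, GO ancestor
  categories) are user-supplied data, not bundled knowledge.
* Published clocks' nonlinear age transforms are supported via a transform
  tag (identity default, Horvath-style log-linear available); which
  published coefficient sets used the transform must be declared by the
  user in the clock's JSON sidecar.
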