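---
title: "Methods: untargeted metabolomic classification of thyroid FNAC fluids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted metabolomic classification of thyroid FNAC fluids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fnacmet)
```

## The problem

Fine-needle aspiration cytology (FNAC) of thyroid nodules leaves an
indeterminate diagnosis in a quarter to a third of cases, and most of
those nodules turn out benign after diagnostic surgery. The fluid left
over after liquid-based cytology still contains the nodule's small
molecules, so an untargeted LC-MS metabolomic profile of that fluid is a
candidate ancillary test: measure thousands of ions, learn which handful
separate benign from malignant (papillary carcinoma) nodules, and
classify new samples from those few ions.

`fnacmet` implements that workflow end to end: per-run peak lists are
aligned into an ions-by-samples table, annotated against a compound
database, reduced by quality filters to analyzable ions, and a compact
ion signature is selected with a supervised autoencoder (SAE); PLS-DA
with permutation testing and SVM/random-forest comparators quantify how
much of the separation is real. Because cohorts of this kind are rarely
shareable, a synthetic-cohort generator with planted ground truth stands
in for patient data everywhere the package needs to be exercised or
tested.

## Feature construction

**Alignment.** Runs of one ion mode are aligned greedily in
lexicographic run order: each peak joins the existing feature minimising
`|ppm|/mz_tol + |dRT|/rt_tol` provided both tolerances hold (defaults 10
ppm, 1 min), otherwise it founds a new feature; within a run a feature
accepts at most one peak, the better-scoring peak winning conflicts.
Consensus m/z and RT are intensity-weighted means, updated run by run.
The greedy pass is order-dependent by construction — the run order is
fixed to make it deterministic — and on well-separated ions it matches
an exhaustive single-linkage clustering, which the test suite asserts on
small instances.

**Annotation.** Only the two proton adducts are considered: `[M+H]+` in
positive mode, `[M-H]-` in negative mode. A feature's neutral mass is
`mz ∓ 1.00727646` Da (CODATA proton mass; the electron mass is ~0.5 mDa
and irrelevant at a 15 ppm tolerance). Every compound whose monoisotopic
mass lies within 15 ppm yields one annotation; multiple candidates are
all retained, ranked by |ppm error|, since nothing in the data
disambiguates them.

**Filtering.** The ion-selection cascade runs annotation → mean
intensity → blank ratio → evidence flag. The mean-intensity floor (1e4,
inclusive) averages over *all* sample runs, counting non-detections as
zero — the conservative reading of "mean peak intensity". The blank
ratio (≥ 50, inclusive) compares the sample mean to the blank-run mean;
an ion absent from every blank is maximally sample-specific and is
retained outright rather than divided by an arbitrary floor. The
evidence flag models dual-software verification as a boolean and is off
by default. Each stage records removed ion ids, and the report conserves
counts exactly.

## Normalisation

Intensities are log-normal over orders of magnitude, so modelling works
on standardised log10 values: zeros are imputed with half the smallest
positive *training* intensity of the feature, then log10, then centring
and scaling by training statistics. The stated transform order
("mean-centered, scaled, and logarithm-transformed") is not executable
literally — centred values are negative — so the log is applied first,
matching the convention of the usual metabolomics platforms. Held-out
samples always reuse training parameters; inside cross-validation the
standardisation is redone per fold, so no information leaks from test
folds. A feature constant after log transform gets its SD floored at
1e-12 and maps to zero.

## PLS-DA, VIP and significance

PLS-DA is fitted by NIPALS PLS1 on a ±1 class coding (malignant = +1),
deflating both matrices after each component; prediction is the sign of
the regression output, with an exact zero resolved to the benign
majority class. R² is the cumulative fraction of response variance
explained in training; Q² is `1 − PRESS/TSS` from cross-validated
held-out predictions, so worthless models go negative. The variable
importance in projection is

  VIP_j = sqrt( p · Σ_a SS_a w_ja² / Σ_a SS_a ),

with unit-norm weight vectors and `SS_a = q_a² t_aᵀt_a`; the mean
squared VIP is identically 1, which the tests assert to 1e-10. The
reported component count maximises R² (smallest count on ties) with the
full curves alongside, because R² alone always favours the largest
model.

The permutation test refits the cross-validated model on label
permutations, using CV accuracy as the statistic (the source procedure
does not name its statistic; CV accuracy is the quantity we report
everywhere else), and applies the add-one rule
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`, which can never return 0.

## The supervised autoencoder

The SAE is a small dense network: encoder `p → 64 → 2` (ReLU hidden,
linear latent), a linear two-logit classifier on the latent layer, and a
mirror decoder. The loss is class-weighted cross-entropy plus `λ` times
the mean squared reconstruction error (`λ = 0.1`). Class weights default
to inverse class frequency, so the minority malignant class is not
drowned by the benign majority. Training is minibatch Adam (batch 16,
300 epochs); initialisation and batch order come from a private RNG
stream, making every fit bitwise reproducible given its seed.

The learning rate of 0.01 was chosen by design experiments on synthetic
cohorts of the package's target shape (78 samples, hundreds of ions):
smaller rates leave the network visibly undertrained within the epoch
budget (holdout accuracy barely above the majority rate), while 0.01
trains to convergence without instability. The reconstruction term is a
regulariser: at `λ = 0` the model is a plain classifier, and at absurdly
large `λ` the 2-D latent is spent on dominant variance directions and
classification degrades toward chance — both ends are pinned by tests.

**Feature scores.** The importance of feature `j` is the mean input
gradient of the logit difference (malignant − benign) over the training
samples, sign retained. The definition is architecture-agnostic — a dead
input scores exactly zero, duplicated inputs with identical wiring score
identically — and is checked against finite differences in the tests.
Whether the original procedure's score was a weight, gradient or
saliency is not recoverable; ours is documented rather than claimed
identical.

**Top-down selection.** Starting from all surviving ions, each round
keeps the top `ceiling(0.5 · p)` features by score magnitude (never
fewer than `k = 15`) and repeats until `k` remain, then refits on
exactly those `k`. Within a round the ranking score is averaged over
three replicate fits trained at a conservative learning rate (1e-3):
gently-trained replicas rank features by the reproducible class signal
rather than by whichever noise the run happened to fit, which roughly
doubled the recovery of planted informative ions in design experiments
(median 13/15 versus 9/15 from single hard-trained fits on synthetic
cohorts). The final refit uses the full configuration. The halving
schedule is a package choice; "step-by-step top-down" admits many.

**Confidence.** Per-class Gaussian kernel densities of the predicted
malignant probability (Silverman bandwidth per class, floored at 1e-3,
reflected at 0 and 1 so each density integrates to one on `[0, 1]`)
give each sample a confidence `d_own / (d_own + d_other)` at its own
predicted probability: 0.5 at the density crossing, near 1 where the
classes' probability distributions do not overlap.

## Evaluation harness

Performance is estimated by repeated stratified Monte-Carlo splits:
each repeat holds out `round(0.25 · n)` samples with class proportions
preserved to one sample (largest-remainder allocation). For a 56/22
cohort this yields test sets of 19–20, matching the per-fold
denominators evident in the reference fold tables, which are
incompatible with disjoint 12-fold partitions of 78 — hence "12-fold
cross-validation" is implemented as 12 repeats with a 0.25 test
fraction, both configurable. Metrics per split: global accuracy,
per-class accuracy (class recall), AUROC as Mann–Whitney concordance
with ties counted half (equal to trapezoidal ROC integration, asserted
exactly), and macro-averaged precision/recall/F1 — the source's
averaging convention is not recoverable from its printed values, so the
macro convention is fixed and stated. Aggregation is mean and sample SD
(n−1); full precision is kept internally and three decimals used for
reporting.

The four-model comparison (SAE, PLS-DA, and SVM/random forest from
`e1071`/`randomForest` behind the same train/predict contract) runs on
identical splits. By default the signature is frozen before splitting —
exactly how a once-selected signature is evaluated in practice, and
optimistic for that reason. `honest_signature_cv()` re-runs the
selection inside every training split; on null data it yields
chance-level accuracy, which the tests assert, quantifying that
optimism.

## The synthetic cohort generator

The generator emulates the study design the pipeline targets: 56 benign
and 22 malignant samples, 6 acetonitrile blanks, 3 pooled QCs, positive-
and negative-mode ion sets (5081/2609 at full scale), and 15 informative
ions whose benign/malignant mean-intensity ratios are the package's
default effect-size vector (0.554–7.002, i.e. |log2| ≈ 0.55–2.8), two of
them negative-mode. Intensities are log-normal: a per-feature base
log10 level (mean 4.8, SD 0.6), a symmetric class effect of
`±log10(ratio)/2`, and multiplicative biological noise with CV 0.35 —
no dispersion statistics are available for the real cohort, so this
value is an exposed assumption, and the package's stochastic guarantees
are stated at it. Retention times are uniform on 1–24 min of a 25-min
gradient.

Decoy structure is planted by counts, not by chance: 30% of
non-informative ions are constructed below the intensity floor, 25%
with blank contamination at sample/blank ratios drawn in [2, 40], and
45% of each stratum receives an m/z matching a compound-table adduct
(informative ions always do). Margins are enforced during generation —
passing ions sit well above 1e4, failing ones well below, contaminated
ratios stay below 45 — so each ion's fate through the cascade is exact
bookkeeping, not probability. Feature positions are kept separable
(close m/z implies distant RT) so alignment recovers the planted ions
one-to-one; per-run jitter is ≤3 ppm and ≤0.2 min. Compound masses keep
≥40 ppm mutual spacing so planted identities re-annotate uniquely.

What the generator does *not* emulate: instrument drift and batch
effects (the real QCs only monitor stability), correlated metabolite
modules, isotope envelopes and in-source fragments, missingness beyond
blank/threshold structure, and the hydrophilic dropout window of the
real chromatograms. Passing tests therefore demonstrate correctness of
the pipeline's logic and its behaviour under the stated statistical
model — not clinical performance on real fluids.

`fixture_cohort()` is the seed-locked miniature used throughout tests
and documentation: the full 78-sample design at 500 + 200 ions, 154 of
which survive the cascade by construction.

## Problem sizes and numerical choices

Tests and the acceptance script run desk-scale versions of every claim:
signature recovery uses twelve 500-ion cohorts (selection takes a few
dozen SAE fits each), the null calibration uses 200 permutation tests
at 99 permutations, and the end-to-end determinism check runs a
180-ion pipeline twice. SD floors are 1e-12 (standardisation), 1e-3
(KDE bandwidth); classification ties resolve to the benign majority
class; blank-absent ions bypass the ratio test; all seeds derive
deterministically from a single configured seed.

## Known limitations

The alignment is greedy and run-order dependent, as is the tool it
emulates; pathological peak clouds can split differently under other
orders. Annotation by accurate mass alone cannot separate isomers, and
MS2 verification is modelled only as a boolean flag. The SAE feature
score is one defensible definition among several. Frozen-signature
evaluation overstates generalisation — the honest mode exists precisely
to measure that gap — and all stochastic guarantees are statements
about the generator's model of the data, at its default noise level.
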