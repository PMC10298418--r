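---
title: "Benchmarking readers against AI: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking readers against AI: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readerbench)
```

This vignette is the package's account of its statistical content: the
aggregation and inference procedures, their assumptions, the parameters
that matter, what the synthetic-study generator does and does not emulate,
and the design decisions that were genuinely open.

## The setting

A multi-reader multi-case (MRMC) benchmark asks how a panel of human
readers compares to stand-alone AI classifiers on the *same* labelled case
set. Each reader scores a personal subset of cases on a 5-point ordinal
scale (1 "definitely without pathology" to 5 "definitely with pathology",
with 3 meaning "undefined"); each AI model returns a continuous
probability-of-pathology in [0, 1] at 0.01 precision for every case.
Ground truth is binary. Higher score always means more suspicious — that
orientation is fixed throughout the package.

## Consensus aggregation

### Reader side

`reader_consensus()` reduces a case's ratings to one number in three steps:

1. **Undefined-majority exclusion.** If strictly more than 50% of a case's
   scores equal 3, the case is excluded. The boundary matters: exactly half
   undefined does *not* exclude.
2. **Minimum-response filter.** Otherwise, a case with fewer than
   `min_responses` (default 5) ratings is excluded — except in specialist
   subgroup analyses, where the filter is off (`apply_min_filter = FALSE`).
   Small specialist panels would otherwise lose most cases. The rules are
   applied in this order; order affects only the recorded exclusion reason.
3. **Upper median.** The consensus is the ⌈(n+1)/2⌉-th order statistic of
   the scores, mapped to probability by (score − 1)/4.

The upper median deserves a note, because a rule stated as "the median,
with frequency ties resolved toward the higher score" is internally
inconsistent — frequencies belong to a mode, not a median. We read it as
the upper median: for odd n it is the ordinary median, and for even n it
resolves the only genuinely ambiguous situation (two central values) toward
the higher score. The alternative reading — most frequent score, frequency
ties to the higher score — is implemented as `rule = "mode_high"` for
sensitivity analysis; the default is the upper median.

Useful exact properties of this aggregation, all enforced by tests:
permutation invariance, unanimity (all scores s give consensus s),
monotonicity (raising one rating never lowers the consensus), and
invariance under duplicating the whole panel. Duplicating a *single*
reader, by contrast, can change an upper median (adding a second 5 to
{1, 4, 5} moves it from 4 to 5) — which is why the duplication test works
with whole-panel duplication and with median-scoring readers on odd-n
cases.

### AI side

AI models score on incomparable internal scales, so before averaging, each
model's scores are individually mapped to a common scale by the midrank
transform (midrank − ½)/m over the model's m scores. Two things recommend
this transform over supervised recalibration (Platt, isotonic-on-outcome):
it uses no ground-truth labels, so the ensemble cannot leak the endpoint it
is later evaluated on, and it is strictly increasing up to ties, so each
model's ROC curve and AUC are exactly preserved (a tested invariant). The
ensemble consensus is the per-case arithmetic mean of the calibrated
scores. No exclusion rules apply on the AI side: every model scores every
case by design, and a case without any AI score is reported, not silently
dropped.

## ROC inference

All inference runs on the **empirical** ROC; smoothing is display-only.
DeLong's variance estimator is defined for the empirical Mann–Whitney AUC,
and mixing a smoothed point estimate with an empirical variance would make
the CI incoherent.

* **AUC** — Mann–Whitney estimator with ties half-weighted, computed via
  midranks in O(n log n).
* **DeLong CI** — per-positive placements V₁₀ᵢ (fraction of negatives the
  i-th positive outranks) and per-negative placements V₀₁ⱼ; the variance is
  the sum of their *sample* variances (n−1 denominators, as in the original
  estimator and in pROC, which the tests use as an independent
  cross-check) divided by n₁ and n₀; the interval is the normal
  approximation truncated to [0, 1]. Under perfect separation the variance
  is zero and the degenerate interval [AUC, AUC] is returned with a
  warning rather than an error — small perfect groups are routine in
  subgroup analyses.
* **Youden operating point** — thresholds scanned over the distinct
  observed scores with predicted-positive meaning score ≥ t. The inclusive
  convention matters for ordinal consensus scales: a reported cutoff of
  "3" means an undefined case counts as positive. Ties in J are broken
  toward the *lowest* threshold, i.e. the highest sensitivity — the
  screening-appropriate choice, fixed so results are bit-reproducible.
  Se/Sp/accuracy carry exact Clopper–Pearson intervals; the exact interval
  is the only standard one whose x = n bound is (α/2)^(1/n), matching
  operating-point cells like 1.00(0.63–1.00) at n = 8.
* **Permutation comparison** — for two classifiers on the same cases, the
  null "equal AUROC" is generated by swapping, per case and with
  probability ½, the pair of scores between arms. Scores are first mapped
  to per-arm rank scales (midrank/n) so a swap is scale-free; the rank
  transform leaves each arm's AUC unchanged. The statistic is |ΔAUC|,
  two-sided by construction, with the add-one estimator
  p = (1 + #{stat* ≥ stat})/(B + 1), so p ≥ 1/(B+1) and p is never zero.
  Default B = 10,000. The paired scheme is the default because both arms
  are evaluated on an identical case set; an unpaired arm-reassignment
  scheme is available (`paired = FALSE`) for sensitivity analysis. An
  exhaustive 2ⁿ enumeration mode exists for small n and is tested against
  a brute-force oracle.
* **Smoothing** — the binormal model fitted by ordinary least squares on
  probit-transformed interior empirical points,
  Φ⁻¹(TPR) = a + b·Φ⁻¹(FPR), sampled on a fixed FPR grid, with implied
  AUC Φ(a/√(1+b²)). The exact smoothing method behind published smooth ROC
  figures is usually unstated; the binormal probit fit is the conventional
  choice for ordinal reader data and is transparent about its two
  parameters. With fewer than two interior points (e.g. perfect
  separation) the empirical curve is returned with a warning.

Confidence level is 95% everywhere by default and configurable once, in
`benchmark_config(level = )`.

## The benchmark pipeline

Per modality, `run_benchmark()` builds the AI ensemble consensus, then for
each reader group (all readers, the four experience bands 0–1, 1–5, 5–10,
10+ years, and for mammography the breast-specialist subgroups with the
minimum-response filter off) builds the reader consensus, drops excluded
cases, and runs all inference on the cases shared by the group's consensus
and the AI consensus. Comparisons are AI-vs-group only. The reported n is
the paired set size, which legitimately differs across rows: a band with
few readers loses more cases to the 5-response filter. The AI row itself is
evaluated on the cases shared with the all-readers consensus, so the AI and
all-readers rows are directly comparable. Groups with no usable cases
produce `insufficient_data` rows and the pipeline continues. Per-row
p-values are reported unadjusted, matching common practice for descriptive
benchmark tables; `holm = TRUE` applies a Holm correction within modality
for users who want familywise control. Display rounding is half-up to two
decimals; all stored values are full precision, which is why the identity
J = Se + Sp − 1 checks out exactly in `youden_identity_check()`.

## The synthetic-study generator

`simulate_study()` emulates the statistical structure the analysis
assumes, so the full pipeline is testable without any rating data:

* **Cases.** Fixed-margin labels: exactly round(n × prevalence) positives
  (hypergeometric design), because benchmark datasets are deliberately
  enriched to a fixed composition — prevalence is a design constant, not a
  random variable. Defaults: 140 cases (47 positive) X-ray, 184 (84)
  fluorography, 269 (167) mammography.
* **Readers.** An equal-variance binormal latent model: for a case with
  label y, a reader draws z ~ N(y·d, 1) with d = √2·Φ⁻¹(AUC_band), so the
  latent AUC equals the band's target exactly (AUC = Φ(d/√2)). The latent
  value is cut at four thresholds symmetric about d/2 with inner spacing
  0.75 SD — a fixed choice that populates all five categories at plausible
  rates. Independently, with probability `undefined_rate` (default 0.03) a
  rating is replaced by 3, emulating unreadable studies. Each reader rates
  a uniformly random subset of 20, 50 or 80 cases of one modality. Default
  band AUCs are 0.87/0.92/0.93/0.98, an experience gradient typical of
  published chest-radiograph reader studies.
* **AI models.** The same latent model, passed through a per-model
  strictly increasing logistic distortion plogis(αz + β) and rounded to
  0.01. The distortion emulates miscalibrated commercial models whose
  ranking is nonetheless sound; because it is monotone, each model's AUC
  is untouched up to rounding ties (a tested invariant).
* **Reproducibility.** Each `simulate_*` step runs in its own seeded
  substream derived from the config seed, so tables are bit-identical
  across runs and across component order.

### What the generator does *not* emulate

Readers (and AI models) are **conditionally independent given the label**.
Real readers share training, context and the image's difficulty, and real
commercial models share architectures and training corpora, so their
errors correlate strongly. Two visible consequences, worth understanding
before interpreting synthetic benchmarks:

1. A consensus over k independent readers is far more accurate than any
   individual — the median of many independent looks at the same case
   approaches the truth. With the default panel sizes (36–60 readers per
   X-ray band), the all-readers consensus separates the default case set
   perfectly, and AI ensembles of several independent models likewise
   exceed each member's AUC. Real consensus panels improve on individuals
   much more modestly. Passing pipeline tests on synthetic data therefore
   demonstrates correctness of the machinery, not realistic effect sizes.
2. The "average reader's" individual accuracy is recovered only in the
   sparse regime of about one rating per case, where consensus reduces to
   a single rating.

There is also no fatigue, learning, case-order or reading-time structure:
ratings are exchangeable within reader.

### Recovering generator parameters

Validating the generator means estimating each band's configured AUC back
from the simulated ratings. Two subtleties make the obvious estimator
biased, and both are properties of the analysis rules rather than bugs:

* **Discretisation.** Binning a continuous latent into 5 ordered
  categories costs the empirical (midrank) AUC about 0.006–0.013
  depending on d, because within-bin orderings become ties. (The
  frequently repeated claim that "only ordering matters for ROC" holds
  for monotone *relabelling*, not for *binning*.)
* **Exclusion interaction.** At ~1 rating per case, a single rating of 3
  is a 100% "undefined majority", so the exclusion rule removes exactly
  the ambiguous middle cases and inflates the surviving consensus AUC by
  roughly +0.02 at band AUC 0.87.

The unbiased route is the classic ordinal-ROC observation: for discretised
binormal data the interior empirical ROC points lie *exactly* on the
latent binormal curve, so the probit fit of `smooth_roc()` recovers the
configured AUC without discretisation bias. The parameter-recovery
acceptance test uses that estimator on pooled per-band ratings (measured
bias below 0.005 with SD ≈ 0.008 at 2000 cases, 25 readers per band, 80
cases per reader, undefined rate 0 — the undefined mechanism is deliberate
noise, excluded from a latent-recovery check); AI recovery uses the plain
empirical AUC, since continuous scores lose nothing to binning.

## Numerical conventions and degenerate inputs

* Ties everywhere are handled by midranks; the AUC tie convention is ½.
* Perfect separation: zero DeLong variance → degenerate CI plus warning;
  too few interior points → empirical curve plus warning.
* Constant-score models calibrate to 0.5 everywhere, with a warning.
* Single-class label vectors raise typed inference errors naming the
  missing class; malformed files raise typed validation errors naming the
  row or key — validation never silently drops records.
* Permutation p-values are floored at 1/(B+1); exhaustive enumeration is
  capped at n = 20 (2²⁰ patterns).
* Problem sizes in the test suite were chosen for tight Monte-Carlo
  control at interactive runtimes: 1000 replicates for DeLong coverage
  (binomial SE ≈ 0.7% around 95%), 500 replicates × 999 permutations for
  permutation-test uniformity, 2000 cases for parameter recovery.

## Known limitations

* No MRMC variance components (Obuchowski–Rockette, Dorfman–Berbaum–Metz):
  reader variability is deliberately collapsed into the consensus before
  inference, so CIs quantify case sampling only.
* No covariate-adjusted or partial-AUC analyses.
* The permutation and DeLong machinery assume exchangeable cases; clustered
  cases (multiple studies per patient) are not modelled.
* The generator's independence assumption above: synthetic consensus
  accuracy saturates quickly and should not be read as a realistic
  reader-panel effect size.
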