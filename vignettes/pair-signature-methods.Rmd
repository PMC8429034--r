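---
title: "Rank-based lncRNA pair signatures: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based lncRNA pair signatures: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Most expression-based prognostic signatures score a patient with a weighted
sum of absolute expression values, which makes them fragile across
platforms, normalizations and batches. The pair signature implemented here
replaces each feature with a *within-sample rank comparison*: for an
ordered pair of long noncoding RNAs (lncRNAs) `A|B`, the covariate is

    value(A|B, s) = 1  if expression of A exceeds expression of B in sample s
                    0  otherwise,

so only the ordering of two genes inside one sample matters. Any strictly
increasing per-sample transformation of the expression values (scaling,
log, quantile shifts) leaves the whole covariate matrix unchanged — the
property the test suite asserts directly. The patient-level risk score is
the linear predictor of a Cox proportional-hazards model on these binary
covariates,

    riskScore(s) = sum_i value(i, s) * coef(i),    i = 1..N,

with no intercept and no normalization; it takes at most `2^N` distinct
values and is additive over indicator patterns.

Candidate pairs are restricted to *immune-related, differentially
expressed* lncRNAs, found in two screening passes over a tumor/normal
expression matrix:

1. **Coexpression screen.** Every lncRNA × immune-gene combination is
   tested for Pearson correlation; a lncRNA is immune-related when some
   immune gene reaches `|r| >= 0.8` with Benjamini–Hochberg adjusted
   `p < 0.001`. P-values come from the exact t-transform of `r`. The BH
   family is the full lncRNA × immune-gene grid: the adjustment scope was
   genuinely open, and the grid-wide family is the conservative,
   order-independent choice.
2. **Differential expression.** Among immune-related lncRNAs, a per-feature
   two-sample Wilcoxon rank-sum test (tumor vs normal, tie-corrected normal
   approximation, no continuity correction) with BH adjustment; a feature
   is kept at `|log2 FC| >= 1` and `FDR < 0.05`. The log fold change is the
   difference of group means on the log2 scale. A nonparametric test was
   chosen because the pipeline makes no distributional claim about the
   expression values it is given; the absolute-value reading of the fold
   change cut is used because down-regulated candidates are legitimate
   pair members (a one-sided mode is available via `absolute = FALSE`).

All `k(k-1)/2` unordered pairs of the retained lncRNAs are then encoded as
above (canonical orientation: lexicographically smaller id first, so runs
are independent of input order; ties in expression score 0, consistent
with the strict "greater than" definition and measure-zero on continuous
data). The **stability filter** keeps a pair only when its ones-fraction
across patients lies strictly in (0.2, 0.8): a pair that is 0 or 1 in
(nearly) every patient carries no comparative information and would
destabilize the Cox fits. The bounds are exclusive — the most conservative
reading of "between 20% and 80%" — and configurable.

## Signature construction

Three nested selection stages, all operating on the stable pairs over the
survival cohort (tumor samples with usable follow-up):

1. **Univariate Cox screen** (`unicox_screen`): one Cox model per pair,
   Breslow tie handling (Efron available), Wald p `< 0.05` retained.
   Monotone-likelihood fits (infinite coefficients) are excluded with a
   warning rather than propagated.
2. **Cross-validated L1 Cox** (`lasso_cox_select`): an L1-penalized Cox
   path with seeded, event-stratified 10-fold cross-validation; pairs with
   nonzero coefficients at `lambda.min` (the penalty minimizing mean
   cross-validated partial-likelihood deviance) survive. The penalized
   stage is deliberately standard L1: nothing beyond lasso-plus-CV is
   needed to reproduce the funnel behavior, and `lambda.min` is the
   documented anchor.
3. **Bidirectional stepwise Cox** (`stepwise_multicox`): starting from the
   full model on the selected pairs, stepwise search minimizing
   `AIC = 2k − 2 log PL`. Selection is by AIC, not per-term significance —
   individually non-significant pairs can and do remain in the final
   model, as in the packaged reference signature (`kirc_signature()`,
   where one pair has Wald p = 0.156). Exactly duplicated indicator
   columns are collapsed to the first occurrence (deterministic
   tie-break).

Wald intervals and p-values are reported throughout because the signature
table schema (coef, HR, 95% CI bounds, p) is per-term; the identities
`HR = exp(coef)` and `HR = sqrt(HR_low * HR_high)` hold by construction
and are asserted on the packaged reference table at 1e-9/1e-6 relative
tolerance.

## Evaluation

**Time-dependent ROC.** Discrimination at a horizon `t` uses the
cumulative-case / dynamic-control definition (cases: event by `t`;
controls: beyond `t`) with Kaplan–Meier reweighting for censoring before
the horizon: writing `S(t)` for overall KM survival, `S(t|X>c)` for KM
survival among samples scoring above threshold `c`, and `F(c)` for the
empirical score CDF,

    sens(c) = (1 − F(c)) (1 − S(t|X>c)) / (1 − S(t))
    spec(c) = 1 − (1 − F(c)) S(t|X>c) / S(t).

With no censoring before the horizon this reduces exactly to the
empirical ROC, and the trapezoidal AUC equals the Mann–Whitney U
statistic — the oracle the tests compare against. The raw KM-weighted
estimates need not be monotone in `c`; they are clipped to [0, 1] and
monotonized by a running maximum along the threshold grid, which leaves
the uncensored case untouched. Incident/dynamic variants are out of
scope.

**Cutoff.** Two documented rules coexist for dichotomizing the score, and
they are not equivalent; the AIC rule is the default because it is the
more specific prescription. `"aic"`: every midpoint between consecutive
distinct scores is a candidate, each candidate's indicator enters a
one-covariate Cox model, lowest AIC wins (ties to the smaller cutoff;
candidates emptying a group are skipped; a flat AIC profile — range < 2 —
flags the result unstable). `"youden"`: maximize `sens + spec − 1` on the
horizon ROC; note the Youden threshold is an observed score value, so with
well-separated score clusters it sits at the boundary of the gap rather
than its middle. Scores strictly above the cutoff are `high` risk; exact
ties go to `low` ("high" means strictly elevated).

**Stratified survival.** Product-limit curves per risk group and the
two-sample log-rank test, via the survival package; the test suite pins
both to a hand-worked six-subject table.

## Associations

* Chi-square (Pearson, no continuity correction) of risk group against
  each categorical clinical variable, with `GX`/`NX`/`MX`/unknown levels
  excluded from the test but retained in the descriptive summary
  (count + within-group percentage to one decimal).
* Rank-sum tests of the risk score across the conventional clinical
  dichotomies (age >65/≤65, G1-2/G3-4, T1-2/T3-4, N0/N1, M0/M1, stage
  I-II/III-IV, gender). These comparisons are between independent groups,
  so the two-sample Mann–Whitney test is the correct procedure even where
  the source literature's wording says "signed-rank"; a signed-rank test
  requires paired data.
* Univariate and multivariate Cox with age (years), gender (binary),
  grade and stage (ordinal integer codes — the encoding of ordinal
  categories was unspecified and integer coding is the transparent
  default), and the risk score, to assess prognostic independence.
* Log-rank tests inside each of the 14 clinical subgroups (both sides of
  the seven dichotomies), with subgroups lacking both risk groups or
  having fewer than 2 events skipped and noted.
* Spearman correlation of the risk score with each immune-infiltration
  fraction (all reported, raw `p < 0.05` flagged — no multiplicity
  correction by default, matching the screening convention; BH can be
  applied downstream), rank-sum tests of checkpoint-gene expression
  (default set `PDCD1, CD247, CTLA4, TIGIT, LAG3`, configurable) and of
  the IC50-like drug-sensitivity score between risk groups. Infiltration
  estimation and drug-sensitivity prediction themselves are consumed as
  precomputed tables; running deconvolution or ridge-based sensitivity
  models is out of scope.

## The synthetic cohort generator

`simulate_cohort()` produces data with exactly the structure the analysis
assumes, so every stage is testable end to end without external data:

* **Expression.** Immune genes are Gaussian around per-gene baselines
  (unit residual SD). A linked lncRNA is `gene + offset + N(0, noise_sd)`
  with unit slope, giving population correlation
  `1/sqrt(1 + noise_sd^2 / var(gene))` — at the default `noise_sd = 0.3`,
  r ≈ 0.958, safely above the 0.8 screen; the closed form is verified
  against direct correlation of emitted matrices. The planted fold change
  is applied to the *partner immune gene* of each DE lncRNA and inherited
  through the coupling: planting it on the lncRNA alone would inject
  group variance uncorrelated with the gene and silently destroy the
  coexpression signal the screen relies on.
* **Pairs and survival.** The planted hazard-driving pairs are disjoint
  consecutive DE lncRNAs whose partner genes share a baseline mean and
  whose offsets are equal, so each indicator has ones-fraction near 0.5
  and survives the stability filter. Tumor event times are exponential
  with hazard `baseline_hazard * exp(sum coef_i * value_i)` computed from
  the *emitted* expression; censoring is independent exponential. The
  exponential/exponential choice satisfies proportional hazards exactly,
  which keeps parameter-recovery assertions clean.
* **Clinical covariates.** Age and gender are independent of risk (their
  association tests should be null); grade, stage, T, N, M are drawn with
  probabilities shifted toward advanced disease for samples in the top
  tertile of the linear predictor — tied to the risk tertile rather than
  to individual pairs, so association tests have planted signal without
  leaking pair membership. Normal samples carry `NA` survival and staging
  fields and never enter survival models.
* **Annotations.** A Tregs infiltration row, five checkpoint rows and an
  IC50-like drug score are coupled to the standardized linear predictor
  `z` through latents `w z + sqrt(1 − w^2) ε` (positive for
  Tregs/checkpoints, negative for drug), so a single `mixing_weight`
  controls all planted correlations: `w = 1` gives Spearman rho exactly
  ±1, `w = 0` independence. The default `w = 0.6` produces observed
  Spearman rho around 0.5 — the strength of reported
  infiltration–risk correlations in this literature. Fractions are mapped
  through a probit link into [0.05, 0.30], within the plausible range for
  a single cell type.

Default sizes follow the cohort regime the method targets (539 tumor, 72
normal samples; survival in days with baseline hazard 4e-4/day and
censoring 4e-4/day, giving multi-year follow-up with roughly 40%
censoring). The feature space defaults to 300 lncRNAs and 120 immune
genes — deliberately smaller than a full transcriptome, since the
screening mathematics is size-independent and examples stay fast; planted
effects default to `de_log2fc = 2` and pair coefficients `(1, −1, 0.9)`,
i.e. clearly detectable but not trivial at these sample sizes.

**What the generator does not emulate:** negative-binomial count noise,
batch effects, tumor purity, correlated lncRNA co-regulation beyond the
single-gene coupling, non-proportional hazards, informative censoring,
and realistic missingness patterns. Passing tests therefore demonstrate
that the machinery is correct and calibrated under the model's own
assumptions — not that the signature generalizes to any particular real
cohort.

## Verification approach and problem sizes

The test suite pins each computational stage to an independent oracle:
brute-force double-loop pair construction (200 random matrices up to 6×8),
direct maximization of the Breslow partial likelihood, a hand-worked
six-subject Kaplan–Meier/log-rank table, Mann–Whitney pair counting for
the uncensored horizon AUC, a step-up reimplementation of BH, and the
packaged reference signature's analytic identities. Parameter recovery
runs the *entire* pipeline on 20 seeded cohorts (300 tumor samples, 3
planted pairs with |coef| ≥ 0.8, fold change 2, coupling noise 0.3) and
requires ≥ 80% of planted pairs in the final signature on average with
mean absolute univariate-Cox coefficient error ≤ 0.25; null calibration
permutes labels and checks the DE flag rate and the univariate-Cox
retention rate against their nominal levels. These sizes keep the full
suite under a minute on one core while leaving Monte-Carlo error well
inside the asserted margins.

## Known limitations

* The screening stages test each feature marginally; no attempt is made
  to model correlation among lncRNAs beyond the BH adjustment.
* `lambda.min` selection is seeded but fold-split dependent; on real data
  the post-lasso pair count varies with the split (the stepwise stage
  absorbs most of that variation).
* The AIC cutoff search refits one Cox model per distinct score value,
  which is quadratic-ish for near-continuous scores; for the ≤ `2^N`
  distinct values a pair signature produces this is negligible.
* The time-dependent ROC estimator can be non-monotone under heavy early
  censoring before monotonization; confidence bands are not provided.
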