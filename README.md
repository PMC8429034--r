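# lncPairSig

Rank-based prognostic signatures from pairs of immune-related long
noncoding RNAs (lncRNAs), for survival analysis of bulk tumor expression
cohorts — built for the setting where absolute expression levels cannot be
trusted across platforms or batches, as in TCGA-style kidney clear cell
renal cell carcinoma (KIRC/ccRCC) cohorts.

Instead of weighting expression values, the signature scores each patient
from *within-sample rank comparisons*: for a lncRNA pair `A|B` the
covariate is 1 when `A` is expressed above `B` in that sample and 0
otherwise, so the model is invariant to any strictly increasing per-sample
transform of the data. The per-patient risk score is the Cox linear
predictor over the `N` signature pairs,

    riskScore = Σᵢ value(i) · coef(i),   value(i) ∈ {0, 1},

with no intercept and no normalization.

The pipeline mirrors the full published workflow:

1. **Screen** — Pearson coexpression against a curated immune-gene list
   (`|r| ≥ 0.8`, BH-adjusted `p < 0.001`) finds immune-related lncRNAs;
   a Wilcoxon rank-sum test between tumor and normal (`|log2FC| ≥ 1`,
   `FDR < 0.05`) keeps the differentially expressed ones.
2. **Pair** — all pairwise 0/1 indicators over the survival cohort, kept
   only when the ones-fraction lies strictly between 20% and 80% of
   patients (the stability filter).
3. **Fit** — univariate Cox screen (`p < 0.05`) → seeded 10-fold
   cross-validated L1 Cox (`lambda.min`) → bidirectional AIC-stepwise
   multivariate Cox → risk scores.
4. **Evaluate** — KM-weighted time-dependent ROC at 1/2/3 years, AIC-optimal
   cutoff, high/low risk groups, Kaplan–Meier curves and the log-rank test.
5. **Associate** — chi-square against clinicopathological variables,
   rank-sum tests across clinical dichotomies, univariate + multivariate
   Cox for prognostic independence, per-subgroup log-rank, and Spearman /
   rank-sum associations with immune infiltration fractions, checkpoint
   expression (`PDCD1, CD247, CTLA4, TIGIT, LAG3`) and an IC50-like
   drug-sensitivity score (both consumed as precomputed tables).

A synthetic-cohort generator (`simulate_cohort()`) produces
tumor/normal expression, survival, clinical covariates and
infiltration/checkpoint/drug annotations with planted, recoverable ground
truth, so the entire pipeline is testable without external downloads. The
package also ships the published 12-pair KIRC reference signature
(`kirc_signature()`) and the matching 530-patient clinical contingency
counts (`kirc_clinical_counts()`) as plain-text fixtures.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
cohort (539 tumor / 72 normal samples, 3 planted hazard-driving pairs
with coefficients 1, −1, 0.9) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_screen.R
Rscript analysis/03_pair.R
Rscript analysis/04_fit.R
Rscript analysis/05_evaluate.R
Rscript analysis/06_associate.R
```

Output of a run (seed 1):

```
60 of 300 lncRNAs are immune-related (60 passing tests)
16 DEirlncRNAs (16 up, 0 down)
120 pairs from 16 DEirlncRNAs; 50 stable (20-80% rule)
24 of 50 pairs pass the univariate Cox screen
13 pairs selected at lambda.min
final signature: 9 pairs (AIC 3168.3); 539 patients scored
AUC at 1/2/3 years: 0.782 / 0.783 / 0.790
cutoff 0.7720 (AIC 3228.8): 238 high / 301 low; log-rank chisq 136.0, p 1.96e-31
chi-square p by variable: gender=0.582, grade=1.28e-07, stage=0.000147, ...
riskScore HR: univariate 2.718 (p 3.7e-41), multivariate 2.718 (p 2.6e-37)
Tregs rho 0.543 (p 9.8e-43); drug score median diff high-low -0.915 (p 4.6e-27)
```

Reading this: the screen recovers exactly the 60 immune-coupled and 16
differentially expressed lncRNAs that were planted; the final 9-pair
signature contains all 3 hazard-driving pairs; discrimination exceeds
AUC 0.78 at every horizon; the high-risk group has sharply worse survival;
grade/stage/T/N/M associate with risk while gender does not (age and
gender are generated independent of risk); the risk score is an
independent prognostic factor with hazard ratio ≈ e per unit (the planted
per-pair log-hazard is 1); regulatory T cell infiltration rises with risk
and the drug-sensitivity (IC50-like) score falls — the planted direction
pattern.

Equivalent one-call API: `run_pipeline_cohort(simulate_cohort(sim_params()),
pipeline_config())`, or `run_pipeline()` on your own expression matrix,
biotype annotation (`extract_biotypes()` reads GTF or two-column TSV),
immune-gene list and clinical table.

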