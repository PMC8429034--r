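#!/usr/bin/env Rscript
# Stage 4: construct the prognostic signature.
#
# Univariate Cox keeps pairs with Wald p < 0.05; seeded 10-fold
# cross-validated L1 Cox keeps the pairs active at lambda.min; a
# bidirectional AIC stepwise multivariate Cox gives the final model. Each
# patient's risk score is sum(value_i * coef_i) over the final pairs.
# Writes signature.tsv and risk_scores.tsv.

library(lncPairSig)

seed <- 1
pm <- read_pair_matrix("results/pair_matrix.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")

uni <- unicox_screen(pm, clinical, alpha = 0.05)
message(sprintf("%d of %d pairs pass the univariate Cox screen",
                nrow(uni), nrow(pm$values)))

sel <- if (nrow(uni) > 1) {
  lasso_cox_select(subset_pairs(pm, pairs = uni$pair_id), clinical,
                   n_folds = 10, seed = seed + 1)
} else uni$pair_id
message(sprintf("%d pairs selected at lambda.min", length(sel)))

sig <- stepwise_multicox(sel, pm, clinical)
print(sig)
write.table(sig$table, "results/signature.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

risk <- compute_risk_scores(sig, pm)
write.table(risk, "results/risk_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("final signature: %d pairs (AIC %.1f); %d patients scored",
                sig$n_pairs, sig$aic, nrow(risk)))
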