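#!/usr/bin/env Rscript
# Stage 6: clinical, immune and drug associations of the risk model.
#
# Chi-square tests of risk group against the clinicopathological
# variables, rank-sum tests of the risk score across clinical dichotomies,
# univariate + multivariate Cox for prognostic independence, per-subgroup
# log-rank tests, and Spearman/rank-sum associations with immune
# infiltration, checkpoint expression and drug sensitivity. Writes
# clinical_assoc.tsv, cox_independence.tsv, subgroup_logrank.tsv and
# immune_drug.tsv.

library(lncPairSig)

clinical <- read_clinical("results/cohort/clinical.tsv")
grp <- read.delim("results/groups.tsv")

cc <- chisq_clinical(grp, clinical)
write.table(cc$tests, "results/clinical_assoc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cc$summary, "results/clinical_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("chi-square p by variable: ",
        paste(sprintf("%s=%.3g", cc$tests$variable, cc$tests$p),
              collapse = ", "))

rs <- do.call(rbind, lapply(
  c("age", "gender", "grade", "stage", "t_stage", "n_stage", "m_stage"),
  function(v) tryCatch(ranksum_by_subgroup(grp, clinical, v),
                       error = function(e) NULL)))
write.table(rs, "results/score_by_subgroup.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cx <- cox_independence(grp, clinical)
write.table(cx, "results/cox_independence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
rsc <- cx[cx$variable == "riskScore", ]
message(sprintf(
  "riskScore HR: univariate %.3f (p %.2g), multivariate %.3f (p %.2g)",
  rsc$hr[1], rsc$p[1], rsc$hr[2], rsc$p[2]))

sub <- subgroup_survival(grp, clinical)
write.table(sub, "results/subgroup_logrank.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

infil <- local({
  df <- read.delim("results/cohort/infiltration.tsv", check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]; m
})
chk <- local({
  df <- read.delim("results/cohort/checkpoints.tsv", check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]; m
})
drug <- local({
  df <- read.delim("results/cohort/drug_scores.tsv")
  setNames(df$drug_score, df$sample_id)
})
ida <- immune_drug_correlations(grp, infil, chk, drug)
write.table(ida, "results/immune_drug.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tre <- ida[ida$variable == "Tregs", ]
dr <- ida[ida$family == "drug", ]
message(sprintf(
  "Tregs rho %.3f (p %.2g); drug score median diff high-low %.3f (p %.2g)",
  tre$effect, tre$p, dr$effect, dr$p))
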