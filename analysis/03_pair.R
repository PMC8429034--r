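#!/usr/bin/env Rscript
# Stage 3: build the 0-or-1 DEirlncRNA pair matrix over the survival cohort
# and keep the pairs whose ones-fraction is stable between 20% and 80% of
# the patients. Writes pair_matrix.tsv (stable pairs only).

library(lncPairSig)

groups <- read.delim("results/cohort/groups.tsv")
expr <- read_expression("results/cohort/expression.tsv",
                        setNames(groups$group, groups$sample_id))
clinical <- read_clinical("results/cohort/clinical.tsv")
de <- read.delim("results/DEirlncRNA.tsv")

de_ids <- de$lnc_id[de$de]
surv_ok <- clinical$sample_id[!is.na(clinical$os_time) &
                                !is.na(clinical$os_event)]
tum <- tumor_samples(subset_expr(expr, features = de_ids))
tum <- subset_expr(tum, samples = intersect(colnames(tum$values), surv_ok))

pm <- build_pair_matrix(tum)
pm_stable <- filter_stable_pairs(pm, low = 0.2, high = 0.8)
write_pair_matrix(pm_stable, "results/pair_matrix.tsv")
message(sprintf("%d pairs from %d DEirlncRNAs; %d stable (20-80%% rule)",
                nrow(pm$values), length(de_ids), nrow(pm_stable$values)))
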