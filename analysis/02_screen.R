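#!/usr/bin/env Rscript
# Stage 2: screen for immune-related, differentially expressed lncRNAs.
#
# Pearson coexpression of every lncRNA against every immune gene retains
# lncRNAs with |r| >= 0.8 and BH-adjusted p < 0.001; a Wilcoxon rank-sum
# test between tumor and normal then flags the immune-related lncRNAs with
# |log2 FC| >= 1 and FDR < 0.05. Writes irlncRNA_hits.tsv and
# DEirlncRNA.tsv.

library(lncPairSig)

groups <- read.delim("results/cohort/groups.tsv")
expr <- read_expression("results/cohort/expression.tsv",
                        setNames(groups$group, groups$sample_id))
annotation <- setNames(
  ifelse(startsWith(rownames(expr$values), "LNC"), "lncRNA",
         "protein_coding"),
  rownames(expr$values))
immune <- grep("^IRG", rownames(expr$values), value = TRUE)

parts <- split_by_biotype(expr, annotation, immune)
scr <- correlate_immune(parts$lnc, parts$irgene,
                        r_min = 0.8, p_adj_max = 0.001)
write.table(scr$hits, "results/irlncRNA_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d lncRNAs are immune-related (%d passing tests)",
                length(scr$ids), nrow(parts$lnc$values), nrow(scr$hits)))

de <- differential_expression(subset_expr(parts$lnc, features = scr$ids),
                              logfc_min = 1, fdr_max = 0.05)
write.table(de, "results/DEirlncRNA.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d DEirlncRNAs (%d up, %d down)",
                sum(de$de), sum(de$de & de$direction == "up"),
                sum(de$de & de$direction == "down")))
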