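#!/usr/bin/env Rscript
# Differential expression of the knockdown experiment: moderated-t contrast
# (knockdown minus control, log2 scale) with Benjamini-Hochberg FDR.

library(modnet)

cfg <- yaml::read_yaml("results/synthetic_study/config.yaml")
expr_df <- utils::read.delim(cfg$expression, check.names = FALSE)
expr <- as.matrix(expr_df[-1]); rownames(expr) <- expr_df[[1]]
groups_df <- utils::read.delim(cfg$groups)
groups <- groups_df$group[match(colnames(expr), groups_df$sample)]

dge <- dge_contrast(expr, groups, control = "control")
write_dge_table(dge, "results/dge.tsv")
sig <- dge[dge$significant, ]
cat(sprintf("%d of %d genes significant at FDR %.2f\n",
            nrow(sig), nrow(dge), attr(dge, "alpha")))
cat(sprintf("seed gene %s: logFC %.2f (down-regulated in knockdown: %s)\n",
            cfg$seed_gene, dge$logFC[dge$gene == cfg$seed_gene],
            dge$logFC[dge$gene == cfg$seed_gene] < 0))
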