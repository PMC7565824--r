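#!/usr/bin/env Rscript
# Variant-classification arithmetic over the bundled gnomAD and ClinVar
# count tables for the ten candidate genes: totals, truncated percentages,
# and per-column top genes.

library(modnet)

gnomad <- read_counts(system.file("extdata", "gnomad_variant_counts.tsv",
                                  package = "modnet"), "gnomad")
clinvar <- read_counts(system.file("extdata", "clinvar_variant_counts.tsv",
                                   package = "modnet"), "clinvar")

summary <- data.frame(
  quantity = c("gnomad_total", "clinvar_germline_total", "vus_percent_overall",
               "vus_percent_egfr", "plp_percent_pten", "plp_percent_braf",
               "missense_percent_egfr"),
  value = c(total(gnomad, "all"), total(clinvar, "all"),
            fraction(clinvar, "vus"), fraction(clinvar, "vus", gene = "EGFR"),
            fraction(clinvar, "p_lp", gene = "PTEN"),
            fraction(clinvar, "p_lp", gene = "BRAF"),
            fraction(gnomad, "missense", gene = "EGFR")))
print(summary, row.names = FALSE)
cat(sprintf("most variants overall (gnomAD): %s | most P/LP (ClinVar): %s\n",
            argmax_gene(gnomad, "all"), argmax_gene(clinvar, "p_lp")))
utils::write.table(summary, "results/variant_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
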