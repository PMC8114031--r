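#!/usr/bin/env Rscript
# EV-proteome fold-change / significance classification of the published
# quantitation tables: peptide-treatment contrasts (table 1) and the CD9-KO
# vs wt contrast (table 2), with the 1.5 / 0.66 fold thresholds and the
# significance-20 gate (p <= 0.01), plus log2 coordinates for the
# two-contrast plot.

library(spotMSI)

dir.create("results/proteins", showWarnings = FALSE, recursive = TRUE)

t1 <- read_protein_table(system.file("extdata",
        "ev_protein_ratios_cd9_cd63_peptides.tsv", package = "spotMSI"))
t2 <- read_protein_table(system.file("extdata",
        "ev_protein_ratios_cd9ko_wt.tsv", package = "spotMSI"))

t1$label_cd9pep <- classify_fold_change(t1, "cd9pep_sc")
t1$label_cd63pep <- classify_fold_change(t1, "cd63pep_sc")
t2$label_cd9ko <- classify_fold_change(t2, "cd9ko_wt")

cat("peptide-treatment table:", nrow(t1), "proteins\n")
print(table(cd9pep = t1$label_cd9pep, cd63pep = t1$label_cd63pep))
cat("\nCD9-KO table:", nrow(t2), "proteins\n")
print(table(t2$label_cd9ko))
cat("\nCD63 row: ratio", t2$ratio_cd9ko_wt[t2$gene == "CD63"],
    "-> label", t2$label_cd9ko[t2$gene == "CD63"],
    "(significance", t2$significance[t2$gene == "CD63"],
    "is below the gate; by ratio alone it is",
    classify_fold_change(t2[t2$gene == "CD63", ], "cd9ko_wt",
                         min_significance = 0), ")\n")

write.table(t1[, c("gene", "accession", "significance", "ratio_cd9pep_sc",
                   "ratio_cd63pep_sc", "label_cd9pep", "label_cd63pep")],
            "results/proteins/peptide_contrasts_classified.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(t2[, c("gene", "accession", "significance", "ratio_cd9ko_wt",
                   "label_cd9ko")],
            "results/proteins/cd9ko_contrast_classified.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

xy <- ratio_plot_coords(t1, "cd9pep_sc", "cd63pep_sc")
write.table(xy, "results/proteins/ratio_plot_coords.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("\nratio plot: %d significant proteins; threshold lines at +/- %.2f\n",
            nrow(xy), attr(xy, "threshold")))
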