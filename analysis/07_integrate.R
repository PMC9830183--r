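#!/usr/bin/env Rscript
# Stage 7: intersect the three detection arms into the putative toolkit
# (SVM predictors common to all species ∩ network trait-associated genes),
# report all pairwise and three-way overlaps with named denominators, and
# score recovery against the planted truth.

library(castemeta)

svm_set <- read.delim("results/svm_predictors_common.tsv")$gene
wgcna_set <- read.delim("results/network_trait_genes.tsv")$gene
de_set <- read.delim("results/de_overlap.tsv")$gene
truth_json <- jsonlite::read_json("results/data/truth.json",
                                  simplifyVector = TRUE)
truth <- structure(list(toolkit_gene_ids = truth_json$toolkit_gene_ids,
                        clade_specific_gene_ids =
                          truth_json$clade_specific_gene_ids,
                        module_membership = unlist(truth_json$module_membership),
                        trait_modules = truth_json$trait_modules),
                   class = "synthetic_truth")

report <- build_toolkit(svm_set, wgcna_set, de_set, truth = truth)
print(report)
cat(sprintf("SVM ∩ DE: %d (%.1f%% of SVM set); WGCNA ∩ DE: %d (%.1f%% of WGCNA set)\n",
            length(report$intersections$svm_de), report$percentages$de_of_svm,
            length(report$intersections$wgcna_de),
            report$percentages$de_of_wgcna))

write.table(data.frame(gene = report$toolkit), "results/toolkit.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/toolkit.tsv\n")
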