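#!/usr/bin/env Rscript
# Stage 1: generate the synthetic six-species, two-clade study.
#
# Emulates the structure of the cross-species brain transcriptome design:
# 300 orthogroups x 96 samples (8 reproductive + 8 non-reproductive females
# per species), negative-binomial counts with a dominant species signal,
# 40 planted "toolkit" genes with sign-consistent phenotype effects in all
# species, 10 clade-restricted effect genes per clade, and 4 latent
# co-expression modules of which one tracks phenotype. Writes the on-disk
# formats the pipeline consumes (per-species counts TSVs, metadata TSV,
# an OrthoFinder-style Orthogroups.tsv, truth JSON) under results/data/.

library(castemeta)

cfg <- sim_config(n_genes = 300, n_toolkit_genes = 40, toolkit_lfc = 1.5,
                  n_clade_specific_genes = 10, n_modules = 4,
                  module_size_range = c(15, 25), n_trait_modules = 1,
                  n_samples_per_phenotype = c(8, 8), seed = 20260101)
sim <- simulate_dataset(cfg)
paths <- write_dataset(sim, "results/data")

cat(sprintf("simulated %d orthogroups x %d samples (%d species)\n",
            nrow(sim$dataset$counts), ncol(sim$dataset$counts),
            length(unique(sim$dataset$samples$species))))
cat(sprintf("planted: %d toolkit genes, %d clade-specific genes, %d modules (%d trait-linked)\n",
            length(sim$truth$toolkit_gene_ids),
            length(unlist(sim$truth$clade_specific_gene_ids)),
            max(sim$truth$module_membership),
            length(sim$truth$trait_modules)))
cat("wrote:", length(paths), "files under results/data\n")
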