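#!/usr/bin/env Rscript
# Stage 3: does global brain expression cluster by phylogeny or by
# phenotype? PCA on the species-aware VST matrix, Pearson screening of the
# top components against clade / species / phenotype codings with joint BH
# correction, and a within-species label-shuffle control for the phenotype
# statistic.

library(castemeta)

species <- sub("^counts_(.*)\\.tsv$", "\\1",
               list.files("results/data", pattern = "^counts_"))
counts <- lapply(species, function(s)
  read_counts(file.path("results/data", paste0("counts_", s, ".tsv"))))
names(counts) <- species
meta <- read_metadata("results/data/metadata.tsv")
og <- read_orthogroups("results/data/Orthogroups.tsv")
ds <- assemble_ortho_matrix(counts, og, meta)
vst <- variance_stabilize(ds)

pca <- run_pca(vst)
cat(sprintf("top 5 PCs explain %.1f%% of variance\n",
            100 * sum(pca$explained_variance_fraction[1:5])))

screen <- trait_correlation_screen(
  pca, ds$samples[, c("clade", "species", "phenotype")], n_top = 10)
write.table(screen, "results/pca_trait_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (trait in c("clade", "species", "phenotype")) {
  ve <- trait_variance_explained(pca, screen, trait)
  cat(sprintf("variance accounted for by %s (significant PCs, r^2-weighted): %.1f%%\n",
              trait, 100 * ve))
}

ctl <- randomized_phenotype_control(pca, n_top = 10, n_shuffles = 200,
                                    seed = 20260103)
cat(sprintf("max |r(PC, phenotype)| observed %.3f; null 95%% quantile %.3f (empirical quantile %.3f)\n",
            ctl$observed, quantile(ctl$null, 0.95), ctl$quantile))
cat("wrote results/pca_trait_screen.tsv\n")
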