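#!/usr/bin/env Rscript
# Stage 4: leave-one-species-out SVM recursive feature elimination.
#
# Each species in turn is held out as the test set; a radial-kernel
# C-classification SVM is tuned by 3-fold CV over gamma {1e-7..1e-5} and
# cost {8,16,32}, the lowest-|weight| gene removed, and the cycle repeated
# down to 20 genes. The best model per focal species (lowest held-out
# error, margin score breaking ties) defines its predictor gene set; the
# intersection across all six species is the SVM arm of the toolkit.
# A 100-shuffle randomization of the focal labels tests each best model.

library(castemeta)

species <- sub("^counts_(.*)\\.tsv$", "\\1",
               list.files("results/data", pattern = "^counts_"))
counts <- lapply(species, function(s)
  read_counts(file.path("results/data", paste0("counts_", s, ".tsv"))))
names(counts) <- species
meta <- read_metadata("results/data/metadata.tsv")
og <- read_orthogroups("results/data/Orthogroups.tsv")
ds <- assemble_ortho_matrix(counts, og, meta)
scaled <- center_scale(variance_stabilize(ds), scope = "per_species")

svm_res <- run_svm_rfe(scaled, svm_config(rfe_floor = 20, seed = 20260104))

for (s in names(svm_res$per_species)) {
  r <- svm_res$per_species[[s]]
  cat(sprintf("%s: best model %d genes, held-out error %.3f, randomization p %.4f\n",
              s, length(r$predictor_genes), r$test_error,
              svm_res$randomization[[s]]$p))
}
common <- svm_res$intersection$common_all
cat(sprintf("predictor genes common to all %d species: %d\n",
            length(svm_res$per_species), length(common)))

write.table(data.frame(gene = common), "results/svm_predictors_common.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
ranks <- do.call(cbind, lapply(svm_res$per_species, function(r) r$gene_ranks))
write.table(data.frame(gene = rownames(ranks), ranks, check.names = FALSE),
            "results/svm_rank_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/svm_predictors_common.tsv and results/svm_rank_matrix.tsv\n")
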