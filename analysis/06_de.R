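#!/usr/bin/env Rscript
# Stage 6: conventional differential expression baseline.
#
# Per-species negative-binomial Wald tests between phenotypes at FDR 0.05
# (with permutation balancing when group sizes are unequal), a joint
# clade-adjusted model over all samples, and cross-species overlap counts
# of the significant orthogroups.

library(castemeta)

species <- sub("^counts_(.*)\\.tsv$", "\\1",
               list.files("results/data", pattern = "^counts_"))
counts <- lapply(species, function(s)
  read_counts(file.path("results/data", paste0("counts_", s, ".tsv"))))
names(counts) <- species
meta <- read_metadata("results/data/metadata.tsv")
og <- read_orthogroups("results/data/Orthogroups.tsv")
ds <- assemble_ortho_matrix(counts, og, meta)

de <- run_de(ds, alpha = 0.05, seed = 20260106)
for (s in names(de$significant))
  cat(sprintf("%s: %d significant orthogroups\n", s,
              length(de$significant[[s]])))
cat(sprintf("orthogroups significant in >= 2 species: %d (max shared: %d of %d)\n",
            length(de$overlap$common), de$overlap$max_shared_species,
            length(de$significant)))
cat(sprintf("joint clade-adjusted model: %d significant\n",
            sum(de$joint_clade$p_adj < 0.05, na.rm = TRUE)))

write.table(data.frame(gene = de$overlap$common), "results/de_overlap.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
for (s in names(de$per_species))
  write.table(de$per_species[[s]],
              file.path("results", paste0("de_", s, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote per-species DE tables and results/de_overlap.tsv\n")
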