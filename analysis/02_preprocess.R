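#!/usr/bin/env Rscript
# Stage 2: read the on-disk inputs back, assemble the orthogroup matrix
# under the nearly-single-copy policy (<= 3 copies per species, absent in
# <= 1 species), and apply the three transformations every downstream
# stage relies on: median-of-ratios size factors, the species-aware
# variance-stabilizing transform, and per-species center-scaling.

library(castemeta)

species <- sub("^counts_(.*)\\.tsv$", "\\1",
               list.files("results/data", pattern = "^counts_"))
counts <- lapply(species, function(s)
  read_counts(file.path("results/data", paste0("counts_", s, ".tsv"))))
names(counts) <- species
meta <- read_metadata("results/data/metadata.tsv")
og <- read_orthogroups("results/data/Orthogroups.tsv")
cat(sprintf("orthogroups retained: %d, dropped: %d\n",
            length(og$map), nrow(og$log)))

ds <- assemble_ortho_matrix(counts, og, meta)
vst <- variance_stabilize(ds, species_aware = TRUE)
cat(sprintf("transform: %s; dispersion trend asympt=%.4f extra_pois=%.4f\n",
            vst$transform, vst$dispersion_trend["asympt"],
            vst$dispersion_trend["extra_pois"]))
scaled <- center_scale(vst, scope = "per_species")

dir.create("results", showWarnings = FALSE)
write.table(data.frame(sample_id = ds$samples$sample_id,
                       size_factor = vst$size_factors),
            "results/size_factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(orthogroup = rownames(vst$values), vst$values,
                       check.names = FALSE),
            "results/vst_values.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/size_factors.tsv and results/vst_values.tsv\n")
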