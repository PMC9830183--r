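# stage seeds derive from the global seed via a stable name hash, so adding
# a stage never shifts another stage's random stream
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h) %% .Machine$integer.max)
}

#' Pipeline configuration
#'
#' Either a simulation config (synthetic run) or paths to counts, metadata
#' and orthogroups files (user data), plus per-stage configurations.
#'
#' @param sim a [sim_config()] for synthetic runs, or `NULL`.
#' @param counts_paths named list of per-species counts TSVs (user data).
#' @param metadata_path,orthogroups_path input paths (user data).
#' @param policy an [ortho_filter_policy()].
#' @param svm an [svm_config()].
#' @param network a [network_config()].
#' @param de_alpha FDR threshold for differential expression.
#' @param stages character vector of stages to run, in dependency order.
#' @param resample if `TRUE`, run the network resampling null.
#' @param outdir output directory (`NULL` = keep results in memory only).
#' @param seed global seed propagated per stage.
#' @export
pipeline_config <- function(sim = NULL, counts_paths = NULL,
                            metadata_path = NULL, orthogroups_path = NULL,
                            policy = ortho_filter_policy(),
                            svm = svm_config(),
                            network = network_config(),
                            de_alpha = 0.05,
                            stages = c("simulate", "preprocess", "pca",
                                       "svm", "network", "de", "integrate"),
                            resample = FALSE,
                            outdir = NULL, seed = 1L) {
  if (is.null(sim)) stages <- setdiff(stages, "simulate")
  if (is.null(sim) &&
      (is.null(counts_paths) || is.null(metadata_path) ||
         is.null(orthogroups_path)))
    stop("either a simulation config or input paths are required")
  structure(list(sim = sim, counts_paths = counts_paths,
                 metadata_path = metadata_path,
                 orthogroups_path = orthogroups_path, policy = policy,
                 svm = svm, network = network, de_alpha = de_alpha,
                 stages = stages, resample = resample, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stage_tsv <- function(outdir, name, df) {
  if (is.null(outdir)) return(invisible(NULL))
  p <- file.path(outdir, paste0(name, ".tsv"))
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order (simulate, preprocess, pca, svm,
#' network, de, integrate), writes stage outputs and a JSON manifest with
#' md5 checksums when an output directory is set, and returns all stage
#' results. Reruns with an identical config reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list: `dataset`, `truth`, `vst`, `scaled`,
#'   `pca`, `svm`, `network`, `de`, `toolkit`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  res <- list()
  files <- character(0)
  stages_done <- character(0)
  for (stage in config$stages) {
    seed <- stage_seed(config$seed, stage)
    if (stage == "simulate") {
      sim_cfg <- config$sim
      sim_cfg$seed <- seed
      sim <- simulate_dataset(sim_cfg)
      res$dataset <- sim$dataset; res$truth <- sim$truth
    } else if (stage == "preprocess") {
      if (is.null(res$dataset)) {
        counts <- lapply(config$counts_paths, read_counts)
        meta <- read_metadata(config$metadata_path)
        og <- read_orthogroups(config$orthogroups_path, config$policy)
        res$dataset <- assemble_ortho_matrix(counts, og, meta, config$policy)
      }
      res$vst <- variance_stabilize(res$dataset, species_aware = TRUE)
      res$scaled <- center_scale(res$vst, scope = "per_species")
      files["counts"] <- write_stage_tsv(outdir, "counts",
        data.frame(orthogroup = rownames(res$dataset$counts),
                   res$dataset$counts, check.names = FALSE)) %||% ""
    } else if (stage == "pca") {
      res$pca <- run_pca(res$vst)
      res$pca_screen <- trait_correlation_screen(
        res$pca, res$dataset$samples[, c("clade", "species", "phenotype")])
      res$pca_control <- randomized_phenotype_control(res$pca, seed = seed)
      files["pca_screen"] <- write_stage_tsv(outdir, "pca_screen",
                                             res$pca_screen) %||% ""
    } else if (stage == "svm") {
      svm_cfg <- config$svm
      svm_cfg$seed <- seed
      res$svm <- run_svm_rfe(res$scaled, svm_cfg)
      files["svm_predictors"] <- write_stage_tsv(outdir, "svm_predictors",
        data.frame(gene = res$svm$intersection$common_all)) %||% ""
    } else if (stage == "network") {
      net_cfg <- config$network
      net_cfg$seed <- seed
      res$network <- consensus_network(res$vst, net_cfg)
      if (config$resample && length(res$network$trait_genes) > 0)
        res$network_resampling <- resampling_null(res$vst, net_cfg,
                                                  res$network$trait_genes)
      files["network_modules"] <- write_stage_tsv(outdir, "network_modules",
        data.frame(gene = res$network$genes,
                   module = res$network$module_labels)) %||% ""
      files["network_trait_genes"] <- write_stage_tsv(
        outdir, "network_trait_genes",
        data.frame(gene = res$network$trait_genes)) %||% ""
    } else if (stage == "de") {
      res$de <- run_de(res$dataset, alpha = config$de_alpha, seed = seed)
      files["de_overlap"] <- write_stage_tsv(outdir, "de_overlap",
        data.frame(gene = res$de$overlap$common)) %||% ""
    } else if (stage == "integrate") {
      res$toolkit <- build_toolkit(res$svm$intersection$common_all,
                                   res$network$trait_genes,
                                   res$de$overlap$common,
                                   truth = res$truth)
      files["toolkit"] <- write_stage_tsv(outdir, "toolkit",
        data.frame(gene = res$toolkit$toolkit)) %||% ""
    } else stop("unknown stage: ", stage)
    stages_done <- c(stages_done, stage)
  }
  manifest <- list(stages = stages_done, seed = config$seed)
  if (!is.null(outdir)) {
    files <- files[nzchar(files)]
    manifest$checksums <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  res$manifest <- manifest
  structure(res, class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
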