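#' Simulation configuration for multi-species synthetic counts
#'
#' Describes a six-species, two-clade study design with negative-binomial
#' orthogroup counts, a dominant species/clade expression signal, a small set
#' of "toolkit" genes with a consistent cross-species phenotype effect,
#' clade-restricted effect genes, and latent-factor co-expression modules a
#' subset of which tracks phenotype.
#'
#' The count model for gene \eqn{g} in sample \eqn{j} of species \eqn{s} is
#' \deqn{y_{gj} \sim NB(\mu_{gj}, \alpha_g), \quad
#'   \mu_{gj} = L_j \exp(b_g + c_{g,clade(s)} + e_{gs} + l_g f_j + \delta_{gj})}
#' with library-size multiplier \eqn{L_j}, gene baseline \eqn{b_g}, clade and
#' species shifts, module loading \eqn{l_g} times a per-sample latent factor
#' \eqn{f_j}, and a phenotype effect \eqn{\delta} applied to toolkit genes in
#' every species (consistent sign) and to clade-specific genes only within
#' their clade. Variance is \eqn{\mu + \alpha\mu^2}.
#'
#' @param n_species number of species (split across two clades by default).
#' @param clade_of_species named character vector mapping species to clade.
#' @param n_samples_per_phenotype integer length-2 vector
#'   `c(reproductive, non_reproductive)` used for every species, or a named
#'   list of such vectors per species. Each count must lie in `[3, 12]`.
#' @param n_genes total orthogroups simulated.
#' @param n_toolkit_genes genes with a consistent cross-species phenotype
#'   effect.
#' @param toolkit_lfc nominal phenotype effect size for toolkit (and
#'   clade-specific) genes, in log2 units; the reproductive vs
#'   non-reproductive mean ratio is `2^lfc` (sign drawn per gene, fixed
#'   across species).
#' @param lfc_species_cv coefficient of variation of the per-species
#'   realized effect magnitude around the nominal `toolkit_lfc`
#'   (`lfc_gs = sign_g * toolkit_lfc * max(N(1, cv), 0.25)`); conserved
#'   effects in species separated by ~200 My differ in magnitude, not in
#'   direction. Scales with the nominal effect, so a zero effect stays
#'   exactly zero. Realized values are recorded in the truth object.
#' @param n_clade_specific_genes per clade, genes whose phenotype effect is
#'   restricted to that clade.
#' @param n_modules number of latent co-expression modules.
#' @param module_size_range length-2 integer range of module sizes.
#' @param n_trait_modules modules whose latent factor mean is shifted by
#'   phenotype.
#' @param trait_module_shift shift of the factor mean in reproductive samples
#'   (factor sd is 1).
#' @param species_effect_sd,clade_effect_sd,base_mean_log_sd standard
#'   deviations of the gene-wise species shift, clade shift and baseline, in
#'   natural-log units.
#' @param base_mean_log mean of the gene baseline (natural log of expected
#'   counts at library size 1).
#' @param dispersion_shape length-2 `c(meanlog, sdlog)` of the log-normal
#'   gene-wise NB dispersion; `c(-Inf, 0)` gives Poisson counts.
#' @param library_size_range length-2 positive range; per-sample multipliers
#'   are drawn log-uniformly within it.
#' @param allow_role_overlap if `FALSE` (default) toolkit, clade-specific and
#'   module gene roles are disjoint.
#' @param seed integer seed; identical configs give identical datasets.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_species = 6,
                       clade_of_species = NULL,
                       n_samples_per_phenotype = c(8, 8),
                       n_genes = 1500,
                       n_toolkit_genes = 40,
                       toolkit_lfc = 1.0,
                       lfc_species_cv = 1 / 3,
                       n_clade_specific_genes = 30,
                       n_modules = 8,
                       module_size_range = c(20, 40),
                       n_trait_modules = 2,
                       trait_module_shift = 0.8,
                       species_effect_sd = 0.9,
                       clade_effect_sd = 0.4,
                       base_mean_log = log(150),
                       base_mean_log_sd = 1.2,
                       dispersion_shape = c(log(0.2), 0.7),
                       library_size_range = c(0.5, 2),
                       allow_role_overlap = FALSE,
                       seed = 1L) {
  if (is.null(clade_of_species)) {
    sp <- sprintf("sp%02d", seq_len(n_species))
    clade_of_species <- setNames(
      rep(c("cladeA", "cladeB"), length.out = n_species)[
        order(rep(c(1, 2), length.out = n_species))],
      sp)
    # contiguous halves: first ceiling(n/2) species cladeA, rest cladeB
    clade_of_species <- setNames(
      ifelse(seq_len(n_species) <= ceiling(n_species / 2), "cladeA", "cladeB"),
      sp)
  }
  species <- names(clade_of_species)
  stopifnot(length(species) == n_species)
  if (!is.list(n_samples_per_phenotype)) {
    n_samples_per_phenotype <- setNames(
      rep(list(as.integer(n_samples_per_phenotype)), n_species), species)
  }
  ns <- unlist(n_samples_per_phenotype)
  if (any(ns < 3) || any(ns > 12))
    stop("samples per phenotype must lie in [3, 12]")
  sds <- c(species_effect_sd, clade_effect_sd, base_mean_log_sd,
           trait_module_shift)
  if (any(sds < 0)) stop("sd and shift parameters must be >= 0")
  if (any(library_size_range <= 0)) stop("library sizes must be positive")
  n_role <- n_toolkit_genes +
    n_clade_specific_genes * length(unique(clade_of_species)) +
    n_modules * module_size_range[2]
  if (!allow_role_overlap && n_role > n_genes)
    stop("gene role assignments exceed n_genes; reduce roles or allow overlap")
  if (n_trait_modules > n_modules)
    stop("n_trait_modules cannot exceed n_modules")
  structure(list(
    n_species = n_species, clade_of_species = clade_of_species,
    n_samples_per_phenotype = n_samples_per_phenotype,
    n_genes = n_genes, n_toolkit_genes = n_toolkit_genes,
    toolkit_lfc = toolkit_lfc, lfc_species_cv = lfc_species_cv,
    n_clade_specific_genes = n_clade_specific_genes,
    n_modules = n_modules, module_size_range = module_size_range,
    n_trait_modules = n_trait_modules,
    trait_module_shift = trait_module_shift,
    species_effect_sd = species_effect_sd, clade_effect_sd = clade_effect_sd,
    base_mean_log = base_mean_log, base_mean_log_sd = base_mean_log_sd,
    dispersion_shape = dispersion_shape,
    library_size_range = library_size_range,
    allow_role_overlap = allow_role_overlap,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a multi-species orthogroup expression dataset with planted truth
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an `ortho_dataset`: integer counts matrix,
#'   sample table, provenance) and `truth` (a `synthetic_truth`: planted
#'   toolkit/clade-specific gene ids, module membership, trait modules,
#'   realized per-species log2 fold changes, seed).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  species <- names(config$clade_of_species)
  clades <- config$clade_of_species
  G <- config$n_genes
  genes <- sprintf("OG%07d", seq_len(G))

  # sample table
  samp <- do.call(rbind, lapply(species, function(s) {
    n <- config$n_samples_per_phenotype[[s]]
    data.frame(
      species = s, clade = unname(clades[s]),
      phenotype = rep(c("reproductive", "non_reproductive"), n),
      stringsAsFactors = FALSE)
  }))
  samp$sample_id <- sprintf("%s_%s_%02d", samp$species,
                            ifelse(samp$phenotype == "reproductive", "R", "N"),
                            stats::ave(seq_len(nrow(samp)),
                                       paste(samp$species, samp$phenotype),
                                       FUN = seq_along))
  samp <- samp[, c("sample_id", "species", "clade", "phenotype")]
  n_samp <- nrow(samp)

  # role assignment (disjoint unless overlap allowed)
  pool <- seq_len(G)
  take <- function(n) {
    idx <- pool[seq_len(n)]
    if (!config$allow_role_overlap) pool <<- setdiff(pool, idx)
    idx
  }
  toolkit_idx <- take(config$n_toolkit_genes)
  clade_levels <- unique(unname(clades))
  clade_idx <- setNames(lapply(clade_levels, function(cl)
    take(config$n_clade_specific_genes)), clade_levels)
  size_pool <- seq(config$module_size_range[1], config$module_size_range[2])
  module_sizes <- if (config$n_modules > 0)
    size_pool[sample.int(length(size_pool), config$n_modules,
                         replace = TRUE)] else integer(0)
  module_membership <- setNames(integer(G), genes)
  module_idx <- list()
  for (m in seq_along(module_sizes)) {
    idx <- take(module_sizes[m])
    module_idx[[m]] <- idx
    module_membership[idx] <- m
  }
  trait_modules <- seq_len(config$n_trait_modules)

  # gene-level parameters
  base <- rnorm(G, config$base_mean_log, config$base_mean_log_sd)
  alpha <- if (is.finite(config$dispersion_shape[1]))
    stats::rlnorm(G, config$dispersion_shape[1], config$dispersion_shape[2])
  else rep(0, G)
  sp_eff <- matrix(rnorm(G * length(species), 0, config$species_effect_sd),
                   G, length(species), dimnames = list(genes, species))
  cl_eff <- matrix(rnorm(G * length(clade_levels), 0, config$clade_effect_sd),
                   G, length(clade_levels), dimnames = list(genes, clade_levels))
  toolkit_sign <- sample(c(-1, 1), config$n_toolkit_genes, replace = TRUE)
  clade_sign <- lapply(clade_idx, function(idx)
    sample(c(-1, 1), length(idx), replace = TRUE))
  loading <- runif(G, 0.5, 1) * sample(c(-1, 1), G, replace = TRUE)

  # per-species realized effect magnitudes: sign-consistent, scaled by the
  # nominal lfc so a null effect stays exactly null
  jitter <- function(n) pmax(rnorm(n, 1, config$lfc_species_cv), 0.25)
  realized <- matrix(0, G, length(species), dimnames = list(genes, species))
  for (s in species) {
    realized[toolkit_idx, s] <-
      toolkit_sign * config$toolkit_lfc *
      jitter(config$n_toolkit_genes)
  }
  for (cl in clade_levels) {
    sp_in <- species[clades[species] == cl]
    for (s in sp_in) {
      realized[clade_idx[[cl]], s] <-
        clade_sign[[cl]] * config$toolkit_lfc *
        jitter(length(clade_idx[[cl]]))
    }
  }

  # per-sample quantities
  libsize <- exp(runif(n_samp, log(config$library_size_range[1]),
                       log(config$library_size_range[2])))
  pheno01 <- as.integer(samp$phenotype == "reproductive")
  factors <- matrix(0, n_samp, max(config$n_modules, 1))
  for (m in seq_along(module_sizes)) {
    shift <- if (m %in% trait_modules) config$trait_module_shift else 0
    factors[, m] <- rnorm(n_samp, shift * pheno01, 1)
  }

  # assemble log-mean and draw counts
  log_mu <- matrix(base, G, n_samp)
  log_mu <- log_mu + cl_eff[, samp$clade] + sp_eff[, samp$species]
  for (m in seq_along(module_sizes)) {
    idx <- module_idx[[m]]
    log_mu[idx, ] <- log_mu[idx, ] + outer(loading[idx], factors[, m])
  }
  log_mu <- log_mu + log(2) * realized[, samp$species] *
    matrix(pheno01, G, n_samp, byrow = TRUE)
  mu <- sweep(exp(log_mu), 2, libsize, "*")
  counts <- matrix(0L, G, n_samp, dimnames = list(genes, samp$sample_id))
  for (j in seq_len(n_samp)) {
    counts[, j] <- ifelse(alpha < 1e-12,
                          rpois(G, mu[, j]),
                          rnbinom(G, mu = mu[, j], size = 1 / pmax(alpha, 1e-12)))
  }

  dataset <- ortho_dataset(counts, samp,
                           provenance = list(source = "simulate_dataset",
                                             seed = config$seed))
  truth <- structure(list(
    toolkit_gene_ids = genes[toolkit_idx],
    clade_specific_gene_ids = lapply(clade_idx, function(i) genes[i]),
    module_membership = module_membership,
    trait_modules = trait_modules,
    realized_lfc = realized,
    library_sizes = setNames(libsize, samp$sample_id),
    seed = config$seed), class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Score recovery of planted structure
#'
#' @param predicted character vector of predicted gene ids (or, for
#'   `role = "module"`, a named integer vector of module labels with 0 =
#'   unassigned).
#' @param truth a `synthetic_truth`.
#' @param role one of `"toolkit"`, `"clade"`, `"module"`.
#' @param clade for `role = "clade"`, which clade's planted set to score
#'   against (default: union over clades).
#' @return list with `precision`, `recall`, `f1` and, for the module role,
#'   `ari` (adjusted Rand index over genes assigned in truth).
#' @export
score_recovery <- function(predicted, truth, role = c("toolkit", "clade", "module"),
                           clade = NULL) {
  role <- match.arg(role)
  if (role == "module") {
    stopifnot(!is.null(names(predicted)))
    assigned <- names(truth$module_membership)[truth$module_membership > 0]
    assigned <- intersect(assigned, names(predicted))
    ari <- mclust::adjustedRandIndex(truth$module_membership[assigned],
                                     predicted[assigned])
    pred_set <- names(predicted)[predicted > 0]
    truth_set <- assigned
  } else {
    truth_set <- if (role == "toolkit") truth$toolkit_gene_ids
    else if (is.null(clade)) unique(unlist(truth$clade_specific_gene_ids))
    else truth$clade_specific_gene_ids[[clade]]
    pred_set <- unique(as.character(predicted))
    ari <- NULL
  }
  tp <- length(intersect(pred_set, truth_set))
  precision <- if (length(pred_set) == 0) 0 else tp / length(pred_set)
  recall <- if (length(truth_set) == 0) 0 else tp / length(truth_set)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  out <- list(precision = precision, recall = recall, f1 = f1)
  if (!is.null(ari)) out$ari <- ari
  out
}

#' Write a simulated dataset to the on-disk formats the pipeline consumes
#'
#' Emits per-species counts TSVs (species-local gene ids), a sample metadata
#' TSV, an OrthoFinder-style `Orthogroups.tsv` and a truth JSON.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of file paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  species <- unique(ds$samples$species)
  genes <- rownames(ds$counts)
  paths <- list()
  og_tab <- data.frame(Orthogroup = genes, stringsAsFactors = FALSE)
  for (s in species) {
    cols <- ds$samples$sample_id[ds$samples$species == s]
    local_ids <- paste0(s, "_", tolower(genes))
    m <- ds$counts[, cols, drop = FALSE]
    rownames(m) <- local_ids
    p <- file.path(dir, paste0("counts_", s, ".tsv"))
    write.table(data.frame(gene_id = local_ids, m, check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    og_tab[[s]] <- local_ids
    paths[[paste0("counts_", s)]] <- p
  }
  p_meta <- file.path(dir, "metadata.tsv")
  write.table(ds$samples, p_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  p_og <- file.path(dir, "Orthogroups.tsv")
  write.table(og_tab, p_og, sep = "\t", quote = FALSE, row.names = FALSE)
  p_truth <- file.path(dir, "truth.json")
  tr <- sim$truth
  jsonlite::write_json(list(
    toolkit_gene_ids = tr$toolkit_gene_ids,
    clade_specific_gene_ids = tr$clade_specific_gene_ids,
    module_membership = as.list(tr$module_membership[tr$module_membership > 0]),
    trait_modules = tr$trait_modules,
    seed = tr$seed), p_truth, auto_unbox = TRUE)
  paths$metadata <- p_meta; paths$orthogroups <- p_og; paths$truth <- p_truth
  invisible(paths)
}
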