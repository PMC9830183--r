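#' Network configuration for consensus weighted co-expression analysis
#'
#' @param beta soft-thresholding power; `NULL` selects the smallest power in
#'   1..20 whose scale-free fit reaches `scale_free_r2` (median across
#'   species), falling back to 6.
#' @param network_sign `"unsigned"` (|cor|^beta) or `"signed"`
#'   (((1+cor)/2)^beta).
#' @param consensus_quantile quantile across species used as the consensus
#'   edge weight; 0 (default) is the component-wise minimum.
#' @param calibrate scale per-species TOMs so their 95th percentiles match
#'   the first species' before taking the consensus quantile.
#' @param min_module_sizes ordered decreasing minimum module sizes of the
#'   relaxation sweep (default 30, 20, 10).
#' @param cut_height_fraction static tree-cut height as a fraction of the
#'   maximum merge height (default 0.995).
#' @param resampling_k label-shuffle resamples for the network null
#'   (default 100; the full-scale convention is 1000).
#' @param alpha significance level for trait association (default 0.05).
#' @param scale_free_r2 target fit for automatic beta selection.
#' @param seed integer seed.
#' @export
network_config <- function(beta = NULL,
                           network_sign = c("unsigned", "signed"),
                           consensus_quantile = 0,
                           calibrate = TRUE,
                           min_module_sizes = c(30, 20, 10),
                           cut_height_fraction = 0.995,
                           resampling_k = 100,
                           alpha = 0.05,
                           scale_free_r2 = 0.8,
                           seed = 1L) {
  stopifnot(is.null(beta) || beta >= 1,
            consensus_quantile >= 0, consensus_quantile <= 1,
            all(diff(min_module_sizes) < 0))
  structure(list(beta = beta, network_sign = match.arg(network_sign),
                 consensus_quantile = consensus_quantile,
                 calibrate = calibrate,
                 min_module_sizes = min_module_sizes,
                 cut_height_fraction = cut_height_fraction,
                 resampling_k = resampling_k, alpha = alpha,
                 scale_free_r2 = scale_free_r2, seed = as.integer(seed)),
            class = "network_config")
}

#' Soft-thresholded co-expression adjacency
#'
#' Unsigned: \eqn{a_{ij} = |cor(x_i, x_j)|^\beta}; signed:
#' \eqn{a_{ij} = ((1 + cor)/2)^\beta}. Genes without variance are removed.
#'
#' @param expr genes x samples matrix for one species (>= 4 samples).
#' @param beta soft power.
#' @param sign `"unsigned"` or `"signed"`.
#' @return symmetric adjacency with unit diagonal, entries in \[0, 1\].
#' @export
adjacency <- function(expr, beta = 6, sign = c("unsigned", "signed")) {
  sign <- match.arg(sign)
  if (ncol(expr) < 4) stop("need at least 4 samples for adjacency")
  v <- apply(expr, 1, var)
  keep <- is.finite(v) & v > 0
  expr <- expr[keep, , drop = FALSE]
  r <- cor(t(expr))
  a <- if (sign == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}, \quad k_i = \sum_{u \ne i} a_{iu}}
#' with unit diagonal.
#'
#' @param a adjacency matrix from [adjacency()].
#' @return symmetric TOM, entries in \[0, 1\].
#' @export
tom <- function(a) {
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a   # sum_u a_iu a_uj counts u = i,j with a_ii = 0
  den <- outer(k, k, pmin) + 1 - a
  t <- num / den
  diag(t) <- 1
  t
}

#' Quantile consensus of per-species TOMs
#'
#' Optionally calibrates each species' TOM so its 95th percentile matches
#' the first species' (preventing one dataset's scale from dominating the
#' minimum), then takes the `quantile` across species entry-wise; quantile
#' 0 is the component-wise minimum.
#'
#' @param toms named list of TOMs on the identical gene set and order.
#' @param quantile consensus quantile in \[0, 1\].
#' @param calibrate logical.
#' @export
consensus_tom <- function(toms, quantile = 0, calibrate = TRUE) {
  g <- rownames(toms[[1]])
  for (t in toms) {
    if (!identical(dim(t), dim(toms[[1]])) ||
        !identical(rownames(t), g))
      stop("per-species TOMs must share gene set and order")
  }
  if (calibrate && length(toms) > 1) {
    ref <- stats::quantile(toms[[1]][upper.tri(toms[[1]])], 0.95)
    toms <- lapply(toms, function(t) {
      q <- stats::quantile(t[upper.tri(t)], 0.95)
      if (q > 0) pmin(t * (ref / q), 1) else t
    })
  }
  arr <- simplify2array(toms)
  cons <- if (quantile == 0) {
    out <- toms[[1]]
    for (i in seq_along(toms)[-1]) out <- pmin(out, toms[[i]])
    out
  } else {
    apply(arr, c(1, 2), stats::quantile, probs = quantile, names = FALSE)
  }
  diag(cons) <- 1
  dimnames(cons) <- dimnames(toms[[1]])
  cons
}

#' Detect modules by hierarchical clustering of a TOM
#'
#' Average-linkage clustering of `1 - TOM`, cut statically at
#' `cut_height_fraction` times the maximum merge height; clusters smaller
#' than `min_size` are labeled 0 (unassigned). Labels are ordered by
#' decreasing size.
#'
#' @param cons a TOM (consensus or single-species).
#' @param min_size minimum module size.
#' @param cut_height_fraction static cut fraction.
#' @return named integer vector of module labels (0 = unassigned), with the
#'   dendrogram in `attr(, "tree")`.
#' @export
detect_modules <- function(cons, min_size = 30, cut_height_fraction = 0.995) {
  d <- stats::as.dist(1 - cons)
  tree <- hclust(d, method = "average")
  h <- cut_height_fraction * max(tree$height)
  raw <- cutree(tree, h = h)
  tab <- sort(table(raw), decreasing = TRUE)
  keep <- names(tab)[tab >= min_size]
  labels <- setNames(integer(length(raw)), names(raw))
  for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  if (all(labels == 0)) warning("all genes unassigned at min_size ", min_size)
  attr(labels, "tree") <- tree
  labels
}

#' Module eigengene
#'
#' First principal component of the module's standardized expression,
#' sign-oriented so the mean gene-eigengene correlation is non-negative.
#'
#' @param expr genes x samples matrix for one species.
#' @param module_genes character gene ids (>= 2 with variance).
#' @return numeric sample-length vector with unit variance.
#' @export
eigengene <- function(expr, module_genes) {
  m <- expr[intersect(module_genes, rownames(expr)), , drop = FALSE]
  v <- apply(m, 1, var)
  m <- m[v > 0, , drop = FALSE]
  if (nrow(m) < 2) stop("module needs >= 2 genes with variance")
  z <- t(scale(t(m)))
  sv <- svd(z)
  e <- sv$v[, 1]
  if (mean(cor(t(m), e)) < 0) e <- -e
  e / sd(e)
}

#' Module membership (kME)
#'
#' @param expr genes x samples matrix.
#' @param eg eigengene vector for the module.
#' @return per-gene Pearson correlation with the eigengene.
#' @export
kme <- function(expr, eg) {
  drop(cor(t(expr), eg))
}

# Stouffer combination of per-species correlations:
# z_s = atanh(r_s) sqrt(n_s - 3), w_s = sqrt(n_s),
# Z = sum(w z) / sqrt(sum(w^2)); two-sided normal p.
stouffer_meta <- function(r, n) {
  ok <- is.finite(r) & n > 3
  if (!any(ok)) return(c(z = NA_real_, p = NA_real_))
  r <- pmin(pmax(r[ok], -0.999999), 0.999999)
  z <- atanh(r) * sqrt(n[ok] - 3)
  w <- sqrt(n[ok])
  Z <- sum(w * z) / sqrt(sum(w^2))
  c(z = Z, p = 2 * pnorm(-abs(Z)))
}

#' Meta-analytic trait association of entities measured per species
#'
#' Pearson correlation with the 0/1 phenotype within each species, combined
#' by weighted Stouffer's method (weights sqrt(n)); two-sided normal p,
#' Benjamini-Hochberg adjusted across entities. Species with a constant
#' phenotype are excluded with a warning.
#'
#' @param values_by_species named list (per species) of entity x sample
#'   matrices (or sample vectors for a single entity), identical entity
#'   sets.
#' @param phenotype_by_species named list of 0/1 vectors per species.
#' @return data.frame with per-species r columns, `z`, `p`, `p_adj`.
#' @export
trait_association <- function(values_by_species, phenotype_by_species) {
  species <- names(values_by_species)
  rs <- list(); ns <- c()
  for (s in species) {
    y <- phenotype_by_species[[s]]
    if (sd(y) == 0) {
      warning("species ", s, " has constant phenotype; excluded from meta")
      next
    }
    m <- values_by_species[[s]]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    rs[[s]] <- drop(cor(t(m), y))
    ns[s] <- length(y)
  }
  rmat <- do.call(cbind, rs)
  if (is.null(dim(rmat))) rmat <- matrix(rmat, nrow = 1,
                                         dimnames = list(NULL, names(rs)))
  meta <- t(apply(rmat, 1, function(r) stouffer_meta(r, ns)))
  out <- data.frame(rmat, z = meta[, "z"], p = meta[, "p"],
                    check.names = FALSE)
  m0 <- values_by_species[[1]]
  rownames(out) <- if (!is.null(dim(m0))) rownames(m0) else NULL
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Permutation Z for module preservation
#'
#' Statistic: mean intramodular consensus |kME| (mean across species of each
#' member gene's absolute correlation with the module eigengene; the
#' absolute value makes the statistic meaningful for unsigned modules whose
#' members split between positive and negative loadings). The null permutes
#' which genes carry the module label (same size); Z = (obs - mean_null) /
#' sd_null.
#'
#' @param expr_by_species named list of genes x samples matrices.
#' @param module_genes character gene ids (>= 2).
#' @param n_permutations permutations (default 50).
#' @param seed integer seed.
#' @export
preservation_z <- function(expr_by_species, module_genes,
                           n_permutations = 50, seed = 1L) {
  if (length(module_genes) < 2) stop("module needs >= 2 genes")
  set.seed(seed)
  all_genes <- rownames(expr_by_species[[1]])
  stat <- function(genes) {
    kk <- vapply(expr_by_species, function(e) {
      eg <- eigengene(e, genes)
      mean(abs(kme(e[genes, , drop = FALSE], eg)))
    }, 1.0)
    mean(kk)
  }
  obs <- stat(module_genes)
  null <- vapply(seq_len(n_permutations), function(b)
    stat(sample(all_genes, length(module_genes))), 1.0)
  s <- sd(null)
  if (s < 1e-12) return(NA_real_)
  (obs - mean(null)) / s
}

# cluster once, then apply the size filter per min_size; returns the list
# of assignments (same dendrogram, weaker filter at smaller sizes)
modules_by_size <- function(cons, sizes, cut_height_fraction) {
  base <- detect_modules(cons, min_size = min(sizes),
                         cut_height_fraction = cut_height_fraction)
  tree <- attr(base, "tree")
  raw <- cutree(tree, h = cut_height_fraction * max(tree$height))
  out <- lapply(sizes, function(ms) {
    tab <- sort(table(raw), decreasing = TRUE)
    keep <- names(tab)[tab >= ms]
    labels <- setNames(integer(length(raw)), names(raw))
    for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
    labels
  })
  names(out) <- as.character(sizes)
  attr(out, "tree") <- tree
  out
}

#' Build a consensus co-expression network and test trait association
#'
#' Per-species soft-thresholded adjacencies and TOMs on the shared
#' orthogroup set, a calibrated quantile consensus, module detection with a
#' relaxation sweep over minimum module sizes, eigengene/kME computation,
#' and meta-analytic association of modules and genes with the reproductive
#' phenotype. A gene counts as trait-associated when its own meta-p (BH) is
#' below alpha, it belongs to a module whose eigengene meta-p (BH) is below
#' alpha, and its kME meta-p (BH) in that module is below alpha.
#'
#' @param nm a `normalized_matrix` (VST values, not center-scaled) with a
#'   sample table.
#' @param config a [network_config()].
#' @return a `consensus_network_result`.
#' @export
consensus_network <- function(nm, config = network_config()) {
  samples <- nm$samples
  species <- unique(samples$species)
  expr_by_species <- lapply(species, function(s)
    nm$values[, samples$species == s, drop = FALSE])
  names(expr_by_species) <- species
  # complete-case across species; drop zero-variance genes in any species
  ok <- Reduce(`&`, lapply(expr_by_species, function(e)
    stats::complete.cases(e) & apply(e, 1, var, na.rm = TRUE) > 0))
  expr_by_species <- lapply(expr_by_species, function(e)
    e[ok, , drop = FALSE])
  genes <- rownames(expr_by_species[[1]])
  beta <- config$beta
  if (is.null(beta)) beta <- pick_soft_power(expr_by_species,
                                             config$network_sign,
                                             config$scale_free_r2)
  toms <- lapply(expr_by_species, function(e)
    tom(adjacency(e, beta, config$network_sign)))
  cons <- consensus_tom(toms, config$consensus_quantile, config$calibrate)
  mods <- modules_by_size(cons, config$min_module_sizes,
                          config$cut_height_fraction)
  labels <- mods[[as.character(min(config$min_module_sizes))]]
  module_ids <- sort(unique(labels[labels > 0]))
  pheno <- lapply(species, function(s)
    as.integer(samples$phenotype[samples$species == s] == "reproductive"))
  names(pheno) <- species

  # Per-species eigengenes, sign-aligned across species: within a species
  # the PC1 sign is arbitrary (modules mix positively and negatively
  # loaded genes), so each species' eigengene is flipped to make its kME
  # profile over the module agree with the first species'. Without this the
  # per-species trait correlations cancel in the meta-analysis.
  eigengenes <- setNames(lapply(module_ids, function(mid) {
    mg <- genes[labels == mid]
    egs <- lapply(expr_by_species, function(e) eigengene(e, mg))
    ref_kme <- kme(expr_by_species[[1]][mg, , drop = FALSE], egs[[1]])
    for (s in seq_along(egs)[-1]) {
      k_s <- kme(expr_by_species[[s]][mg, , drop = FALSE], egs[[s]])
      if (cor(ref_kme, k_s) < 0) egs[[s]] <- -egs[[s]]
    }
    egs
  }), sprintf("M%d", module_ids))

  module_trait <- if (length(module_ids)) {
    me_mat <- lapply(species, function(s)
      do.call(rbind, lapply(eigengenes, function(eg) eg[[s]])))
    names(me_mat) <- species
    mt <- trait_association(me_mat, pheno)
    rownames(mt) <- names(eigengenes)
    mt
  } else NULL

  gene_trait <- trait_association(expr_by_species, pheno)

  kme_by_species <- if (length(module_ids)) {
    setNames(lapply(species, function(s) {
      sapply(names(eigengenes), function(m)
        kme(expr_by_species[[s]], eigengenes[[m]][[s]]))
    }), species)
  } else setNames(vector("list", length(species)), species)

  # kME meta significance of each assigned gene in its own module
  kme_meta <- rep(NA_real_, length(genes))
  names(kme_meta) <- genes
  if (length(module_ids)) {
    assigned <- genes[labels > 0]
    ns <- vapply(pheno, length, 1L)
    for (g in assigned) {
      mname <- paste0("M", labels[g])
      r <- vapply(species, function(s) kme_by_species[[s]][g, mname], 1.0)
      kme_meta[g] <- stouffer_meta(r, ns)["p"]
    }
  }
  kme_meta_adj <- setNames(rep(NA_real_, length(genes)), genes)
  has <- !is.na(kme_meta)
  kme_meta_adj[has] <- bh_adjust(kme_meta[has])

  sig_modules <- if (!is.null(module_trait))
    rownames(module_trait)[module_trait$p_adj < config$alpha] else character(0)
  in_sig_module <- paste0("M", labels) %in% sig_modules & labels > 0
  trait_genes <- genes[!is.na(gene_trait$p_adj) &
                         gene_trait$p_adj < config$alpha &
                         in_sig_module &
                         !is.na(kme_meta_adj) & kme_meta_adj < config$alpha]

  pres <- if (length(module_ids)) {
    vapply(module_ids, function(mid)
      preservation_z(expr_by_species, genes[labels == mid],
                     seed = config$seed), 1.0)
  } else numeric(0)

  structure(list(
    genes = genes, beta = beta,
    per_species_tom = toms, consensus_tom = cons,
    modules_by_size = mods, module_labels = labels,
    eigengenes = eigengenes, kme = kme_by_species,
    kme_meta_p_adj = kme_meta_adj,
    module_trait = module_trait, gene_trait = gene_trait,
    significant_modules = sig_modules, trait_genes = trait_genes,
    preservation_z = setNames(pres, sprintf("M%d", module_ids)),
    expr_by_species = expr_by_species, phenotype = pheno,
    config = config), class = "consensus_network_result")
}

#' Single-species co-expression network (orthology-independent path)
#'
#' Same construction as [consensus_network()] for one species: the
#' "consensus" of a single dataset is its own TOM.
#'
#' @param expr genes x samples matrix (zero-variance genes removed).
#' @param phenotype 0/1 vector.
#' @param config a [network_config()].
#' @return list with `tom`, `module_labels`, `modules_by_size`,
#'   `eigengenes`, `module_trait`, `gene_trait`, `trait_genes`.
#' @export
single_species_network <- function(expr, phenotype,
                                   config = network_config()) {
  v <- apply(expr, 1, var)
  expr <- expr[is.finite(v) & v > 0, , drop = FALSE]
  beta <- config$beta
  if (is.null(beta)) beta <- pick_soft_power(list(expr), config$network_sign,
                                             config$scale_free_r2)
  tm <- tom(adjacency(expr, beta, config$network_sign))
  mods <- modules_by_size(tm, config$min_module_sizes,
                          config$cut_height_fraction)
  labels <- mods[[as.character(min(config$min_module_sizes))]]
  genes <- rownames(expr)
  module_ids <- sort(unique(labels[labels > 0]))
  egs <- setNames(lapply(module_ids, function(mid)
    eigengene(expr, genes[labels == mid])), sprintf("M%d", module_ids))
  sp <- list(one = expr); ph <- list(one = phenotype)
  gene_trait <- trait_association(sp, ph)
  module_trait <- if (length(module_ids)) {
    mt <- trait_association(list(one = do.call(rbind, egs)), ph)
    rownames(mt) <- names(egs)
    mt
  } else NULL
  sig_modules <- if (!is.null(module_trait))
    rownames(module_trait)[module_trait$p_adj < config$alpha] else character(0)
  in_sig <- paste0("M", labels) %in% sig_modules & labels > 0
  trait_genes <- genes[!is.na(gene_trait$p_adj) &
                         gene_trait$p_adj < config$alpha & in_sig]
  list(tom = tm, module_labels = labels, modules_by_size = mods,
       eigengenes = egs, module_trait = module_trait,
       gene_trait = gene_trait, trait_genes = trait_genes, beta = beta)
}

#' Label-shuffle resampling null for the trait-associated gene set
#'
#' Shuffles phenotype labels within species, rebuilds the consensus network
#' and trait-associated gene set, and records the proportion of the
#' point-estimate set recovered in each resample. Two p-values are
#' reported: the two-tailed rule comparing each resample's deviation from
#' the 50% null expectation against the observed deviation, and a
#' conventional one-tailed exceedance `p = (1 + #(null >= obs)) / (k + 1)`.
#'
#' @param nm the `normalized_matrix` used for the point estimate.
#' @param config a [network_config()]; `resampling_k` sets k.
#' @param point_estimate character vector: the observed trait-associated
#'   gene set.
#' @return list with `proportions`, `p_two_tailed`, `p_exceedance`.
#' @export
resampling_null <- function(nm, config = network_config(),
                            point_estimate) {
  if (length(point_estimate) == 0) stop("empty point-estimate set")
  set.seed(config$seed)
  k <- config$resampling_k
  samples <- nm$samples
  props <- vapply(seq_len(k), function(b) {
    shuffled <- samples
    for (s in unique(samples$species)) {
      idx <- which(samples$species == s)
      shuffled$phenotype[idx] <- samples$phenotype[sample(idx)]
    }
    nm_b <- nm
    nm_b$samples <- shuffled
    cfg <- config
    cfg$resampling_k <- 0
    res_b <- consensus_network(nm_b, cfg)
    length(intersect(res_b$trait_genes, point_estimate)) /
      length(point_estimate)
  }, 1.0)
  obs <- 1  # the point estimate recovers itself in full
  p_two <- mean(abs(props - 0.5) >= abs(obs - 0.5))
  p_exc <- (1 + sum(props >= obs)) / (k + 1)
  list(proportions = props, p_two_tailed = p_two, p_exceedance = p_exc)
}

#' Pick the soft-thresholding power by scale-free fit
#'
#' Smallest beta in 1..20 whose median (across species) scale-free topology
#' fit R^2 reaches the target; falls back to 6.
#'
#' @param expr_by_species list of genes x samples matrices.
#' @param sign network sign.
#' @param target_r2 fit target (default 0.8).
#' @export
pick_soft_power <- function(expr_by_species, sign = "unsigned",
                            target_r2 = 0.8) {
  for (beta in 1:20) {
    r2 <- vapply(expr_by_species, function(e) {
      a <- adjacency(e, beta, sign)
      diag(a) <- 0
      k <- colSums(a)
      scale_free_r2(k)
    }, 1.0)
    if (median(r2, na.rm = TRUE) >= target_r2) return(beta)
  }
  6
}

# R^2 of log10 p(k) vs log10 k over 10 connectivity bins
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  summary(fit)$r.squared
}
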