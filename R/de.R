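#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `p.adjust(method = "BH")`; missing values are excluded
#' from the number of tests and returned as missing.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

# one-gene NB GLM: log link, offset, Cox-Reid adjusted ML dispersion.
# X: design matrix; returns c(beta_cov, se_cov, ...) for the last column.
fit_nb_gene <- function(y, X, offset) {
  if (all(y == 0)) return(c(beta = NA, se = NA, alpha = NA))
  irls <- function(alpha, beta) {
    for (it in 1:25) {
      eta <- drop(X %*% beta) + offset
      mu <- pmax(exp(eta), 1e-10)
      w <- mu / (1 + alpha * mu)
      z <- eta - offset + (y - mu) / mu
      XtW <- t(X * w)
      beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                           error = function(e) NULL)
      if (is.null(beta_new)) return(NULL)
      if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
      beta <- beta_new
    }
    drop(beta)
  }
  # init from log counts
  beta <- tryCatch(
    coef(stats::lm.fit(X, log(pmax(y, 0.5)) - offset)),
    error = function(e) rep(0, ncol(X)))
  beta[!is.finite(beta)] <- 0
  alpha <- 0.1
  alpha_prev <- Inf
  for (round in 1:8) {
    if (abs(log(alpha) - log(alpha_prev)) < 1e-6) break
    alpha_prev <- alpha
    b <- irls(alpha, beta)
    if (is.null(b)) return(c(beta = NA, se = NA, alpha = NA))
    beta <- b
    mu <- pmax(exp(drop(X %*% beta) + offset), 1e-10)
    # Cox-Reid adjusted profile likelihood in log alpha
    nll <- function(la) {
      a <- exp(la)
      w <- mu / (1 + a * mu)
      ll <- sum(stats::dnbinom(y, mu = mu, size = 1 / a, log = TRUE))
      cr <- 0.5 * determinant(t(X * w) %*% X, logarithm = TRUE)$modulus
      -(ll - cr)
    }
    opt <- tryCatch(optimize(nll, c(-15, 5)), error = function(e) NULL)
    if (is.null(opt)) break
    alpha <- max(exp(opt$minimum), 1e-8)
  }
  mu <- pmax(exp(drop(X %*% beta) + offset), 1e-10)
  w <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
  if (is.null(cov)) return(c(beta = NA, se = NA, alpha = NA))
  j <- ncol(X)
  c(beta = unname(beta[j]), se = sqrt(cov[j, j]), alpha = unname(alpha))
}

#' Per-gene negative-binomial Wald test
#'
#' For each gene, a NB log-link regression of counts on phenotype (with
#' optional additional covariates such as clade) and offset
#' `log(size_factor)`; gene-wise dispersion by Cox-Reid adjusted maximum
#' likelihood; two-sided Wald p on the phenotype coefficient, referred to a
#' t distribution with residual degrees of freedom (the normal reference is
#' anti-conservative at the 3-12 samples per group this design uses).
#' This is a deliberate re-implementation of the standard RNA-seq NB
#' testing framework without fold-change shrinkage, independent filtering
#' or outlier replacement; its operating characteristics are checked by
#' calibration, not by equality with any package.
#'
#' @param counts genes x samples integer matrix.
#' @param phenotype vector coercible to 0/1 (1 = reproductive), or a factor.
#' @param sf size factors (default computed from `counts`).
#' @param covariates optional data.frame of additional model terms (e.g.
#'   `data.frame(clade = ...)`).
#' @return data.frame with `gene`, `lfc` (log2 reproductive vs
#'   non-reproductive), `stat`, `p`, `p_adj`; all-zero genes get NA.
#' @export
nb_wald_test <- function(counts, phenotype, sf = NULL, covariates = NULL) {
  if (is.factor(phenotype) || is.character(phenotype))
    phenotype <- as.integer(as.character(phenotype) == "reproductive")
  if (length(unique(phenotype)) < 2) stop("both phenotypes required")
  if (min(table(phenotype)) < 3)
    stop("need >= 3 samples per phenotype")
  if (is.null(sf)) sf <- size_factors(counts)
  offset <- log(sf)
  X <- matrix(1, length(phenotype), 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  X <- cbind(X, phenotype = phenotype)
  res <- t(apply(counts, 1, function(y) {
    if (any(is.na(y))) return(c(beta = NA, se = NA, alpha = NA))
    fit_nb_gene(as.numeric(y), X, offset)
  }))
  stat <- res[, "beta"] / res[, "se"]
  # t reference with residual df: at this study's group sizes (3-12) the
  # normal reference is anti-conservative at the nominal level
  df <- length(phenotype) - ncol(X)
  p <- 2 * stats::pt(-abs(stat), df = df)
  out <- data.frame(gene = rownames(counts),
                    lfc = res[, "beta"] / log(2),
                    stat = stat, p = p,
                    dispersion = res[, "alpha"],
                    stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Permutation balancing of unequal group sizes
#'
#' Repeatedly subsamples the larger phenotype group down to the smaller
#' group's size, reruns the NB Wald test with BH correction, and retains
#' genes significant in at least `support_threshold` of the subsamples.
#' Equal groups pass through the single-run significant set with a note.
#'
#' @param counts genes x samples matrix.
#' @param phenotype 0/1 vector (or phenotype strings).
#' @param sf size factors for all samples.
#' @param n_permutations balanced subsamples (>= 20 when groups differ).
#' @param support_threshold fraction of subsamples a gene must be
#'   significant in (default 0.5).
#' @param alpha FDR threshold (default 0.05).
#' @param seed integer seed.
#' @return list with `significant` (robust set), `support` (per-gene
#'   fraction), `balanced` (whether subsampling happened).
#' @export
permutation_balance <- function(counts, phenotype, sf = NULL,
                                n_permutations = 25,
                                support_threshold = 0.5,
                                alpha = 0.05, seed = 1L) {
  if (is.factor(phenotype) || is.character(phenotype))
    phenotype <- as.integer(as.character(phenotype) == "reproductive")
  if (is.null(sf)) sf <- size_factors(counts)
  tab <- table(phenotype)
  if (length(unique(tab)) == 1) {
    de <- nb_wald_test(counts, phenotype, sf)
    sig <- de$gene[!is.na(de$p_adj) & de$p_adj < alpha]
    return(list(significant = sig,
                support = setNames(as.numeric(de$gene %in% sig), de$gene),
                balanced = FALSE))
  }
  stopifnot(n_permutations >= 20)
  set.seed(seed)
  n_small <- min(tab)
  larger <- names(tab)[which.max(tab)]
  hits <- setNames(numeric(nrow(counts)), rownames(counts))
  for (b in seq_len(n_permutations)) {
    keep_large <- sample(which(phenotype == as.integer(larger)), n_small)
    keep <- sort(c(which(phenotype != as.integer(larger)), keep_large))
    de <- nb_wald_test(counts[, keep, drop = FALSE], phenotype[keep],
                       sf[keep])
    sig <- de$gene[!is.na(de$p_adj) & de$p_adj < alpha]
    hits[sig] <- hits[sig] + 1
  }
  support <- hits / n_permutations
  list(significant = names(support)[support >= support_threshold],
       support = support, balanced = TRUE)
}

#' Cross-species overlap of significant gene sets
#'
#' @param sets named list of character vectors (per-species significant
#'   orthogroups).
#' @param min_species minimum number of species for the `common` set.
#' @return list with `membership` matrix, `counts_by_cardinality` (genes
#'   significant in exactly k species), `common`, `max_shared_species`.
#' @export
overlap_de <- function(sets, min_species = 2) {
  genes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  if (length(genes) == 0)
    return(list(membership = membership,
                counts_by_cardinality = rep(0L, length(sets)),
                common = character(0), max_shared_species = 0L))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(genes),
                         dimnames = list(genes, names(sets)))
  rownames(membership) <- genes
  k <- rowSums(membership)
  counts <- as.integer(table(factor(k, levels = seq_along(sets))))
  list(membership = membership, counts_by_cardinality = counts,
       common = genes[k >= min_species],
       max_shared_species = max(k))
}

#' Per-species differential expression with cross-species overlap
#'
#' Runs the NB Wald test between phenotypes in each species (permutation
#' balancing when group sizes are unequal), plus a joint clade-adjusted
#' model over all samples, and counts cross-species overlaps among
#' significant orthogroups.
#'
#' @param dataset an `ortho_dataset`.
#' @param alpha FDR threshold (default 0.05).
#' @param balance use permutation balancing for unequal group sizes.
#' @param n_permutations balanced subsamples (when balancing).
#' @param seed integer seed.
#' @return list with `per_species` (test tables), `significant` (sets),
#'   `overlap`, `joint_clade` (clade-adjusted joint test table).
#' @export
run_de <- function(dataset, alpha = 0.05, balance = TRUE,
                   n_permutations = 25, seed = 1L) {
  samples <- dataset$samples
  sf_all <- size_factors(dataset$counts)
  per_species <- list(); sig <- list()
  for (s in unique(samples$species)) {
    cols <- samples$species == s
    cnt <- dataset$counts[, cols, drop = FALSE]
    cnt <- cnt[stats::complete.cases(cnt), , drop = FALSE]
    ph <- samples$phenotype[cols]
    de <- nb_wald_test(cnt, ph, sf_all[cols])
    per_species[[s]] <- de
    tab <- table(ph)
    if (balance && length(unique(tab)) > 1) {
      pb <- permutation_balance(cnt, ph, sf_all[cols],
                                n_permutations = max(n_permutations, 20),
                                alpha = alpha, seed = seed)
      sig[[s]] <- pb$significant
      per_species[[s]]$support <- pb$support[per_species[[s]]$gene]
    } else {
      sig[[s]] <- de$gene[!is.na(de$p_adj) & de$p_adj < alpha]
    }
  }
  cc <- stats::complete.cases(dataset$counts)
  joint <- nb_wald_test(dataset$counts[cc, , drop = FALSE],
                        samples$phenotype, sf_all,
                        covariates = data.frame(clade = samples$clade))
  list(per_species = per_species, significant = sig,
       overlap = overlap_de(sig), joint_clade = joint, alpha = alpha)
}
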