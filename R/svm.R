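#' SVM configuration for leave-one-species-out recursive feature elimination
#'
#' Defaults follow the study design this package standardizes: radial
#' kernel, gamma grid 1e-7..1e-5 (decade points), cost grid 2^3..2^5,
#' 3-fold cross-validation for tuning, elimination of one gene per step to
#' a floor, and a 100-shuffle randomization test.
#'
#' @param kernel `"radial"` or `"linear"`.
#' @param gamma_grid positive reals (ignored for linear kernel).
#' @param cost_grid positive reals.
#' @param k_folds folds for tuning cross-validation (>= 2).
#' @param rfe_floor gene count at which elimination stops.
#' @param n_randomizations label shuffles for the randomization test.
#' @param seed integer seed (fold assignment and shuffles).
#' @export
svm_config <- function(kernel = c("radial", "linear"),
                       gamma_grid = c(1e-7, 1e-6, 1e-5),
                       cost_grid = c(8, 16, 32),
                       k_folds = 3,
                       rfe_floor = 100,
                       n_randomizations = 100,
                       seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(length(gamma_grid) > 0, length(cost_grid) > 0, k_folds >= 2,
            all(gamma_grid > 0), all(cost_grid > 0))
  structure(list(kernel = kernel, gamma_grid = sort(gamma_grid),
                 cost_grid = sort(cost_grid), k_folds = k_folds,
                 rfe_floor = rfe_floor,
                 n_randomizations = n_randomizations, seed = as.integer(seed)),
            class = "svm_config")
}

#' Leave-one-species-out split
#'
#' @param nm a center-scaled `normalized_matrix` (genes x samples) with a
#'   sample table, as produced by [center_scale()].
#' @param focal_species the species forming the test set.
#' @param lineage optional character vector of species to restrict the
#'   analysis to (e.g. the bees only); the focal species must be in it.
#' @return list with `x_train`, `y_train`, `x_test`, `y_test`; x matrices
#'   are samples x genes, labels are 1 = reproductive, 0 = non_reproductive.
#' @export
loso_split <- function(nm, focal_species, lineage = NULL) {
  samples <- nm$samples
  values <- nm$values
  if (!is.null(lineage)) {
    keep <- samples$species %in% lineage
    samples <- samples[keep, ]
    values <- values[, keep, drop = FALSE]
  }
  if (length(unique(samples$species)) < 2)
    stop("leave-one-species-out needs at least 2 species")
  if (!focal_species %in% samples$species)
    stop("unknown focal species: ", focal_species)
  y <- as.integer(samples$phenotype == "reproductive")
  test <- samples$species == focal_species
  if (length(unique(y[test])) < 2)
    stop("focal species lacks one phenotype class")
  keep_genes <- stats::complete.cases(values)
  values <- values[keep_genes, , drop = FALSE]
  list(x_train = t(values[, !test, drop = FALSE]),
       y_train = y[!test],
       x_test = t(values[, test, drop = FALSE]),
       y_test = y[test],
       focal_species = focal_species)
}

# squared Euclidean distance matrices (train x train, train x test)
sqdist <- function(a, b = a) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

# stratified k folds; redraws (bounded) until every training portion keeps
# both classes
make_folds <- function(y, k, max_retries = 20) {
  n <- length(y)
  for (r in seq_len(max_retries)) {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == 2, TRUE))
    if (ok) return(fold)
  }
  stop("could not build folds with both classes in every training portion")
}

# kernel matrix from squared distances (or linear gram)
kernel_from_d2 <- function(D2, gamma) exp(-gamma * D2)

# fit C-SVC on a precomputed kernel; y01 in {0,1}; returns coef (alpha*y,
# +1 = reproductive), rho.
# Under the dual equality constraint, (K, C) is exactly equivalent to
# ((K - c)/s, C s) with coefficients scaled back by 1/s; solving at unit
# kernel spread keeps the stopping tolerance meaningful even for tiny
# gammas, where the raw kernel is nearly constant.
fit_kernel_svm <- function(K, y01, cost) {
  y <- ifelse(y01 == 1, 1L, -1L)
  c0 <- mean(K)
  s <- max(K) - min(K)
  if (!is.finite(s) || s < 1e-12) s <- 1
  fit <- smo_csvc((K - c0) / s, y, cost * s)
  fit$coef <- fit$coef / s
  fit
}

predict_kernel_svm <- function(fit, Ktx) {
  f <- smo_decision(Ktx, fit$coef, fit$rho)
  as.integer(f > 0)
}

# grid-search CV over (gamma, cost); returns best params and cv error.
# Ties break toward smaller cost then smaller gamma (grids pre-sorted).
tune_kernel_svm <- function(D2_train, gram_train, y, config, fold) {
  best <- list(cv_error = Inf)
  gammas <- if (config$kernel == "radial") config$gamma_grid else NA
  for (g in gammas) {
    K <- if (config$kernel == "radial") kernel_from_d2(D2_train, g)
    else gram_train
    for (cost in config$cost_grid) {
      miss <- 0L
      for (f in sort(unique(fold))) {
        tr <- fold != f
        fit <- fit_kernel_svm(K[tr, tr, drop = FALSE], y[tr], cost)
        pred <- predict_kernel_svm(fit, K[tr, !tr, drop = FALSE])
        miss <- miss + sum(pred != y[!tr])
      }
      err <- miss / length(y)
      if (err < best$cv_error - 1e-12) {
        best <- list(gamma = g, cost = cost, cv_error = err)
      }
    }
  }
  best
}

#' Tune and fit an SVM on training data
#'
#' Exhaustive grid search over gamma and cost with seeded stratified k-fold
#' cross-validation; the CV error is the misclassification fraction pooled
#' over held-out folds. Ties break toward smaller cost, then smaller gamma.
#'
#' @param x samples x genes matrix (center-scaled).
#' @param y 0/1 labels (1 = reproductive).
#' @param config an [svm_config()].
#' @return a fitted classifier: list with `coef` (alpha_i y_i per training
#'   sample), `rho`, `gamma`, `cost`, `cv_error`, `x`, `y`.
#' @export
tune_and_fit <- function(x, y, config = svm_config()) {
  set.seed(config$seed)
  fold <- make_folds(y, config$k_folds)
  D2 <- if (config$kernel == "radial") sqdist(x) else NULL
  gram <- if (config$kernel == "linear") tcrossprod(x) else NULL
  tuned <- tune_kernel_svm(D2, gram, y, config, fold)
  K <- if (config$kernel == "radial") kernel_from_d2(D2, tuned$gamma) else gram
  fit <- fit_kernel_svm(K, y, tuned$cost)
  structure(list(coef = fit$coef, rho = fit$rho,
                 gamma = if (config$kernel == "radial") tuned$gamma else NA,
                 cost = tuned$cost, cv_error = tuned$cv_error,
                 kernel = config$kernel, x = x, y = y),
            class = "cm_svm")
}

#' Predict phenotype labels with a fitted classifier
#' @param object a `cm_svm` fit.
#' @param newdata samples x genes matrix on the fit's gene set.
#' @param ... unused.
#' @return integer 0/1 labels.
#' @export
predict.cm_svm <- function(object, newdata, ...) {
  Ktx <- if (object$kernel == "radial")
    kernel_from_d2(t(sqdist(newdata, object$x)), object$gamma)
  else tcrossprod(object$x, newdata)
  predict_kernel_svm(object, Ktx)
}

#' Per-gene SVM feature weights
#'
#' The matrix product of the model's (signed) support-vector coefficients
#' with the support vectors: \eqn{w_g = \sum_i \alpha_i y_i x_{ig}}. For a
#' linear kernel this is the exact primal weight vector; for the radial
#' kernel it is the same operator applied as a ranking heuristic.
#'
#' @param fit a `cm_svm` fit.
#' @return named numeric vector of weights, one per gene.
#' @export
feature_weights <- function(fit) {
  sv <- abs(fit$coef) > 1e-12
  if (!any(sv)) stop("degenerate fit: no support vectors")
  w <- drop(crossprod(fit$x[sv, , drop = FALSE], fit$coef[sv]))
  names(w) <- colnames(fit$x)
  w
}

#' Recursive feature elimination with a held-out focal species
#'
#' At each step the model is re-tuned over the full grid, the held-out
#' (focal species) test error recorded, and the gene with the smallest
#' |weight| removed (ties: lexicographically smallest id), until
#' `rfe_floor` genes remain. The best model is the trace entry with minimal
#' held-out test error (ties: smaller gene set), refit on its gene set.
#'
#' @param split a [loso_split()] result (or any list with `x_train`,
#'   `y_train`, `x_test`, `y_test`).
#' @param config an [svm_config()].
#' @return an `svm_rfe_result`: `trace` data.frame (`size`, `gamma`, `cost`,
#'   `cv_error`, `test_error`, `removed`), `best_model` (trace row index),
#'   `predictor_genes`, `predictor_weights`, `gene_ranks` (1 = most
#'   predictive), `final_fit`, `test_predictions`, `focal_species`.
#' @export
recursive_elimination <- function(split, config = svm_config()) {
  x_tr <- split$x_train; y_tr <- split$y_train
  x_te <- split$x_test; y_te <- split$y_test
  G <- ncol(x_tr)
  if (G <= config$rfe_floor) stop("rfe_floor must be below the gene count")
  set.seed(config$seed)
  fold <- make_folds(y_tr, config$k_folds)
  genes <- colnames(x_tr)
  active <- genes
  D2_tr <- sqdist(x_tr)
  D2_te <- sqdist(x_tr, x_te)
  removal_order <- character(0)
  trace <- vector("list", G - config$rfe_floor + 1)
  step <- 0
  repeat {
    step <- step + 1
    gram <- if (config$kernel == "linear")
      tcrossprod(x_tr[, active, drop = FALSE]) else NULL
    tuned <- tune_kernel_svm(D2_tr, gram, y_tr, config, fold)
    K <- if (config$kernel == "radial") kernel_from_d2(D2_tr, tuned$gamma)
    else gram
    fit <- fit_kernel_svm(K, y_tr, tuned$cost)
    Kte <- if (config$kernel == "radial") kernel_from_d2(D2_te, tuned$gamma)
    else tcrossprod(x_tr[, active, drop = FALSE],
                    x_te[, active, drop = FALSE])
    f_te <- smo_decision(Kte, fit$coef, fit$rho)
    pred <- as.integer(f_te > 0)
    test_error <- mean(pred != y_te)
    # continuous margin-quality score: squared deviation of the decision
    # values from the +/-1 class targets; resolves ties when the discrete
    # error saturates at 0 on separable data
    test_mse <- mean((f_te - (2 * y_te - 1))^2)
    sv <- abs(fit$coef) > 1e-12
    w <- drop(crossprod(x_tr[sv, active, drop = FALSE], fit$coef[sv]))
    names(w) <- active
    trace[[step]] <- data.frame(
      size = length(active), gamma = ifelse(is.null(tuned$gamma), NA,
                                            tuned$gamma),
      cost = tuned$cost, cv_error = tuned$cv_error,
      test_error = test_error, test_mse = test_mse,
      removed = NA_character_,
      stringsAsFactors = FALSE)
    if (length(active) == config$rfe_floor) break
    aw <- abs(w)
    drop_gene <- active[order(aw, active)][1]
    trace[[step]]$removed <- drop_gene
    removal_order <- c(removal_order, drop_gene)
    # maintain squared distances without the removed gene
    dcol_tr <- x_tr[, drop_gene]
    D2_tr <- D2_tr - outer(dcol_tr, dcol_tr, "-")^2
    D2_tr[D2_tr < 0] <- 0
    dcol_te <- x_te[, drop_gene]
    D2_te <- D2_te - outer(dcol_tr, dcol_te, "-")^2
    D2_te[D2_te < 0] <- 0
    active <- setdiff(active, drop_gene)
  }
  trace <- do.call(rbind, trace)
  # best: minimal held-out misclassification; ties resolved by the
  # continuous margin score, then toward the smaller gene set
  minimal <- which(trace$test_error <= min(trace$test_error) + 1e-12)
  mse_min <- min(trace$test_mse[minimal])
  minimal <- minimal[trace$test_mse[minimal] <= mse_min + 1e-12]
  best <- minimal[length(minimal)]
  best_genes <- setdiff(genes, removal_order[seq_len(best - 1)])
  final_fit <- tune_and_fit(x_tr[, best_genes, drop = FALSE], y_tr, config)
  final_w <- feature_weights(final_fit)
  test_pred <- predict(final_fit, x_te[, best_genes, drop = FALSE])
  # ranks: floor survivors by final |weight|, removed genes in reverse order
  ranks <- setNames(rep(NA_integer_, G), genes)
  surv <- names(sort(abs(final_w), decreasing = TRUE))
  ranks[surv] <- seq_along(surv)
  if (length(removal_order) > 0)
    ranks[rev(removal_order)] <- length(surv) + seq_along(removal_order)
  structure(list(trace = trace, best_model = best,
                 predictor_genes = best_genes,
                 predictor_weights = final_w,
                 gene_ranks = ranks,
                 final_fit = final_fit,
                 test_predictions = test_pred,
                 test_error = mean(test_pred != y_te),
                 y_test = y_te,
                 focal_species = split$focal_species),
            class = "svm_rfe_result")
}

#' Randomization test of a trained model's held-out error
#'
#' Shuffles the focal species' phenotype labels and recomputes the test
#' error against the model's fixed predictions. The reported p-value uses
#' the add-one estimator `p = (1 + #(null <= observed)) / (n + 1)`; a
#' tie-randomized variant (`p_rand`, uniform under the null despite the
#' discreteness of error rates) is returned alongside.
#'
#' @param result an `svm_rfe_result` (or a list with `test_predictions` and
#'   `y_test`).
#' @param n_randomizations number of shuffles.
#' @param seed integer seed.
#' @return list with `observed_error`, `null_errors`, `p`, `p_rand`.
#' @export
randomization_test <- function(result, n_randomizations = 100, seed = 1L) {
  set.seed(seed)
  pred <- result$test_predictions; y <- result$y_test
  observed <- mean(pred != y)
  null <- vapply(seq_len(n_randomizations), function(b)
    mean(pred != sample(y)), 1.0)
  p <- (1 + sum(null <= observed)) / (n_randomizations + 1)
  # exactly uniform under exchangeability: the observed run counts as one
  # of the ties and the tied block is broken uniformly
  p_rand <- (sum(null < observed) +
               runif(1) * (1 + sum(null == observed))) /
    (n_randomizations + 1)
  list(observed_error = observed, null_errors = null, p = p, p_rand = p_rand)
}

#' Intersect predictor gene sets across focal species
#'
#' @param results list of `svm_rfe_result` (or a named list of character
#'   gene-id vectors).
#' @param min_species minimum number of focal species a gene must appear in.
#' @return list with `membership` (gene x species logical matrix),
#'   `counts_by_cardinality` (how many genes appear in exactly k sets),
#'   `common` (genes in >= `min_species` sets), `common_all` (genes in every
#'   set).
#' @export
intersect_predictors <- function(results, min_species = length(results)) {
  stopifnot(length(results) >= 2)
  sets <- lapply(results, function(r)
    if (inherits(r, "svm_rfe_result")) r$predictor_genes else as.character(r))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- vapply(results, function(r)
      if (inherits(r, "svm_rfe_result")) r$focal_species else NA_character_,
      "")
  if (anyDuplicated(names(sets))) stop("duplicate focal species")
  genes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  rownames(membership) <- genes
  k <- rowSums(membership)
  counts <- table(factor(k, levels = seq_along(sets)))
  list(membership = membership,
       counts_by_cardinality = as.integer(counts),
       common = genes[k >= min_species],
       common_all = genes[k == length(sets)])
}

#' Run leave-one-species-out SVM-RFE for every focal species
#'
#' @param nm a center-scaled `normalized_matrix` with a sample table.
#' @param config an [svm_config()].
#' @param lineage optional species subset (lineage-only SVMs).
#' @return list with `per_species` (named `svm_rfe_result`s),
#'   `randomization` (per-species randomization tests), `intersection`
#'   ([intersect_predictors()] at all species).
#' @export
run_svm_rfe <- function(nm, config = svm_config(), lineage = NULL) {
  species <- unique(nm$samples$species)
  if (!is.null(lineage)) species <- intersect(species, lineage)
  res <- list(); rand <- list()
  for (i in seq_along(species)) {
    s <- species[i]
    cfg <- config
    cfg$seed <- config$seed + i  # independent folds per focal species
    split <- loso_split(nm, s, lineage = lineage)
    r <- recursive_elimination(split, cfg)
    res[[s]] <- r
    rand[[s]] <- randomization_test(r, config$n_randomizations,
                                    seed = cfg$seed + 1000L)
  }
  list(per_species = res, randomization = rand,
       intersection = intersect_predictors(res))
}
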