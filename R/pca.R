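#' Principal component analysis of a normalized expression matrix
#'
#' Samples are observations, genes variables. Rows with missing values are
#' dropped (and logged on the result). PC signs are fixed so the
#' largest-|loading| gene of each component is positive, making results
#' deterministic.
#'
#' @param nm a `normalized_matrix` or bare genes-by-samples matrix.
#' @return a `pca_result`: `scores` (sample x PC), `loadings` (gene x PC),
#'   `explained_variance_fraction`, `n_dropped_rows`.
#' @export
run_pca <- function(nm) {
  values <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  samples <- if (inherits(nm, "normalized_matrix")) nm$samples else NULL
  keep <- stats::complete.cases(values)
  values <- values[keep, , drop = FALSE]
  if (ncol(values) < 3) stop("PCA needs at least 3 samples")
  pc <- prcomp(t(values), center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| gene positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance_fraction = evf,
                 center = pc$center,
                 samples = samples, n_dropped_rows = sum(!keep)),
            class = "pca_result")
}

# one-vs-rest 0/1 codings for a trait; binary traits give a single coding
trait_codings <- function(v, name) {
  lev <- sort(unique(as.character(v)))
  if (length(lev) < 2) return(NULL)
  if (length(lev) == 2) {
    out <- list(as.integer(as.character(v) == lev[2]))
    names(out) <- name
    return(out)
  }
  out <- lapply(lev, function(l) as.integer(as.character(v) == l))
  names(out) <- paste0(name, ":", lev)
  out
}

#' Screen top principal components for trait correlations
#'
#' Pearson correlation of each of the first `n_top` PC score vectors with
#' 0/1 codings of each trait; multi-level traits (species) are expanded
#' one-vs-rest. Benjamini-Hochberg correction is applied jointly across all
#' tested (PC, coding) pairs.
#'
#' @param pca a `pca_result`.
#' @param traits data.frame of traits (one row per sample, same order as
#'   scores), e.g. `samples[, c("clade", "species", "phenotype")]`.
#' @param n_top number of leading PCs to screen (default 10).
#' @param alpha significance level used by [trait_variance_explained()].
#' @return data.frame with columns `pc`, `trait`, `r`, `p`, `p_adj`;
#'   constant codings give `NA` correlations and are excluded from the
#'   adjustment.
#' @export
trait_correlation_screen <- function(pca, traits, n_top = 10, alpha = 0.05) {
  n_top <- min(n_top, ncol(pca$scores))
  codings <- list()
  for (nm in names(traits))
    codings <- c(codings, trait_codings(traits[[nm]], nm))
  rows <- list()
  for (k in seq_len(n_top)) {
    for (nm in names(codings)) {
      x <- pca$scores[, k]; y <- codings[[nm]]
      if (sd(y) == 0 || sd(x) == 0) {
        rows[[length(rows) + 1]] <-
          data.frame(pc = k, trait = nm, r = NA_real_, p = NA_real_)
      } else {
        ct <- cor.test(x, y)
        rows[[length(rows) + 1]] <-
          data.frame(pc = k, trait = nm, r = unname(ct$estimate),
                     p = ct$p.value)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  attr(out, "alpha") <- alpha
  out
}

#' Variance accounted for by a trait
#'
#' Defined as the sum over significantly correlated PCs of
#' `explained_variance_fraction * r^2`, where significance is
#' `p_adj < alpha` on the screen. For multi-level traits the maximum |r|
#' coding per PC is used.
#'
#' @param pca a `pca_result`.
#' @param screen result of [trait_correlation_screen()].
#' @param trait trait name (prefix for expanded codings).
#' @param alpha significance level (default the screen's).
#' @export
trait_variance_explained <- function(pca, screen, trait,
                                     alpha = attr(screen, "alpha")) {
  rows <- screen[screen$trait == trait |
                   startsWith(screen$trait, paste0(trait, ":")), ]
  rows <- rows[!is.na(rows$p_adj), ]
  if (nrow(rows) == 0) return(0)
  best <- aggregate(cbind(r2 = rows$r^2, sig = rows$p_adj < alpha),
                    by = list(pc = rows$pc),
                    FUN = max)
  sum(pca$explained_variance_fraction[best$pc] * best$r2 * (best$sig > 0))
}

#' Randomized-phenotype control for PC-trait correlations
#'
#' Shuffles phenotype labels within species (preserving the species signal
#' under the null) and records the maximum |r| between any of the first
#' `n_top` PCs and the shuffled phenotype coding. Since PCA is unsupervised
#' the components themselves are unchanged; only the labels move.
#'
#' @param pca a `pca_result` with a `samples` table.
#' @param n_top PCs screened (default 10).
#' @param n_shuffles number of label shuffles (>= 20).
#' @param seed integer seed.
#' @return list with `observed` (max |r| on real labels), `null` (vector of
#'   shuffled statistics), and `quantile` (empirical quantile of observed in
#'   the null).
#' @export
randomized_phenotype_control <- function(pca, n_top = 10, n_shuffles = 100,
                                         seed = 1L) {
  stopifnot(n_shuffles >= 20, !is.null(pca$samples))
  set.seed(seed)
  n_top <- min(n_top, ncol(pca$scores))
  scores <- pca$scores[, seq_len(n_top), drop = FALSE]
  pheno <- as.integer(pca$samples$phenotype == "reproductive")
  max_abs_r <- function(y) {
    if (sd(y) == 0) return(NA_real_)
    max(abs(suppressWarnings(cor(scores, y))), na.rm = TRUE)
  }
  observed <- max_abs_r(pheno)
  species <- pca$samples$species
  null <- vapply(seq_len(n_shuffles), function(b) {
    y <- pheno
    for (s in unique(species)) {
      idx <- which(species == s)
      y[idx] <- y[sample(idx)]
    }
    max_abs_r(y)
  }, 1.0)
  list(observed = observed, null = null,
       quantile = mean(null <= observed))
}
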