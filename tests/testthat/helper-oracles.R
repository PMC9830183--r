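# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles rather than calling the
# implementation under test.

# Benjamini-Hochberg step-up, literal definition:
# q_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  o <- order(pp)
  qs <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    qs[i] <- min(pp[o][js] * m / js)
  }
  qs <- pmin(qs, 1)
  res <- numeric(m)
  res[o] <- qs
  q[ok] <- res
  q
}

# topological overlap, element-by-element literal formula
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      u <- setdiff(seq_len(n), c(i, j))
      num <- sum(a[i, u] * a[u, j]) + a[i, j]
      ki <- sum(a[i, setdiff(seq_len(n), i)])
      kj <- sum(a[j, setdiff(seq_len(n), j)])
      out[i, j] <- num / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(a)
  out
}

# one-sided (enrichment) hypergeometric tail by explicit enumeration of
# choose() products: P(X >= k) for k successes among n_fg draws from a pool
# of K annotated in N total
hyper_tail_oracle <- function(k, K, n_fg, N) {
  kk <- k:min(K, n_fg)
  sum(choose(K, kk) * choose(N - K, n_fg - kk)) / choose(N, n_fg)
}

# random symmetric adjacency with unit diagonal
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# two-Gaussian-blob toy classification data
make_blobs <- function(n_per_class = 30, d = 5, sep = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d, 0), n_per_class, d),
             matrix(rnorm(n_per_class * d, sep / sqrt(d)), n_per_class, d))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

# small simulation configs shared across files
small_sim <- function(seed = 1, ...) {
  args <- modifyList(list(
    n_genes = 120, n_toolkit_genes = 10, toolkit_lfc = 1.5,
    n_clade_specific_genes = 4, n_modules = 2,
    module_size_range = c(12, 15), n_trait_modules = 1,
    n_samples_per_phenotype = c(6, 6), seed = seed), list(...))
  do.call(sim_config, args)
}

acceptance_sim <- function(seed, toolkit_lfc = 1.5, n_trait_modules = 1) {
  sim_config(n_genes = 300, n_toolkit_genes = 40, toolkit_lfc = toolkit_lfc,
             n_clade_specific_genes = 10, n_modules = 4,
             module_size_range = c(15, 25), n_trait_modules = n_trait_modules,
             n_samples_per_phenotype = c(8, 8), seed = seed)
}
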