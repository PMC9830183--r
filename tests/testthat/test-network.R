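test_that("soft-thresholded adjacency follows the power formulas", {
  # engineered exact correlation of 0.5
  x <- c(1, -1, 1, -1)
  z <- c(1, 1, -1, -1)
  y <- 0.5 * x + sqrt(3) / 2 * z
  expr <- rbind(g1 = x, g2 = y, g3 = x)
  expect_equal(cor(x, y), 0.5)
  a2 <- adjacency(expr, beta = 2)
  expect_equal(a2["g1", "g2"], 0.25, tolerance = 1e-12)
  expect_equal(a2["g1", "g3"], 1)  # perfectly correlated pair
  diagless <- a2; diag(diagless) <- 0
  expect_true(all(diagless >= 0 & diagless <= 1))
  # signed convention
  as <- adjacency(rbind(g1 = x, g2 = -x, g3 = z), beta = 1, sign = "signed")
  expect_equal(as["g1", "g2"], 0)
  # constant gene removed, too few samples rejected
  expect_false("gc" %in% rownames(adjacency(rbind(expr, gc = rep(1, 4)), 2)))
  expect_error(adjacency(expr[, 1:3], 2), "4 samples")
})

test_that("TOM equals the brute-force formula on random matrices", {
  set.seed(1)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    a <- random_adjacency(n)
    expect_lt(max(abs(tom(a) - tom_oracle(a))), 1e-10)
  }
  # no shared neighbors: identity adjacency gives zero off-diagonal
  id <- diag(4); dimnames(id) <- list(paste0("g", 1:4), paste0("g", 1:4))
  t_id <- tom(id)
  expect_equal(max(abs(t_id[upper.tri(t_id)])), 0)
  # complete graph: full overlap
  ones <- matrix(1, 5, 5, dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
  expect_equal(min(tom(ones)), 1)
})

test_that("consensus TOM takes calibrated quantiles with minimum semantics", {
  a <- random_adjacency(6); b <- random_adjacency(6)
  ta <- tom(a); tb <- tom(b)
  same <- consensus_tom(list(s1 = ta, s2 = ta), calibrate = FALSE)
  expect_equal(same, ta)
  cons0 <- consensus_tom(list(s1 = ta, s2 = tb), quantile = 0,
                         calibrate = FALSE)
  expect_equal(cons0[upper.tri(cons0)], pmin(ta, tb)[upper.tri(ta)])
  # an edgeless dataset forces the minimum to zero
  id <- diag(6); dimnames(id) <- dimnames(ta)
  cons_id <- consensus_tom(list(s1 = ta, s2 = id), quantile = 0,
                           calibrate = FALSE)
  expect_equal(max(cons_id[upper.tri(cons_id)]), 0)
  # direct median quantile on a constructed entry pair
  t1 <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = list(c("g1", "g2"),
                                                        c("g1", "g2")))
  t2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2, dimnames = dimnames(t1))
  cons_med <- consensus_tom(list(t1, t2), quantile = 0.5, calibrate = FALSE)
  expect_equal(cons_med["g1", "g2"], 0.4)
  # adding a species can only shrink minimum-consensus entries
  cons3 <- consensus_tom(list(s1 = ta, s2 = tb, s3 = tom(random_adjacency(6))),
                         quantile = 0, calibrate = FALSE)
  expect_true(all(cons3 <= cons0 + 1e-12))
  expect_error(consensus_tom(list(ta, tb[1:5, 1:5])), "share gene set")
})

test_that("module detection recovers planted blocks and respects min size", {
  cfg <- sim_config(n_genes = 150, n_toolkit_genes = 0, toolkit_lfc = 0,
                    n_clade_specific_genes = 0, n_modules = 3,
                    module_size_range = c(31, 40), n_trait_modules = 0,
                    dispersion_shape = c(log(0.05), 0.3), seed = 21)
  sim <- simulate_dataset(cfg)
  net <- consensus_network(variance_stabilize(sim$dataset),
                           network_config(beta = 6, resampling_k = 0))
  sc <- score_recovery(net$module_labels, sim$truth, role = "module")
  expect_gte(sc$ari, 0.9)
  # min_size above the gene count leaves everything unassigned
  expect_warning(lab <- detect_modules(net$consensus_tom, min_size = 1000),
                 "unassigned")
  expect_true(all(lab == 0))
  # relaxation nesting: assigned genes only grow as the size floor drops
  sizes <- names(net$modules_by_size)
  for (i in seq_along(sizes)[-1]) {
    prev <- net$modules_by_size[[sizes[i - 1]]]
    cur <- net$modules_by_size[[sizes[i]]]
    expect_true(all(names(prev)[prev > 0] %in% names(cur)[cur > 0]))
  }
})

test_that("a 15-gene module appears only once the size floor relaxes", {
  cfg <- sim_config(n_genes = 120, n_toolkit_genes = 0, toolkit_lfc = 0,
                    n_clade_specific_genes = 0, n_modules = 1,
                    module_size_range = c(15, 15), n_trait_modules = 0,
                    dispersion_shape = c(log(0.05), 0.3), seed = 22)
  sim <- simulate_dataset(cfg)
  net <- consensus_network(variance_stabilize(sim$dataset),
                           network_config(beta = 6, resampling_k = 0))
  mg <- names(sim$truth$module_membership)[sim$truth$module_membership == 1]
  found_at <- vapply(net$modules_by_size, function(lab) {
    mods <- unique(lab[lab > 0])
    length(mods) > 0 && any(vapply(mods, function(m)
      sum(lab[mg] == m) >= 12, TRUE))
  }, TRUE)
  expect_false(found_at[["30"]])
  expect_false(found_at[["20"]])
  expect_true(found_at[["10"]])
})

test_that("eigengenes match the leading SVD direction with oriented sign", {
  set.seed(31)
  expr <- matrix(rnorm(5 * 12), 5, 12,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  eg <- eigengene(expr, paste0("g", 1:5))
  v1 <- svd(t(scale(t(expr))))$v[, 1]
  expect_lt(min(max(abs(eg - v1 / sd(v1))),
                max(abs(eg + v1 / sd(v1)))), 1e-8)
  expect_equal(sd(eg), 1)
  # identical member genes: kME 1 for all of them
  same <- matrix(rep(rnorm(12), 4), 4, 12, byrow = TRUE,
                 dimnames = list(paste0("g", 1:4), NULL))
  same <- same + matrix(rnorm(48, sd = 1e-8), 4, 12)
  eg2 <- eigengene(same, paste0("g", 1:4))
  expect_true(all(kme(same, eg2) > 0.999))
  # anti-correlated outsider gets negative kME
  anti <- rbind(same, g5 = -same[1, ])
  expect_lt(kme(anti, eg2)["g5"], 0)
  expect_error(eigengene(matrix(1, 2, 6,
                                dimnames = list(c("a", "b"), NULL)),
                         c("a", "b")),
               "variance")
})

test_that("Stouffer meta-analysis combines per-species correlations correctly", {
  # identical r, equal n: equal weights reduce to z_single * sqrt(S)
  z <- castemeta:::stouffer_meta(rep(0.5, 4), rep(16, 4))
  z1 <- atanh(0.5) * sqrt(13)
  expect_equal(unname(z["z"]), z1 * sqrt(4), tolerance = 1e-12)
  # opposite correlations cancel
  z0 <- castemeta:::stouffer_meta(c(0.9, -0.9), c(16, 16))
  expect_equal(unname(z0["z"]), 0, tolerance = 1e-12)
  # hand-computed three-species case, frozen:
  # z_s = atanh(0.6, 0.3, -0.1) * sqrt(7, 13, 21) = (1.83400, 1.11600,
  # -0.45981); w = sqrt(10, 16, 24); sum(w z)/sqrt(50) = 1.13290
  r <- c(0.6, 0.3, -0.1); n <- c(10, 16, 24)
  expect_equal(unname(castemeta:::stouffer_meta(r, n)["z"]),
               1.13290, tolerance = 1e-4)
})

test_that("module preservation Z separates planted from random gene sets", {
  cfg <- sim_config(n_genes = 100, n_toolkit_genes = 0, toolkit_lfc = 0,
                    n_clade_specific_genes = 0, n_modules = 1,
                    module_size_range = c(30, 30), n_trait_modules = 0,
                    dispersion_shape = c(log(0.01), 0.1), seed = 41)
  sim <- simulate_dataset(cfg)
  vst <- variance_stabilize(sim$dataset)
  samples <- vst$samples
  expr <- lapply(unique(samples$species), function(s)
    vst$values[, samples$species == s, drop = FALSE])
  names(expr) <- unique(samples$species)
  mg <- names(sim$truth$module_membership)[sim$truth$module_membership == 1]
  z_planted <- preservation_z(expr, mg, n_permutations = 30, seed = 5)
  expect_gt(z_planted, 5)
  set.seed(6)
  z_rand <- vapply(1:5, function(i)
    preservation_z(expr, sample(rownames(vst$values), 30),
                   n_permutations = 30, seed = i), 1.0)
  expect_gte(mean(abs(z_rand) < 2), 0.8)
  expect_error(preservation_z(expr, mg[1]), ">= 2 genes")
})

test_that("trait association flags planted trait modules, not others", {
  cfg <- small_sim(seed = 51, n_genes = 150, n_modules = 3,
                   module_size_range = c(15, 20), n_trait_modules = 1)
  sim <- simulate_dataset(cfg)
  net <- consensus_network(variance_stabilize(sim$dataset),
                           network_config(beta = 6, resampling_k = 0))
  # identify detected modules dominated by planted trait-module genes
  mm <- sim$truth$module_membership
  trait_genes_planted <- names(mm)[mm %in% sim$truth$trait_modules]
  overlap <- vapply(net$significant_modules, function(m) {
    mid <- as.integer(sub("M", "", m))
    mem <- names(net$module_labels)[net$module_labels == mid]
    length(intersect(mem, trait_genes_planted)) / length(mem)
  }, 1.0)
  # at least one significant module is dominated by the planted trait module
  # (the toolkit genes may legitimately form a second phenotype module)
  expect_true(any(overlap > 0.6))
})

test_that("resampling null is seeded and degenerate literal rule is exposed", {
  cfg <- small_sim(seed = 61, toolkit_lfc = 2, n_toolkit_genes = 16)
  sim <- simulate_dataset(cfg)
  vst <- variance_stabilize(sim$dataset)
  ncfg <- network_config(beta = 6, resampling_k = 12, seed = 9)
  net <- consensus_network(vst, ncfg)
  expect_gt(length(net$trait_genes), 0)
  rn1 <- resampling_null(vst, ncfg, net$trait_genes)
  rn2 <- resampling_null(vst, ncfg, net$trait_genes)
  expect_identical(rn1$proportions, rn2$proportions)
  # strong planted signal: no shuffled network recovers the full set
  expect_equal(rn1$p_exceedance, 1 / 13)
  # the literal two-tailed rule counts every fully-extreme proportion;
  # with all-zero recoveries it saturates at 1
  if (all(rn1$proportions == 0)) expect_equal(rn1$p_two_tailed, 1)
  expect_error(resampling_null(vst, ncfg, character(0)), "empty")
})

test_that("a single dataset's consensus is its own network", {
  set.seed(71)
  cfg <- sim_config(n_genes = 80, n_toolkit_genes = 0, toolkit_lfc = 0,
                    n_clade_specific_genes = 0, n_modules = 2,
                    module_size_range = c(15, 20), n_trait_modules = 1,
                    dispersion_shape = c(log(0.05), 0.3), seed = 71)
  sim <- simulate_dataset(cfg)
  vst <- variance_stabilize(sim$dataset)
  one <- vst$values[, vst$samples$species == "sp01"]
  pheno <- as.integer(
    vst$samples$phenotype[vst$samples$species == "sp01"] == "reproductive")
  res <- single_species_network(one, pheno,
                                network_config(beta = 6, resampling_k = 0))
  expect_equal(res$tom,
               consensus_tom(list(tom(adjacency(one, 6))), quantile = 0))
  # planted modules recovered within the single species
  mm <- sim$truth$module_membership
  pred <- res$module_labels[names(mm)]
  ari <- mclust::adjustedRandIndex(mm[mm > 0], pred[mm > 0])
  expect_gte(ari, 0.7)
})
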