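make_og_tsv <- function(path) {
  # 4 orthogroups over 6 species: one retained (absent in 1, <=3 copies),
  # one with 4 copies in a species, one absent in 2 species, one single-copy
  sp <- paste0("sp0", 1:6)
  rows <- list(
    OG1 = c("a1", "a2, a3", "a4", "a5", "a6", ""),
    OG2 = c("b1, b2, b3, b4", "b5", "b6", "b7", "b8", "b9"),
    OG3 = c("c1", "c2", "c3", "c4", "", ""),
    OG4 = c("d1", "d2", "d3", "d4", "d5", "d6"))
  df <- data.frame(Orthogroup = names(rows),
                   do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df)[-1] <- sp
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

test_that("orthogroup policy retains, drops and logs with reasons", {
  p <- withr::local_tempfile(fileext = ".tsv")
  make_og_tsv(p)
  og <- read_orthogroups(p, ortho_filter_policy())
  expect_setequal(names(og$map), c("OG1", "OG4"))
  expect_equal(og$log$reason[og$log$orthogroup == "OG2"], "copy_number")
  expect_equal(og$log$reason[og$log$orthogroup == "OG3"], "absence")
  # accounting: dropped + retained = input
  expect_equal(length(og$map) + nrow(og$log), 4)
  # stricter absence policy drops OG1 too
  og0 <- read_orthogroups(p, ortho_filter_policy(max_absent_species = 0))
  expect_false("OG1" %in% names(og0$map))
})

test_that("multi-copy reduction follows the policy rule", {
  counts <- list(
    spA = matrix(c(10, 30), 2, 2, dimnames = list(c("x1", "x2"),
                                                  c("A_1", "A_2"))),
    spB = matrix(c(7, 7), 1, 2, dimnames = list("y1", c("B_1", "B_2"))))
  counts$spA[] <- c(10L, 30L, 10L, 30L)
  meta <- data.frame(sample_id = c("A_1", "A_2", "B_1", "B_2"),
                     species = c("spA", "spA", "spB", "spB"),
                     clade = "c1",
                     phenotype = rep(c("reproductive", "non_reproductive"), 2))
  og <- list(OGx = list(spA = c("x1", "x2"), spB = "y1"))
  ds_sum <- assemble_ortho_matrix(counts, og, meta,
                                  ortho_filter_policy(multi_copy_reduction = "sum"))
  expect_equal(unname(ds_sum$counts["OGx", c("A_1", "A_2")]), c(40L, 40L))
  ds_max <- assemble_ortho_matrix(counts, og, meta,
                                  ortho_filter_policy(multi_copy_reduction = "max"))
  expect_equal(unname(ds_max$counts["OGx", "A_1"]), 30L)
  # single-copy species passes its row through untouched
  expect_equal(unname(ds_sum$counts["OGx", c("B_1", "B_2")]), c(7L, 7L))
})

test_that("writing then reading a simulated dataset round-trips exactly", {
  sim <- simulate_dataset(small_sim(seed = 9,
                                    n_samples_per_phenotype = c(3, 4)))
  d <- withr::local_tempdir()
  write_dataset(sim, d)
  species <- unique(sim$dataset$samples$species)
  counts <- lapply(species, function(s)
    read_counts(file.path(d, paste0("counts_", s, ".tsv"))))
  names(counts) <- species
  meta <- read_metadata(file.path(d, "metadata.tsv"))
  og <- read_orthogroups(file.path(d, "Orthogroups.tsv"))
  ds <- assemble_ortho_matrix(counts, og, meta)
  expect_equal(ds$counts, sim$dataset$counts)
  expect_equal(ds$samples$phenotype, sim$dataset$samples$phenotype)
})

test_that("reader errors identify the offending input", {
  expect_error(read_counts(tempfile()), "not found")
  expect_error(read_metadata(tempfile()), "not found")
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = c("g1", "g1"), s1 = c(1, 2)),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_counts(p), "duplicated gene id")
  # sample missing from metadata
  counts <- list(spA = matrix(1:4, 2, 2,
                              dimnames = list(c("x1", "x2"), c("A_1", "A_9"))))
  meta <- data.frame(sample_id = "A_1", species = "spA", clade = "c1",
                     phenotype = "reproductive")
  expect_error(assemble_ortho_matrix(counts, list(OG1 = list(spA = "x1")),
                                     meta),
               "A_9")
})

test_that("size factors are median-of-ratios and scale-equivariant", {
  set.seed(1)
  a <- matrix(rpois(60, 50), 20, 3,
              dimnames = list(paste0("g", 1:20), c("s1", "s2", "s3")))
  doubled <- cbind(a, s4 = 2L * a[, 1])
  sf <- size_factors(doubled)
  expect_equal(unname(sf["s4"] / sf["s1"]), 2, tolerance = 1e-12)
  # identical samples get identical factors
  same <- cbind(a[, 1], a[, 1], a[, 1])
  expect_equal(var(size_factors(same)), 0)
  # 3-gene, 2-sample hand computation
  m <- matrix(c(10, 100, 4, 20, 50, 16), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("u", "v")))
  geo <- exp(rowMeans(log(m)))
  by_hand <- c(median(m[, 1] / geo), median(m[, 2] / geo))
  expect_equal(unname(size_factors(m)), by_hand)
  # no universally expressed gene: falls back with a warning
  z <- matrix(c(0, 5, 3, 0), 2, 2)
  expect_warning(size_factors(z), "total-count")
})

test_that("variance stabilization is monotone and flattens the mean-variance trend", {
  sim <- simulate_dataset(small_sim(seed = 21, n_genes = 200,
                                    n_toolkit_genes = 0, toolkit_lfc = 0,
                                    n_clade_specific_genes = 0, n_modules = 0,
                                    n_trait_modules = 0))
  vst <- variance_stabilize(sim$dataset)
  expect_equal(vst$transform, "vst")
  expect_gt(vst$dispersion_trend["asympt"], 0)
  # monotone in counts within a sample
  o <- order(sim$dataset$counts[, 1])
  expect_true(all(diff(vst$values[o, 1]) >= 0))
  # slope of log variance vs log mean: ~1 on raw normalized counts,
  # near zero after the transform
  q <- sweep(sim$dataset$counts, 2, vst$size_factors, "/")
  slope <- function(m) {
    mu <- rowMeans(m); v <- apply(m, 1, var)
    unname(coef(lm(log(v) ~ log(mu)))[2])
  }
  expect_gt(slope(q), 0.7)
  vv <- apply(vst$values, 1, var)
  mm <- rowMeans(q)
  expect_lte(unname(coef(lm(log(vv) ~ log(mm)))[2]), 0.3)
})

test_that("with a flat dispersion trend the transform becomes affine log2", {
  # constant dispersion (the extra-Poisson/mu term -> 0): for counts well
  # above 1/alpha the stabilizer reduces to log2 up to an additive constant
  set.seed(31)
  mu <- exp(runif(300, log(50), log(50000)))
  counts <- matrix(rnbinom(300 * 20, mu = rep(mu, 20), size = 10), 300, 20,
                   dimnames = list(paste0("g", 1:300), paste0("s", 1:20)))
  samples <- data.frame(sample_id = paste0("s", 1:20), species = "spA",
                        clade = "c1",
                        phenotype = rep(c("reproductive", "non_reproductive"), 10))
  ds <- ortho_dataset(counts, samples)
  vst <- variance_stabilize(ds, species_aware = FALSE)
  q <- sweep(counts, 2, vst$size_factors, "/")
  big <- rowMeans(q) > 1000
  fit <- lm(vst$values[big, 1] ~ log2(q[big, 1] + 1))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
})

test_that("Poisson-simulated data is flattened across mean bins", {
  set.seed(32)
  mu <- exp(runif(300, log(5), log(5000)))
  counts <- matrix(rpois(300 * 20, rep(mu, 20)), 300, 20,
                   dimnames = list(paste0("g", 1:300), paste0("s", 1:20)))
  samples <- data.frame(sample_id = paste0("s", 1:20), species = "spA",
                        clade = "c1",
                        phenotype = rep(c("reproductive", "non_reproductive"), 10))
  vst <- variance_stabilize(ortho_dataset(counts, samples),
                            species_aware = FALSE)
  q <- sweep(counts, 2, vst$size_factors, "/")
  v <- apply(vst$values, 1, var)
  bins <- cut(log(rowMeans(q)), 4)
  bv <- tapply(v, bins, median)
  expect_lt(max(bv) / min(bv), 3)
})

test_that("center-scaling zeroes means, unitizes sds and flags constants", {
  set.seed(2)
  m <- matrix(rnorm(24, 5, 3), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  cs <- center_scale(m)
  expect_lt(max(abs(rowMeans(cs))), 1e-12)
  expect_equal(unname(apply(cs, 1, sd)), rep(1, 4))
  const <- rbind(m, g5 = rep(2, 6))
  cs2 <- center_scale(const)
  expect_equal(unname(cs2["g5", ]), rep(0, 6))
  expect_equal(attr(cs2, "constant_rows"), "g5")
  # per-species scope removes the species signal gene-wise
  sim <- simulate_dataset(small_sim(seed = 23))
  vst <- variance_stabilize(sim$dataset)
  sc <- center_scale(vst, "per_species")
  for (s in unique(sc$samples$species)) {
    block <- sc$values[, sc$samples$species == s]
    expect_lt(max(abs(rowMeans(block))), 1e-10)
  }
})
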