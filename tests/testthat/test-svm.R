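scaled_sim <- function(seed = 1, ...) {
  sim <- simulate_dataset(small_sim(seed = seed, ...))
  list(sim = sim,
       nm = center_scale(variance_stabilize(sim$dataset), "per_species"))
}

test_that("leave-one-species-out splits partition samples by species", {
  s <- scaled_sim(1)
  split <- loso_split(s$nm, "sp03")
  samples <- s$nm$samples
  expect_equal(nrow(split$x_test), sum(samples$species == "sp03"))
  expect_equal(nrow(split$x_train), sum(samples$species != "sp03"))
  expect_setequal(unique(split$y_test), c(0L, 1L))
  # lineage mode restricts to the named species
  lin <- loso_split(s$nm, "sp01", lineage = c("sp01", "sp02", "sp03"))
  expect_equal(nrow(lin$x_train),
               sum(samples$species %in% c("sp02", "sp03")))
  expect_error(loso_split(s$nm, "sp01", lineage = "sp01"), "2 species")
  expect_error(loso_split(s$nm, "nope"), "unknown focal")
})

test_that("grid tuning separates blobs and stays at chance on shuffled labels", {
  blobs <- make_blobs(n_per_class = 30, d = 5, sep = 4, seed = 2)
  cfg <- svm_config(gamma_grid = c(0.001, 0.01, 0.1), cost_grid = c(1, 10),
                    seed = 3)
  fit <- tune_and_fit(blobs$x, blobs$y, cfg)
  expect_lte(fit$cv_error, 0.1)
  set.seed(4)
  y_shuf <- sample(blobs$y)
  fit0 <- tune_and_fit(blobs$x, y_shuf, cfg)
  expect_gt(fit0$cv_error, 0.25)
  # indistinguishable classes: identical rows in both classes
  x_dup <- rbind(blobs$x[1:10, ], blobs$x[1:10, ])
  y_dup <- rep(c(0L, 1L), each = 10)
  fit_dup <- tune_and_fit(x_dup, y_dup, cfg)
  expect_gte(fit_dup$cv_error, 0.4)
})

test_that("feature weights equal the explicit primal vector for linear kernels", {
  set.seed(5)
  n <- 40; d <- 6
  x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
  # separable labels and a high cost: effectively hard margin, where the
  # duplicated-column identity w_f1 + w_f1b = w_f1(original) is exact
  y <- as.integer(x[, 1] > 0)
  cfg <- svm_config(kernel = "linear", cost_grid = 100, seed = 6)
  fit <- tune_and_fit(x, y, cfg)
  w <- feature_weights(fit)
  w_primal <- drop(crossprod(fit$x, fit$coef))  # sum_i alpha_i y_i x_i
  expect_lt(max(abs(w - w_primal)), 1e-8)
  # informative feature dominates
  expect_equal(unname(which.max(abs(w))), 1)
  # a duplicated column splits weight; the pair sums to the original
  x2 <- cbind(x, f1b = x[, 1])
  fit2 <- tune_and_fit(x2, y, cfg)
  w2 <- feature_weights(fit2)
  expect_equal(unname(w2["f1"] + w2["f1b"]), unname(w["f1"]),
               tolerance = 0.15)
  # an identically-zero feature carries zero weight
  x3 <- cbind(x, fz = 0)
  w3 <- feature_weights(tune_and_fit(x3, y, cfg))
  expect_equal(unname(w3["fz"]), 0)
})

test_that("the dual solver matches e1071 decision values on well-posed problems", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 40; d <- 8
    x <- matrix(rnorm(n * d), n, d)
    y <- sample(c(0L, 1L), n, replace = TRUE)
    gamma <- 10^runif(1, -3, -1); cost <- 10^runif(1, 0, 1)
    K <- exp(-gamma * as.matrix(dist(x))^2)
    fit <- castemeta:::fit_kernel_svm(K, y, cost)
    f <- castemeta:::smo_decision(K, fit$coef, fit$rho)
    m <- e1071::svm(x, factor(y, levels = c(1, 0)), kernel = "radial",
                    gamma = gamma, cost = cost, scale = FALSE)
    fe <- attr(predict(m, x, decision.values = TRUE), "decision.values")[, 1]
    sgn <- if (y[1] == 1) 1 else -1
    nfree <- sum(abs(fit$coef) > 1e-9 & abs(fit$coef) < cost - 1e-9)
    if (nfree > 0) expect_lt(max(abs(f - sgn * fe)), 0.05)
  }
})

test_that("recursive elimination keeps informative genes and obeys the floor", {
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60; G <- 50
    x <- matrix(rnorm(n * G), n, G,
                dimnames = list(NULL, sprintf("g%02d", 1:G)))
    y <- rep(c(0L, 1L), each = n / 2)
    x[y == 1, 1:5] <- x[y == 1, 1:5] + 2
    split <- list(x_train = x[c(1:20, 31:50), ], y_train = y[c(1:20, 31:50)],
                  x_test = x[c(21:30, 51:60), ], y_test = y[c(21:30, 51:60)],
                  focal_species = "toy")
    cfg <- svm_config(gamma_grid = c(0.001, 0.01), cost_grid = c(1, 10),
                      rfe_floor = 10, seed = seed)
    r <- recursive_elimination(split, cfg)
    expect_equal(r$trace$size, seq(G, 10))
    if (all(sprintf("g%02d", 1:5) %in% r$predictor_genes)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("a floor one below the gene count yields a two-entry trace", {
  blobs <- make_blobs(n_per_class = 12, d = 6, sep = 3, seed = 8)
  split <- list(x_train = blobs$x[c(1:8, 13:20), ],
                y_train = blobs$y[c(1:8, 13:20)],
                x_test = blobs$x[c(9:12, 21:24), ],
                y_test = blobs$y[c(9:12, 21:24)], focal_species = "toy")
  cfg <- svm_config(gamma_grid = 0.01, cost_grid = 1, rfe_floor = 5, seed = 9)
  r <- recursive_elimination(split, cfg)
  expect_equal(r$trace$size, c(6, 5))
  expect_error(recursive_elimination(split,
                                     svm_config(rfe_floor = 6, seed = 1)),
               "floor")
})

test_that("randomization test uses the add-one estimator", {
  # observed below every null
  rt <- randomization_test(list(test_predictions = rep(c(0L, 1L), 8),
                                y_test = rep(c(0L, 1L), 8)),
                           n_randomizations = 100, seed = 10)
  expect_equal(rt$observed_error, 0)
  expect_equal(rt$p, 1 / 101)
  # chance-level predictions sit mid-null
  set.seed(11)
  rt2 <- randomization_test(list(test_predictions = rbinom(16, 1, 0.5),
                                 y_test = rep(c(0L, 1L), each = 8)),
                            n_randomizations = 200, seed = 12)
  expect_gt(rt2$p, 0.1)
  # determinism under a fixed seed
  pred <- rbinom(16, 1, 0.5)
  rt3 <- randomization_test(list(test_predictions = pred,
                                 y_test = rep(c(0L, 1L), each = 8)),
                            n_randomizations = 50, seed = 13)
  rt4 <- randomization_test(list(test_predictions = pred,
                                 y_test = rep(c(0L, 1L), each = 8)),
                            n_randomizations = 50, seed = 13)
  expect_identical(rt3$null_errors, rt4$null_errors)
  expect_identical(rt3$p_rand, rt4$p_rand)
})

test_that("predictor intersections follow exact set algebra", {
  sets <- list(a = c("A", "B", "C"), b = c("A", "B"), c = "A")
  res <- intersect_predictors(sets, min_species = 2)
  expect_setequal(res$common, c("A", "B"))
  expect_setequal(res$common_all, "A")
  expect_equal(res$counts_by_cardinality, c(1L, 1L, 1L))
  same <- replicate(6, c("x", "y"), simplify = FALSE)
  names(same) <- paste0("s", 1:6)
  expect_setequal(intersect_predictors(same)$common_all, c("x", "y"))
  disjoint <- list(a = "A", b = "B", c = "C")
  expect_length(intersect_predictors(disjoint, 2)$common, 0)
  expect_error(intersect_predictors(list(a = "A", a = "B")), "duplicate")
})
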