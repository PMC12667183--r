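test_that("Mantel r is 1 with p at the add-one floor when matrices coincide", {
  set.seed(103)
  d <- as.matrix(dist(matrix(rnorm(16), 8)))
  res <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)
})

test_that("Mantel input validation catches shape and symmetry problems", {
  d <- as.matrix(dist(matrix(rnorm(10), 5)))
  expect_error(mantel_test(d, d[1:4, 1:4]), "dimension")
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(mantel_test(d, bad), "symmetric")
})

test_that("Mantel p-values are reproducible and never zero", {
  set.seed(107)
  d1 <- as.matrix(dist(matrix(rnorm(20), 10)))
  d2 <- as.matrix(dist(matrix(rnorm(20), 10)))
  a <- mantel_test(d1, d2, n_perm = 199, seed = 3)
  b <- mantel_test(d1, d2, n_perm = 199, seed = 3)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 200)
})

test_that("Spearman Mantel is invariant to monotone rescaling", {
  set.seed(109)
  d1 <- as.matrix(dist(matrix(rnorm(16), 8)))
  d2 <- as.matrix(dist(matrix(rnorm(16), 8)))
  a <- mantel_test(d1, d2, method = "spearman", n_perm = 99, seed = 5)
  b <- mantel_test(d1, exp(d2), method = "spearman", n_perm = 99, seed = 5)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_identical(a$p, b$p)
})

test_that("Monte-Carlo Mantel p matches exhaustive 4x4 enumeration", {
  set.seed(113)
  for (i in 1:5) {
    d1 <- as.matrix(dist(matrix(rnorm(8), 4)))
    d2 <- as.matrix(dist(matrix(rnorm(8), 4)))
    exact <- mantel_exact_oracle(d1, d2)
    # enumerated-permutation path agrees with the oracle exactly
    enum <- mantel_test(d1, d2, permutations = all_permutations(4))
    expect_equal(enum$p, (24 * exact + 1) / 25, tolerance = 1e-12)
    mc <- mantel_test(d1, d2, n_perm = 1999, seed = i)
    se <- sqrt(exact * (1 - exact) / 2000)
    expect_lt(abs(mc$p - exact), 3 * se + 2 / 2000)
  }
})

test_that("Mantel agrees with the vegan implementation on the statistic", {
  set.seed(127)
  d1 <- as.matrix(dist(matrix(rnorm(24), 12)))
  d2 <- as.matrix(dist(matrix(rnorm(24), 12)))
  ours <- mantel_test(d1, d2, n_perm = 999, seed = 1)
  ref <- vegan::mantel(d1, d2, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("a perfect predictor dominates the importance ranking", {
  set.seed(131)
  for (run in 1:10) {
    X <- as.data.frame(matrix(rnorm(30 * 6), 30,
                              dimnames = list(NULL, paste0("f", 1:6))))
    y <- X$f1
    imp <- permutation_importance(X, y, n_trees = 200, n_null = 30)
    expect_equal(imp$feature[1], "f1")
    expect_lte(imp$p[imp$feature == "f1"], 0.05)
  }
})

test_that("importance machinery rejects degenerate input", {
  X <- matrix(rnorm(40), 10)
  expect_error(permutation_importance(X, rep(1, 10)), "no variance")
  expect_error(permutation_importance(X[1:5, ], rnorm(5)), "8 samples")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(permutation_importance(Xna, rnorm(10)), "missing")
})

test_that("constant features earn no importance and no significance", {
  set.seed(137)
  sig <- vapply(1:20, function(i) {
    X <- data.frame(flat = rep(1, 20),
                    a = rnorm(20), b = rnorm(20))
    y <- X$a + rnorm(20, 0, 0.3)
    imp <- permutation_importance(X, y, n_trees = 150, n_null = 40)
    c(imp$importance[imp$feature == "flat"],
      imp$p[imp$feature == "flat"])
  }, numeric(2))
  expect_lt(max(sig[1, ]), 1e-6)      # never informative beyond noise
  expect_true(all(sig[2, ] > 0.05))   # never significant
})

test_that("importance results are reproducible under a fixed seed", {
  X <- as.data.frame(matrix(rnorm(30 * 4), 30))
  y <- rnorm(30)
  a <- permutation_importance(X, y, n_trees = 100, n_null = 20, seed = 9)
  b <- permutation_importance(X, y, n_trees = 100, n_null = 20, seed = 9)
  expect_identical(a$importance, b$importance)
  expect_identical(a$p, b$p)
})

test_that("the driver report recovers known drivers on a synthetic fixture", {
  set.seed(139)
  td <- simulate_trial(trial_config(), seed = 139)
  rep <- driver_report(td, depths = "0-20", n_perm = 199, n_null = 30,
                       n_trees = 200, seed = 139)
  blk <- rep$result[["0-20"]][["yield"]]
  expect_s3_class(blk$importance, "perm_importance")
  expect_true(all(c("feature", "r", "p", "stars") %in%
                    names(blk$correlations)))
  # yield falls with the substitution rate while most topsoil indicators
  # rise, so the feature block must carry signal for yield
  expect_lt(blk$mantel$p, 0.05)
})

test_that("single-depth driver reports work and stay restricted", {
  td <- simulate_trial(trial_config(), seed = 149)
  rep <- driver_report(td, depths = "20-40", n_perm = 99, n_null = 20,
                       n_trees = 100, seed = 7)
  expect_named(rep$result, "20-40")
  expect_named(rep$result[["20-40"]], c("yield", "sqi"))
})
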