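test_that("published summary rows reconstruct their printed ANOVA p-values", {
  yield <- anova_from_summary(c(11.3, 11.7, 10.3, 8.35, 4.03),
                              c(0.83, 1.46, 0.69, 1.22, 0.35), n = 3)
  expect_equal(yield$df, c(4, 10))
  expect_lt(yield$p, 0.001)

  rlen <- anova_from_summary(c(5.86, 5.12, 4.99, 4.92, 3.32),
                             c(0.86, 0.66, 0.43, 0.42, 0.34), n = 3)
  expect_equal(round(rlen$p, 3), 0.004)

  rsa <- anova_from_summary(c(13.9, 12.6, 10.2, 11.9, 7.09),
                            c(2.44, 1.69, 1.44, 1.93, 1.23), n = 3)
  expect_equal(round(rsa$p, 3), 0.008)

  rvol <- anova_from_summary(c(26.2, 24.9, 15.6, 21.5, 12.2),
                             c(5.63, 3.75, 1.88, 3.28, 3.38), n = 3)
  expect_equal(round(rvol$p, 3), 0.004)
})

test_that("degenerate summaries hit the documented F extremes", {
  same <- anova_from_summary(c(3, 3, 3), c(1, 1, 1), n = 4)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  sep <- anova_from_summary(c(1, 2), c(0, 0), n = 3)
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)
  flat <- anova_from_summary(c(2, 2), c(0, 0), n = 3)
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)
})

test_that("with two groups F is the squared pooled t statistic", {
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5, 1)
    res <- anova_from_summary(c(mean(a), mean(b)), c(sd(a), sd(b)), n = 5)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("raw-data ANOVA equals the summary reconstruction on matched moments", {
  set.seed(37)
  for (i in 1:20) {
    k <- sample(3:6, 1); n <- sample(3:5, 1)
    means <- rnorm(k, 10, 3); sds <- runif(k, 0.5, 2)
    vals <- lapply(seq_len(k), function(g)
      moment_matched_group(means[g], sds[g], n))
    names(vals) <- paste0("T", seq_len(k))
    rec <- records_from_groups(vals)
    raw <- anova_from_raw(rec, "y", "0-20")
    summ <- anova_from_summary(means, sds, n)
    expect_equal(raw$F, summ$F, tolerance = 1e-10)
    expect_equal(raw$p, summ$p, tolerance = 1e-10)
    expect_equal(raw$MSW, summ$MSW, tolerance = 1e-10)
  }
})

test_that("a constant dataset yields F = 0", {
  vals <- lapply(setNames(nm = c("A", "B", "C")), function(t) rep(7, 3))
  res <- anova_from_raw(records_from_groups(vals), "y")
  expect_equal(res$F, 0)
})

test_that("one-way ANOVA rejects reliably under a large injected effect", {
  set.seed(41)
  rej <- mean(vapply(1:500, function(i) {
    vals <- list(A = rnorm(3, 10, 1), B = rnorm(3, 10, 1),
                 C = rnorm(3, 15, 1))
    anova_from_raw(records_from_groups(vals), "y")$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.95)
})

test_that("two-way terms are calibrated at the null and detect a depth effect", {
  set.seed(43)
  sim_p <- function(depth_shift) {
    vals <- expand.grid(treatment = c("A", "B", "C"), replicate = 1:3,
                        depth = c("0-20", "20-40"),
                        stringsAsFactors = FALSE)
    vals$variable <- "y"
    vals$value <- rnorm(nrow(vals)) +
      depth_shift * (vals$depth == "20-40")
    vals$unit <- ""
    two_way_anova(vals, "y")
  }
  null_p <- t(vapply(1:400, function(i) sim_p(0)$p[1:3], numeric(3)))
  for (j in 1:3) {
    rate <- mean(null_p[, j] < 0.05)
    expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 400))
    expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400))
  }
  depth_p <- t(vapply(1:100, function(i) sim_p(3)$p[1:3], numeric(3)))
  expect_gt(mean(depth_p[, 2] < 0.05), 0.95)           # depth detected
  trt_rate <- mean(depth_p[, 1] < 0.05)                # treatment still null
  expect_lt(trt_rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 100))
})

test_that("collapsing to one depth reduces the two-way fit to the one-way F", {
  td <- simulate_trial(trial_config(), seed = 47)
  r <- td$records[td$records$depth == "0-20", ]
  tw <- two_way_anova(r, "SOC")
  ow <- anova_from_raw(r, "SOC", "0-20")
  expect_equal(nrow(tw), 2)
  expect_equal(tw$F[1], ow$F, tolerance = 1e-12)
})

test_that("letter displays collapse and separate in the obvious limits", {
  expect_equal(unname(tukey_letters(c(5, 5, 5), c(1, 1, 1), n = 3)),
               rep("a", 3))
  expect_equal(unname(tukey_letters(c(0, 10, 20), c(0.01, 0.01, 0.01),
                                    n = 3)),
               c("c", "b", "a"))
})

test_that("letter sharing matches the brute-force pairwise significance matrix", {
  set.seed(53)
  for (i in 1:60) {
    k <- sample(3:6, 1); n <- sample(3:4, 1)
    means <- rnorm(k, 10, sample(c(0.5, 2, 5), 1))
    sds <- runif(k, 0.3, 2)
    lets <- tukey_letters(means, sds, n, labels = paste0("G", 1:k))
    # oracle: direct pairwise Tukey HSD decisions
    MSW <- mean(sds^2)
    crit <- qtukey(0.95, k, k * (n - 1)) * sqrt(MSW / n)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      sig <- abs(means[a] - means[b]) > crit
      share <- length(intersect(strsplit(lets[a], "")[[1]],
                                strsplit(lets[b], "")[[1]])) > 0
      expect_identical(share, !sig)
    }
  }
})

test_that("LSD letters are at least as separating as Tukey letters", {
  set.seed(59)
  means <- c(10, 11.5, 13, 14.5, 20); sds <- rep(1, 5)
  tk <- tukey_letters(means, sds, n = 3, method = "tukey")
  ls <- tukey_letters(means, sds, n = 3, method = "lsd")
  n_classes <- function(x) length(unique(unlist(strsplit(x, ""))))
  expect_gte(n_classes(ls), n_classes(tk))
})

test_that("percent change reproduces the published root-trait endpoints", {
  expect_equal(round(percent_change(5.86, 4.99), 1), -14.8)
  expect_equal(round(percent_change(5.86, 3.32), 1), -43.3)
  expect_equal(round(percent_change(26.2, 21.5), 1), -17.9)
  expect_equal(round(percent_change(26.2, 12.2), 1), -53.4)
  expect_equal(percent_change(4, 4), 0)
  expect_error(percent_change(0, 1), "nonzero")
})

test_that("percent change satisfies its exchange identity and range helper", {
  set.seed(61)
  for (i in 1:50) {
    a <- runif(1, 1, 10); b <- runif(1, 1, 10)
    expect_equal(percent_change(a, b),
                 -percent_change(b, a) * (b / a), tolerance = 1e-12)
  }
  means <- c(`50%` = 4.99, `75%` = 4.92, `100%` = 3.32)
  rng <- percent_change_range(5.86, means)
  expect_equal(unname(rng), c(14.8, 43.3))
})

test_that("the normality check is calibrated and flags degeneracy", {
  set.seed(67)
  rej <- mean(vapply(1:2000, function(i) normality_check(rnorm(15))$p < 0.05,
                     logical(1)))
  expect_lt(abs(rej - 0.05), 1.96 * sqrt(0.05 * 0.95 / 2000) + 0.005)
  pow <- mean(vapply(1:100, function(i) normality_check(rexp(50))$p < 0.05,
                     logical(1)))
  expect_gt(pow, 0.9)
  expect_true(normality_check(rep(1, 10))$degenerate)
  expect_error(normality_check(c(1, 2)), "at least 3")
})
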