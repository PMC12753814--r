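test_that("univariate Gaussian association equals the correlation t-test", {
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(60)
    y <- 0.4 * x + rnorm(60)
    res <- assoc_univariate(y, x)
    ct <- cor.test(x, y)
    expect_lt(abs(log10(res$p_raw) - log10(ct$p.value)), 1e-8)
    expect_identical(res$df, 1L)
    expect_identical(res$n_used, 60L)
  }
})

test_that("univariate model flags degenerate inputs instead of crashing", {
  x <- rnorm(40)
  expect_identical(assoc_univariate(rnorm(40), rep(2, 40))$flag, "monomorphic")
  res <- assoc_univariate(x, x)       # trait equals dosage exactly
  expect_identical(res$flag, "underflow")
  expect_identical(res$p_raw, .Machine$double.xmin)
  # complete separation in a binomial fit is flagged, not an error
  yb <- as.integer(x > 0)
  res <- assoc_univariate(yb, x, family = "binomial")
  expect_identical(res$flag, "separation")
})

test_that("univariate type-I error is controlled at the nominal level", {
  set.seed(2)
  reps <- 400
  rej <- 0L
  for (i in seq_len(reps)) {
    p <- assoc_univariate(rnorm(80), rbinom(80, 2, 0.3))$p_raw
    if (!is.na(p) && p < 0.05) rej <- rej + 1L
  }
  ci <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2])
})

test_that("forward and reverse regression agree for a single Gaussian trait", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(50 + i)
    y <- 0.3 * x + rnorm(50 + i)
    pf_ <- assoc_univariate(y, x)$p_raw
    pr <- joint_reverse(x, matrix(y, dimnames = list(NULL, "y")))$p_raw
    expect_lt(abs(pf_ - pr), 1e-8)
  }
})

test_that("the joint statistic matches an explicit likelihood-ratio oracle", {
  set.seed(4)
  for (i in 1:5) {
    n <- 90
    x <- rnorm(n)
    tm <- cbind(a = 0.2 * x + rnorm(n), b = rnorm(n), c = rnorm(n))
    cov <- cbind(g = rbinom(n, 1, 0.5))
    res <- joint_reverse(x, tm, cov)
    # oracle: Gaussian ML log-likelihoods from two independent lm fits
    f1 <- lm(x ~ cov + tm)
    f0 <- lm(x ~ cov)
    lrt <- as.numeric(-2 * (logLik(f0) - logLik(f1)))
    expect_equal(res$statistic, lrt, tolerance = 1e-8)
    expect_identical(res$df, 3L)
  }
})

test_that("joint model handles collinearity, sample shortfall and constants", {
  set.seed(5)
  x <- rnorm(60)
  a <- rnorm(60)
  tm <- cbind(a = a, b = 2 * a, c = rnorm(60))   # b aliased with a
  expect_warning(res <- joint_reverse(x, tm), "collinear")
  expect_identical(res$df, 2L)
  expect_error(joint_reverse(rnorm(4), matrix(rnorm(12), 4, 3)), "too few")
  expect_identical(joint_reverse(rep(1, 30), cbind(a = rnorm(30)))$flag,
                   "monomorphic")
})

test_that("joint LRT is chi-square distributed under the null", {
  set.seed(6)
  reps <- 300
  stats <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(200)
    tm <- matrix(rnorm(200 * 4), 200, 4)
    stats[i] <- joint_reverse(x, tm)$statistic
  }
  expect_gt(ks.test(stats, pchisq, df = 4)$p.value, 0.01)
})

test_that("backward selection keeps strong traits and empties under the null", {
  set.seed(7)
  # single trait: identical to the plain joint model
  x <- rnorm(80); y <- 0.5 * x + rnorm(80)
  s1 <- joint_selection(x, cbind(y = y))
  j1 <- joint_reverse(x, cbind(y = y))
  expect_equal(s1$p_raw, j1$p_raw, tolerance = 1e-12)
  expect_identical(s1$retained, "y")

  # one strong causal trait among nulls is retained (high power regime)
  hits <- 0L
  for (i in 1:40) {
    x <- rnorm(300)
    tm <- cbind(causal = x + rnorm(300, 0, 0.5),
                n1 = rnorm(300), n2 = rnorm(300), n3 = rnorm(300),
                n4 = rnorm(300))
    s <- joint_selection(x, tm)
    if ("causal" %in% s$retained) hits <- hits + 1L
  }
  expect_gte(hits, 38L)

  # all-null traits: empty final set in the majority of replicates, p = 1
  empties <- 0L
  for (i in 1:40) {
    s <- joint_selection(rnorm(100), matrix(rnorm(400), 100, 4))
    if (length(s$retained) == 0) {
      empties <- empties + 1L
      expect_identical(s$p_raw, 1)
    }
  }
  expect_gt(empties, 20L)
})

test_that("LRR-response models mirror the dosage models", {
  coh <- make_del_cohort(n_samples = 150, af = 0.4, seed = 8)
  dm <- dosage_from_truth(coh)
  causal <- dm$count_all[, 30]
  lrr <- coh$intensities$lrr
  ph <- simulate_phenotypes(causal, trait_spec("y", beta = 1, sd = 0.3),
                            seed = 9)
  p_dos <- vapply(seq_len(ncol(lrr)), function(j)
    assoc_univariate(ph$y, dm$count_all[, j])$p_raw, numeric(1))
  p_lrr <- vapply(seq_len(ncol(lrr)), function(j)
    lrr_assoc(ph$y, lrr[, j], mode = "univariate")$p_raw, numeric(1))
  # the LRR scan localises to the same planted CNV probes (20..40)
  expect_true(which.min(p_lrr) %in% 20:40)
  expect_true(which.min(p_dos) %in% 20:40)

  res <- lrr_assoc(cbind(y = ph$y), lrr[, 30], mode = "joint")
  expect_identical(res$model, "lrr_joint")
  expect_identical(lrr_assoc(ph$y, rep(0.1, 150),
                             mode = "univariate")$flag, "monomorphic")
})

test_that("power rises with effect size and sample size", {
  set.seed(10)
  power_at <- function(n, beta, reps = 60) {
    hit <- 0L
    for (i in seq_len(reps)) {
      x <- rbinom(n, 2, 0.3)
      y <- beta * x + rnorm(n)
      if (assoc_univariate(y, x)$p_raw < 0.05) hit <- hit + 1L
    }
    hit / reps
  }
  expect_gte(power_at(200, 0.5), power_at(200, 0.1) - 0.05)
  expect_gte(power_at(400, 0.25), power_at(60, 0.25) - 0.05)
})
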