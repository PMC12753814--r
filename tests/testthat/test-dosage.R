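test_that("expected genotype reproduces the worked example and is linear", {
  expect_equal(expected_genotype(c(0, 0.8, 0.2, 0, 0)), 1.2,
               tolerance = 1e-12)
  expect_equal(expected_genotype(c(0, 0, 1, 0, 0)), 2, tolerance = 1e-15)
  expect_equal(expected_genotype(c(0.5, 0, 0, 0, 0.5)), 2, tolerance = 1e-15)

  # linearity in the posterior and range containment, over random posteriors
  set.seed(1)
  for (i in 1:50) {
    p <- rexp(5); p <- p / sum(p)
    q <- rexp(5); q <- q / sum(q)
    a <- runif(1)
    mix <- a * p + (1 - a) * q
    expect_equal(expected_genotype(mix),
                 a * expected_genotype(p) + (1 - a) * expected_genotype(q),
                 tolerance = 1e-12)
    v <- expected_genotype(p)
    expect_gte(v, 0); expect_lte(v, 4)
  }
  expect_error(expected_genotype(c(-0.1, 0.6, 0.5, 0, 0)), "negative")
  expect_error(expected_genotype(c(0.3, 0.3, 0, 0, 0)), "sum to 1")
})

test_that("stratification thresholds are applied as printed", {
  expect_identical(stratify(1.2), "deletion")
  expect_identical(stratify(2.0), "neutral")
  expect_identical(stratify(2.6), "duplication")
  expect_identical(stratify(c(1.7, 2.5)), c("neutral", "neutral"))
  expect_error(stratify(4.2), "\\[0, 4\\]")
})

test_that("stratify of expected genotypes recovers planted classes at zero noise", {
  coh <- make_del_cohort(n_samples = 30, af = 0.5, seed = 2,
                         lrr_sd = 0, baf_sd = 0)
  post <- cnv_call(coh$intensities, emission_model(lrr_var = 0.01))
  dm <- dosage_matrix(post)
  cls <- matrix(stratify(dm$count_all), nrow(dm$count_all))
  truth_cls <- ifelse(coh$true_copy_numbers < 2, "deletion",
                      ifelse(coh$true_copy_numbers > 2, "duplication",
                             "neutral"))
  expect_identical(cls, unname(truth_cls))
})

test_that("certainty filtering masks probes by average certainty", {
  coh <- make_del_cohort(n_samples = 20, seed = 3)
  dm <- dosage_matrix(cnv_call(coh$intensities,
                               emission_model(lrr_var = 0.04)))
  all_sure <- dm
  all_sure$certainty[] <- 1
  expect_false(any(certainty_filter(all_sure)$masked))

  one_low <- dm
  one_low$certainty[] <- 1
  one_low$certainty[, 5] <- 0.4
  m <- certainty_filter(one_low)$masked
  expect_true(m[5]); expect_identical(sum(m), 1L)

  expect_false(any(certainty_filter(dm, min_certainty = 0)$masked))
})

test_that("CNV allele frequencies follow the carrier-counting formula", {
  expect_identical(cnv_maf(rep(2, 100)), 0)
  # 47 heterozygous-deletion carriers among 100: (2*0 + 47) / 200 = 0.235
  expect_identical(cnv_maf(c(rep(1, 47), rep(2, 53))), 0.235)
  # full-frequency homozygous deletion folds to 0
  expect_identical(cnv_maf(rep(0, 40)), 0)
  # brute-force check of the folding rule on random class mixes
  set.seed(4)
  for (i in 1:20) {
    cls <- sample(0:4, 60, replace = TRUE, prob = c(1, 2, 10, 2, 1))
    del <- (2 * sum(cls == 0) + sum(cls == 1)) / 120
    dup <- (2 * sum(cls == 4) + sum(cls == 3)) / 120
    oracle <- max(min(del, 1 - del), min(dup, 1 - dup))
    expect_equal(cnv_maf(cls), oracle, tolerance = 1e-12)
  }
  expect_true(is.na(cnv_maf(rep(NA_real_, 5))))
})

test_that("MAF of a planted locus converges to the configured frequency", {
  for (s in 1:4) {
    coh <- make_del_cohort(n_samples = 300, af = 0.3, seed = 100 + s)
    dm <- dosage_from_truth(coh)
    se <- sqrt(0.3 * 0.7 / 600)
    expect_lt(abs(dm$maf[30] - 0.3), 3 * se)
  }
})

test_that("deletion-only and duplication-only dosages renormalise correctly", {
  post <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  gamma <- array(post, dim = c(1, 1, 5))
  cp <- structure(list(gamma = gamma,
                       viterbi_path = matrix(2L, 1, 1),
                       loglik_trace = numeric(0),
                       probe_map = make_probe_map(1),
                       samples = "S0001"),
                  class = "cnv_posterior")
  dm <- dosage_matrix(cp)
  expect_equal(dm$count_all[1, 1], sum(post * 0:4))
  expect_equal(dm$state0_dosage[1, 1],
               sum(post[1:3] * 0:2) / sum(post[1:3]))
  expect_equal(dm$state2_dosage[1, 1],
               sum(post[3:5] * 2:4) / sum(post[3:5]))
  expect_equal(dm$certainty[1, 1], 0.4)
})

test_that("dosage tables round-trip through TSV with a per-probe summary", {
  coh <- make_del_cohort(n_samples = 15, seed = 5)
  dm <- certainty_filter(dosage_matrix(cnv_call(coh$intensities,
                                                emission_model(lrr_var = 0.04))))
  path <- tempfile(fileext = ".tsv")
  summ <- write_dosage(dm, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".summary.tsv")))
  back <- read.delim(path)
  expect_equal(unname(as.matrix(back[, -1])), unname(t(dm$count_all)),
               tolerance = 1e-9)
  expect_identical(nrow(summ), ncol(dm$count_all))
})
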