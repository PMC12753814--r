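test_that("planted allele frequencies are realized within binomial error", {
  coh <- make_del_cohort(n_samples = 620, af = 0.47, seed = 101)
  se <- sqrt(0.47 * 0.53 / (2 * 620))
  expect_lt(abs(realized_allele_freq(coh) - 0.47), 3 * se)

  # coverage across seeds for a rarer allele
  for (s in 1:5) {
    coh <- make_del_cohort(n_samples = 400, af = 0.1, seed = s)
    se <- sqrt(0.1 * 0.9 / (2 * 400))
    expect_lt(abs(realized_allele_freq(coh) - 0.1), 4 * se)
  }
})

test_that("zero-noise LRR equals the copy-state cluster means exactly", {
  coh <- make_del_cohort(n_samples = 40, af = 0.5, seed = 2,
                         lrr_sd = 0, baf_sd = 0, gc_slope = 0,
                         wave_amplitude = 0)
  means <- c(-4.5, -0.3, 0, 0.305, 0.528)
  expected <- matrix(means[coh$true_copy_numbers + 1L],
                     nrow(coh$true_copy_numbers))
  expect_lt(max(abs(coh$intensities$lrr - expected)), 1e-12)
})

test_that("cohorts are bit-identical under a fixed seed and valid throughout", {
  a <- make_del_cohort(seed = 7)
  b <- make_del_cohort(seed = 7)
  expect_identical(a$intensities$lrr, b$intensities$lrr)
  expect_identical(a$intensities$baf, b$intensities$baf)
  expect_identical(a$true_copy_numbers, b$true_copy_numbers)

  for (s in 1:4) {
    coh <- make_del_cohort(n_samples = 30, seed = s)
    expect_true(all(coh$true_copy_numbers %in% 0:4))
    expect_true(all(is.finite(coh$intensities$lrr)))
    expect_true(all(coh$intensities$baf >= 0 & coh$intensities$baf <= 1))
  }
})

test_that("a locus outside the probe map is rejected by name", {
  pm <- make_probe_map(20)
  loci <- cnv_locus("chr9", 1e6, 2e6, "deletion", 0.2)
  expect_error(simulate_cohort(cohort_config(10, pm, loci, seed = 1)),
               "chr9:1000000-2000000")
  expect_error(cnv_locus("chr1", 100, 200, "deletion", 1.3), "allele_freq")
})

test_that("phenotype generator honours the stated effect and noise model", {
  dosage <- rep(0:4, each = 80)
  # null slope
  ph <- simulate_phenotypes(dosage, trait_spec("y", beta = 0), seed = 3)
  fit <- summary(lm(ph$y ~ dosage))$coefficients
  expect_lt(abs(fit["dosage", "Estimate"]), 3 * fit["dosage", "Std. Error"])
  # exact linear response at zero noise
  ph <- simulate_phenotypes(dosage, trait_spec("y", beta = 1, intercept = 2,
                                               sd = 0), seed = 3)
  expect_equal(ph$y, 2 + dosage, tolerance = 1e-12)
  # count trait moment at dosage 2: mean = exp(intercept + 0.5 * 2)
  d2 <- rep(2, 4000)
  ph <- simulate_phenotypes(d2, trait_spec("k", "count", beta = 0.5,
                                           intercept = 0.3), seed = 4)
  mu <- exp(0.3 + 1)
  expect_lt(abs(mean(ph$k) - mu), 3 * sqrt(mu / 4000))
})

test_that("correlated trait blocks follow the stated correlation matrix", {
  dosage <- rnorm(4000)
  R <- matrix(c(1, 0.7, 0.7, 1), 2)
  ph <- simulate_phenotypes(dosage,
                            list(trait_spec("a"), trait_spec("b")),
                            trait_cor = R, seed = 5)
  expect_lt(abs(cor(ph$a, ph$b) - 0.7), 0.05)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_phenotypes(dosage,
                                   list(trait_spec("a"), trait_spec("b")),
                                   trait_cor = bad, seed = 5),
               "positive definite")
})

test_that("expression generator: exact collinearity at zero noise and null uniformity", {
  n <- 60
  dos <- matrix(sample(0:4, n, replace = TRUE), n, 1,
                dimnames = list(sprintf("S%04d", 1:n), "cnvA"))
  ann <- data.frame(probe_id = c("e1", "e2"), gene = c("G1", "G2"))
  eff <- data.frame(cnv_probe = "cnvA", expr_probe = "e1", gamma = 2)
  ep <- simulate_expression(dos, ann, eff, noise_sd = 0, seed = 6)
  expect_equal(unname(ep$regions$region1["e1", ]),
               unname(8 + 2 * dos[, 1]), tolerance = 1e-12)
  expect_error(simulate_expression(dos, ann,
                                   data.frame(cnv_probe = "cnvA",
                                              expr_probe = "nope",
                                              gamma = 1), seed = 1),
               "nope")

  # with gamma = 0 everywhere, per-pair association p is uniform
  set.seed(7)
  n <- 50; npairs <- 500
  dmat <- matrix(rbinom(n * npairs, 2, 0.3), n, npairs,
                 dimnames = list(sprintf("S%04d", 1:n),
                                 sprintf("c%03d", 1:npairs)))
  ann <- data.frame(probe_id = sprintf("e%03d", 1:npairs),
                    gene = sprintf("G%03d", 1:npairs))
  ep <- simulate_expression(dmat, ann, NULL, noise_sd = 1, seed = 8)
  em <- ep$regions$region1
  ps <- vapply(seq_len(npairs), function(i)
    assoc_univariate(em[i, ], dmat[, i])$p_raw, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("methylation generator seeds region means and anti-phase groups", {
  pos <- seq(1000, by = 100, length.out = 50)
  tr <- simulate_methylation(pos, n_samples = 1, base_meth = 1000,
                             seed = 9)
  rm <- region_mean_counts(tr, data.frame(name = "r", chrom = "chr1",
                                          start = 1000, end = 6000))
  expect_equal(rm$mean_meth, 1000)

  # zero amplitude: no periodic structure at the would-be period
  flat <- simulate_methylation(pos, n_samples = 1, base_meth = 100,
                               wave_amplitude = 0, wave_period = 1000,
                               seed = 10)
  ws <- wave_score(flat)
  expect_lt(ws$amplitude, 1e-9)

  # opposite-phase groups anti-correlate at zero noise
  pos2 <- seq(1000, by = 100, length.out = 200)
  tr2 <- simulate_methylation(pos2, n_samples = 6, base_meth = 500,
                              wave_amplitude = 200, wave_period = 4000,
                              flip_fraction = 0.5, seed = 11)
  flipped <- unique(tr2$sample[tr2$flipped])
  ref <- setdiff(unique(tr2$sample), flipped)
  g <- group_mean_tracks(tr2, flipped, ref)
  expect_lt(g$correlation, -0.8)
})
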