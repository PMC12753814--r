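test_that("emission log-densities follow the stated Gaussian + mixture form", {
  em <- emission_model()  # nine clusters, variance at the 0.25 ceiling
  # LRR exactly at a cluster mean: Gaussian term is -log(2*pi*var)/2
  ll <- emission_loglik(em$cluster_means[3], NA, 3, em)
  expect_equal(ll, -0.5 * log(2 * pi * 0.25), tolerance = 1e-12)

  # diploid cluster: BAF mixture symmetric about 0.5
  dip <- which(em$copies == 2L)
  d <- 0.13
  expect_equal(emission_loglik(0, 0.5 + d, dip, em),
               emission_loglik(0, 0.5 - d, dip, em), tolerance = 1e-12)

  # copy-0 cluster: BAF term independent of baf (uniform component)
  expect_equal(emission_loglik(-4.5, 0.11, 1, em),
               emission_loglik(-4.5, 0.93, 1, em), tolerance = 1e-12)

  expect_error(emission_loglik(Inf, 0.5, 3, em), "non-finite")
  expect_error(emission_loglik(0, 0.5, 99, em), "cluster")
})

test_that("forward-backward equals exhaustive path enumeration", {
  em <- make_em5()
  tr <- transition_model(stay_prob = 0.9)
  set.seed(11)
  for (rep in 1:3) {
    lrr <- rnorm(6, 0, 1)
    baf <- runif(6)
    fb <- forward_backward(lrr, baf, 1:6, em, tr)
    oracle <- enumerate_posterior(lrr, baf, em, tr)
    expect_lt(max(abs(fb$gamma - oracle$gamma)), 1e-9)
    expect_lt(abs(fb$loglik - oracle$loglik), 1e-8)
    expect_lt(abs(fb$loglik - fb$loglik_backward), 1e-8)
    expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-9)
  }
})

test_that("degenerate chains behave analytically", {
  # emissions identical across states: posterior is the stationary law
  em <- emission_model(cluster_means = c(-1, 0, 1), lrr_var = 0.25,
                       baf_sd = 0.05, state_map = 1:3, copies = 1:3)
  tr <- transition_model(stay_prob = 0.8)
  fb <- forward_backward(rep(NA_real_, 10), rep(NA_real_, 10), 1:10, em, tr)
  Tm <- transition_matrix(tr, em)
  statn <- cnvdosage:::.stationary(Tm)
  expect_lt(max(abs(sweep(fb$gamma, 2, statn))), 1e-10)

  # single probe: posterior proportional to prior times emission likelihood
  em5 <- make_em5()
  fb1 <- forward_backward(-0.2, 0.5, 1, em5, tr)
  lik <- exp(vapply(1:5, function(k) emission_loglik(-0.2, 0.5, k, em5),
                    numeric(1)))
  statn5 <- cnvdosage:::.stationary(transition_matrix(tr, em5))
  expect_equal(as.vector(fb1$gamma), statn5 * lik / sum(statn5 * lik),
               tolerance = 1e-10)
})

test_that("viterbi recovers planted segments exactly at zero noise", {
  coh <- make_del_cohort(n_samples = 20, n_probes = 80, from = 30, to = 49,
                         af = 0.5, seed = 21, lrr_sd = 0, baf_sd = 0)
  pm <- coh$intensities$probe_map
  em <- emission_model(lrr_var = 0.01)
  het <- which(apply(coh$true_copy_numbers, 1,
                     function(x) any(x == 1) && all(x >= 1)))[1]
  segs <- viterbi_segments(coh$intensities$lrr[het, ],
                           coh$intensities$baf[het, ], pm, em)
  del <- segs[segs$copy_number == 1, ]
  expect_identical(nrow(del), 1L)
  expect_identical(del$start, pm$pos[30])
  expect_identical(del$end, pm$pos[49])
  expect_identical(del$n_probes, 20L)

  # all-diploid sample: no non-diploid segments
  dip <- which(apply(coh$true_copy_numbers, 1, function(x) all(x == 2)))[1]
  segs <- viterbi_segments(coh$intensities$lrr[dip, ],
                           coh$intensities$baf[dip, ], pm, em)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$copy_number, 2L)
})

test_that("two well-separated planted CNVs give exactly two segments", {
  pm <- make_probe_map(150)
  loci <- rbind(cnv_locus("chr1", pm$pos[20], pm$pos[35], "deletion", 0.5),
                cnv_locus("chr1", pm$pos[110], pm$pos[130], "duplication", 0.5))
  coh <- simulate_cohort(cohort_config(30, pm, loci, seed = 22,
                                       lrr_sd = 0, baf_sd = 0))
  s <- which(coh$true_copy_numbers[, 25] == 1 &
               coh$true_copy_numbers[, 120] == 3)[1]
  segs <- viterbi_segments(coh$intensities$lrr[s, ],
                           coh$intensities$baf[s, ], pm,
                           emission_model(lrr_var = 0.01))
  expect_identical(sum(segs$copy_number != 2), 2L)
  expect_identical(segs$copy_number[segs$start == pm$pos[20]], 1L)
  expect_identical(segs$copy_number[segs$start == pm$pos[110]], 3L)
})

test_that("EM raises the likelihood monotonically and recovers the variance", {
  coh <- make_del_cohort(n_samples = 60, n_probes = 80, seed = 23,
                         lrr_sd = 0.2)
  fit <- em_fit(coh$intensities, init = emission_model(lrr_var = 0.08),
                iters = 6)
  expect_true(all(diff(fit$posterior$loglik_trace) > -1e-6))
  expect_lt(abs(fit$emission$lrr_var - 0.04), 0.1 * 0.04)

  # posterior tensor normalised everywhere
  sums <- apply(fit$posterior$gamma, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)

  # init at the generative parameters: one pass leaves them in place
  fit2 <- em_fit(coh$intensities, init = emission_model(lrr_var = 0.04),
                 iters = 3)
  expect_lt(abs(fit2$emission$lrr_var - 0.04), 0.1 * 0.04)
  expect_identical(fit2$emission$cluster_means,
                   emission_model()$cluster_means)
  expect_error(em_fit(coh$intensities, iters = 0), "iters")
})

test_that("joint multi-cohort calling shares one emission model", {
  pm <- make_probe_map(60)
  loci <- cnv_locus("chr1", pm$pos[20], pm$pos[40], "deletion", 0.4)
  p1 <- simulate_cohort(cohort_config(100, pm, loci, seed = 31))$intensities
  p2 <- simulate_cohort(cohort_config(100, pm, loci, seed = 32))$intensities
  jc <- joint_call(list(a = p1, b = p2), reference_cohort = "a", iters = 4)
  expect_named(jc$posteriors, c("a", "b"))
  # same generative truth: per-probe mean posteriors agree between cohorts
  ma <- apply(jc$posteriors$a$gamma, c(2, 3), mean)
  mb <- apply(jc$posteriors$b$gamma, c(2, 3), mean)
  expect_lt(max(abs(ma - mb)), 0.2)

  # single cohort: same result as em_fit
  jc1 <- joint_call(list(a = p1), iters = 3)
  direct <- em_fit(p1, iters = 3)
  expect_equal(jc1$posteriors$a$gamma, direct$posterior$gamma,
               tolerance = 1e-12)

  # disjoint probe sets are an error
  pm2 <- make_probe_map(30, start = 9e6)
  p3 <- simulate_cohort(cohort_config(10, pm2, NULL, seed = 33))$intensities
  expect_error(joint_call(list(a = p1, b = p3)), "intersection")
})

test_that("segments export as 0-based half-open BED rows", {
  coh <- make_del_cohort(n_samples = 5, n_probes = 40, from = 10, to = 25,
                         af = 0.8, seed = 41, lrr_sd = 0.05, baf_sd = 0.02)
  fit <- em_fit(coh$intensities, init = emission_model(lrr_var = 0.01),
                iters = 2)
  path <- tempfile(fileext = ".bed")
  out <- write_segments(fit$posterior, path)
  expect_true(file.exists(path))
  pm <- coh$intensities$probe_map
  expect_true(all(out$start %in% (pm$pos - 1L)))
  expect_true(all(out$end %in% pm$pos))
})
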