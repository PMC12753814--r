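# shared fixtures: everything is built in code at test time

# evenly spaced single-chromosome probe map
make_probe_map <- function(n = 60, chrom = "chr1", spacing = 2000,
                           start = 1e5, gc = 0.4, pbaf = 0.5) {
  pos <- seq(start, by = spacing, length.out = n)
  probe_map(sprintf("%s_p%04d", chrom, seq_len(n)), chrom, pos,
            gc = gc, population_baf = pbaf)
}

# cohort with one planted deletion spanning probes [from, to]
make_del_cohort <- function(n_samples = 100, n_probes = 60,
                            from = max(2, round(n_probes / 3)),
                            to = min(n_probes - 1, round(2 * n_probes / 3)),
                            af = 0.3, seed = 1, ...) {
  pm <- make_probe_map(n_probes)
  loci <- cnv_locus("chr1", pm$pos[from], pm$pos[to], "deletion", af)
  simulate_cohort(cohort_config(n_samples, pm, loci, seed = seed, ...))
}

# five-state emission model (one cluster per copy class) for oracle tests
make_em5 <- function(lrr_var = 0.2, baf_sd = 0.05) {
  emission_model(cluster_means = c(-4.5, -0.3, 0, 0.305, 0.528),
                 lrr_var = lrr_var, baf_sd = baf_sd,
                 state_map = 0:4, copies = 0:4)
}

# exhaustive path-sum posterior and log-likelihood (oracle for
# forward_backward); feasible only for a handful of probes
enumerate_posterior <- function(lrr, baf, emission, transition) {
  p <- length(lrr)
  K <- length(emission$cluster_means)
  Tm <- transition_matrix(transition, emission)
  init <- cnvdosage:::.stationary(Tm)
  logE <- sapply(seq_len(K), function(k)
    sapply(seq_len(p), function(t) emission_loglik(lrr[t], baf[t], k, emission)))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), p)))
  lp <- apply(paths, 1, function(s) {
    v <- log(init[s[1]]) + logE[1, s[1]]
    for (t in seq_len(p)[-1]) v <- v + log(Tm[s[t - 1], s[t]]) + logE[t, s[t]]
    v
  })
  mx <- max(lp)
  w <- exp(lp - mx)
  post <- sapply(seq_len(K), function(k)
    sapply(seq_len(p), function(t) sum(w[paths[, t] == k])))
  list(gamma = post / sum(w), loglik = mx + log(sum(w)))
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# planted two-block non-negative matrix: rows 1..b1 high in samples group 1,
# remaining rows high in group 2
make_block_matrix <- function(b1 = 15, b2 = 15, s1 = 10, s2 = 10,
                              hi = 10, lo = 0.1, noise = 0, seed = 1) {
  p <- b1 + b2; n <- s1 + s2
  X <- matrix(lo, p, n)
  X[seq_len(b1), seq_len(s1)] <- hi
  X[(b1 + 1):p, (s1 + 1):n] <- hi
  if (noise > 0) {
    set.seed(seed)
    X <- pmax(X + matrix(rnorm(p * n, 0, noise), p, n), 0)
  }
  rownames(X) <- sprintf("probe%03d", seq_len(p))
  colnames(X) <- sprintf("S%03d", seq_len(n))
  X
}
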