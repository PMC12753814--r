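#' Specification of one simulated trait
#'
#' Describes how a phenotype responds to CNV dosage. Quantitative traits are
#' `intercept + beta * dosage + Gaussian noise`; binary traits use a logit
#' link; count traits use a log link with negative-binomial dispersion
#' (`dispersion = Inf` gives Poisson counts).
#'
#' @param name Trait name.
#' @param type `"quantitative"`, `"binary"` or `"count"`.
#' @param beta Effect of one dosage unit on the linear predictor.
#' @param intercept Linear-predictor intercept.
#' @param sd Residual standard deviation (quantitative traits).
#' @param dispersion Negative-binomial size parameter (count traits).
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(name, type = c("quantitative", "binary", "count"),
                       beta = 0, intercept = 0, sd = 1, dispersion = Inf) {
  type <- match.arg(type)
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  structure(list(name = name, type = type, beta = beta,
                 intercept = intercept, sd = sd, dispersion = dispersion),
            class = "trait_spec")
}

#' Simulate phenotypes linked to a CNV dosage vector
#'
#' Generates one column per [trait_spec()]. The Gaussian noise of
#' quantitative traits may be correlated across traits through
#' `trait_cor` (a correlation matrix over the quantitative traits, applied
#' via its Cholesky factor); binary and count traits are conditionally
#' independent given dosage.
#'
#' @param dosage Numeric dosage vector, one entry per sample.
#' @param traits List of [trait_spec()] objects.
#' @param trait_cor Optional correlation matrix for the quantitative traits'
#'   noise (order = order of quantitative traits in `traits`). Must be
#'   positive definite.
#' @param seed Integer seed.
#' @return A `data.frame` with `sample` plus one column per trait.
#' @export
simulate_phenotypes <- function(dosage, traits, trait_cor = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  n <- length(dosage)
  types <- vapply(traits, `[[`, character(1), "type")
  qidx <- which(types == "quantitative")

  L <- NULL
  if (!is.null(trait_cor)) {
    if (!isSymmetric(unname(trait_cor)) || nrow(trait_cor) != length(qidx))
      stop("trait_cor must be symmetric with one row per quantitative trait",
           call. = FALSE)
    L <- tryCatch(chol(trait_cor), error = function(e)
      stop("trait_cor must be positive definite", call. = FALSE))
  }

  with_seed(seed, {
    out <- data.frame(sample = if (is.null(names(dosage)))
      sprintf("S%04d", seq_len(n)) else names(dosage))
    qnoise <- NULL
    if (length(qidx)) {
      z <- matrix(stats::rnorm(n * length(qidx)), n, length(qidx))
      qnoise <- if (is.null(L)) z else z %*% L
    }
    qi <- 0L
    for (tr in traits) {
      eta <- tr$intercept + tr$beta * dosage
      out[[tr$name]] <- switch(tr$type,
        quantitative = {
          qi <- qi + 1L
          eta + tr$sd * qnoise[, qi]
        },
        binary = stats::rbinom(n, 1L, stats::plogis(eta)),
        count = if (is.finite(tr$dispersion))
          stats::rnbinom(n, size = tr$dispersion, mu = exp(eta))
        else stats::rpois(n, exp(eta)))
    }
    out
  })
}

#' Simulate cis-regulated expression panels across tissue regions
#'
#' Each expression probe's value is `baseline + gamma * dosage + noise`,
#' drawn independently per region (the cis effect itself is common to all
#' regions; with `share_noise = TRUE` the noise realisation is shared too).
#' Reciprocal designs — dosage of gene A driving expression of gene B and
#' vice versa — are expressed simply as two rows of `cis_effects`.
#'
#' @param dosage Sample x CNV-probe dosage matrix with probe-id column names.
#' @param expr_probes Annotation of expression probes: `data.frame` with at
#'   least `probe_id` and `gene` (optionally `chrom`, `start`, `end`).
#' @param cis_effects `data.frame(cnv_probe, expr_probe, gamma)`; probes not
#'   named here get `gamma = 0`.
#' @param regions Character vector of region labels.
#' @param baseline Baseline expression level.
#' @param noise_sd Residual standard deviation.
#' @param share_noise If `TRUE`, one noise draw is reused in every region.
#' @param seed Integer seed.
#' @return A list of class `expression_panel`: `regions` (named list of
#'   probe x sample matrices) and `annotation`.
#' @export
simulate_expression <- function(dosage, expr_probes, cis_effects = NULL,
                                regions = "region1", baseline = 8,
                                noise_sd = 1, share_noise = FALSE, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(is.matrix(dosage), !is.null(colnames(dosage)))
  n <- nrow(dosage)
  pids <- expr_probes$probe_id
  if (!is.null(cis_effects) && nrow(cis_effects)) {
    bad <- setdiff(cis_effects$expr_probe, pids)
    if (length(bad))
      stop(sprintf("unknown expression probe id(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    bad <- setdiff(cis_effects$cnv_probe, colnames(dosage))
    if (length(bad))
      stop(sprintf("unknown CNV probe id(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }

  # per expression probe, the summed cis contribution across its effect rows
  signal <- matrix(0, n, length(pids), dimnames = list(rownames(dosage), pids))
  if (!is.null(cis_effects)) {
    for (i in seq_len(nrow(cis_effects))) {
      ep <- cis_effects$expr_probe[i]
      signal[, ep] <- signal[, ep] +
        cis_effects$gamma[i] * dosage[, cis_effects$cnv_probe[i]]
    }
  }

  with_seed(seed, {
    shared <- if (share_noise)
      matrix(stats::rnorm(n * length(pids), 0, noise_sd), n, length(pids))
    mats <- lapply(regions, function(r) {
      noise <- if (share_noise) shared else
        matrix(stats::rnorm(n * length(pids), 0, noise_sd), n, length(pids))
      t(baseline + signal + noise)  # probe x sample
    })
    names(mats) <- regions
    for (r in regions) {
      rownames(mats[[r]]) <- pids
      colnames(mats[[r]]) <- rownames(dosage)
    }
    structure(list(regions = mats, annotation = expr_probes),
              class = "expression_panel")
  })
}

#' Simulate bisulfite methylation tracks with periodic waves
#'
#' Emits per-position methylated/unmethylated read counts along a probe
#' grid. The methylated mean follows a per-region baseline plus a sinusoid
#' of the stated amplitude and period; a configurable fraction of samples
#' carries the wave phase-inverted (anti-phase), emulating groups whose
#' methylation waves flip in the opposite direction. With
#' `count_noise = "none"` counts equal the rounded means exactly; with
#' `"poisson"` they are Poisson draws around them.
#'
#' @param positions Integer positions (1-based, sorted) on one chromosome.
#' @param chrom Chromosome label.
#' @param n_samples Number of sample tracks.
#' @param base_meth,base_unmeth Baseline mean read counts.
#' @param regions Optional `data.frame(start, end, meth_mean)` overriding the
#'   methylated baseline inside each region.
#' @param wave_amplitude,wave_period Sinusoid amplitude (reads) and period (bp).
#' @param flip_fraction Fraction of samples with inverted wave phase.
#' @param count_noise `"none"` or `"poisson"`.
#' @param seed Integer seed.
#' @return A `data.frame` of class `methylation_track` with columns `sample`,
#'   `chrom`, `pos`, `meth`, `unmeth`, `flipped`.
#' @export
simulate_methylation <- function(positions, chrom = "chr1", n_samples = 1,
                                 base_meth = 30, base_unmeth = 60,
                                 regions = NULL, wave_amplitude = 0,
                                 wave_period = 1e4, flip_fraction = 0,
                                 count_noise = c("none", "poisson"), seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  count_noise <- match.arg(count_noise)
  check_fraction(flip_fraction, "flip_fraction")
  if (base_meth < 0 || base_unmeth < 0)
    stop("baseline counts must be non-negative", call. = FALSE)
  npos <- length(positions)

  level <- rep(base_meth, npos)
  if (!is.null(regions)) {
    for (i in seq_len(nrow(regions)))
      level[positions >= regions$start[i] & positions <= regions$end[i]] <-
        regions$meth_mean[i]
  }
  wave <- wave_amplitude * sin(2 * pi * positions / wave_period)

  with_seed(seed, {
    n_flip <- round(flip_fraction * n_samples)
    flipped <- seq_len(n_samples) <= n_flip
    tracks <- lapply(seq_len(n_samples), function(s) {
      mu <- pmax(level + if (flipped[s]) -wave else wave, 0)
      meth <- if (count_noise == "poisson") stats::rpois(npos, mu)
      else as.integer(round(mu))
      unmeth <- if (count_noise == "poisson") stats::rpois(npos, base_unmeth)
      else as.integer(round(rep(base_unmeth, npos)))
      data.frame(sample = sprintf("S%04d", s), chrom = chrom,
                 pos = as.integer(positions), meth = meth, unmeth = unmeth,
                 flipped = flipped[s])
    })
    out <- do.call(rbind, tracks)
    class(out) <- c("methylation_track", "data.frame")
    out
  })
}
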