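# Scaled forward-backward over one chromosome block for a batch of samples.
# lrr/baf: n x p matrices; returns gamma (n x p x K), per-sample loglik from
# the forward pass and an independently scaled backward pass (the two agree
# to numerical precision). Scaling with per-probe log normalisers is
# algebraically identical to log-space recursion and underflow-free for
# arbitrarily long chromosomes.
.fb_batch <- function(lrr, baf, pos, emission, transition, logE = NULL) {
  n <- nrow(lrr); p <- ncol(lrr); K <- length(emission$cluster_means)
  if (is.null(logE)) logE <- .emission_array(lrr, baf, emission)
  Tm <- transition_matrix(transition, emission)
  use_dist <- !is.null(transition$distance_scale)
  Tlist <- if (use_dist && p > 1)
    lapply(diff(pos), function(d) transition_matrix(transition, emission, d))
  init <- .stationary(Tm)

  shift <- apply(logE, c(1, 2), max)
  if (any(!is.finite(shift)))
    stop(sprintf("zero-probability observation at probe %d",
                 which(!is.finite(shift), arr.ind = TRUE)[1, 2]), call. = FALSE)
  E <- exp(logE - as.vector(shift))  # recycles shift over clusters

  alpha <- array(0, dim = c(n, p, K))
  loglik <- numeric(n)
  a <- matrix(init, n, K, byrow = TRUE) * E[, 1, ]
  cs <- rowSums(a)
  if (any(cs == 0))
    stop("zero-probability observation at probe 1", call. = FALSE)
  alpha[, 1, ] <- a / cs
  loglik <- log(cs) + shift[, 1]
  for (t in seq_len(p)[-1]) {
    Tt <- if (use_dist) Tlist[[t - 1]] else Tm
    a <- (alpha[, t - 1, ] %*% Tt) * E[, t, ]
    cs <- rowSums(a)
    if (any(cs == 0))
      stop(sprintf("zero-probability observation at probe %d", t), call. = FALSE)
    alpha[, t, ] <- a / cs
    loglik <- loglik + log(cs) + shift[, t]
  }

  gamma <- array(0, dim = c(n, p, K))
  b <- matrix(1, n, K)
  g <- alpha[, p, ] * b
  gamma[, p, ] <- g / rowSums(g)
  loglik_b <- numeric(n)
  bb <- matrix(1, n, K)
  for (t in rev(seq_len(p)[-1])) {
    Tt <- if (use_dist) Tlist[[t - 1]] else Tm
    b <- (E[, t, ] * b) %*% t(Tt)
    b <- b / rowSums(b)                      # forward-independent rescale
    g <- alpha[, t - 1, ] * b
    gamma[, t - 1, ] <- g / rowSums(g)
    tmp <- (E[, t, ] * bb) %*% t(Tt)
    ds <- rowSums(tmp)
    bb <- tmp / ds
    loglik_b <- loglik_b + log(ds) + shift[, t]
  }
  loglik_b <- loglik_b +
    log(rowSums(matrix(init, n, K, byrow = TRUE) * E[, 1, ] * bb)) + shift[, 1]

  list(gamma = gamma, loglik = loglik, loglik_backward = loglik_b)
}

# Batch Viterbi over one chromosome block; returns n x p cluster indices.
# Ties broken toward the lowest cluster index, i.e. the lowest copy number
# under the (non-decreasing) default state map.
.viterbi_batch <- function(lrr, baf, pos, emission, transition, logE = NULL) {
  n <- nrow(lrr); p <- ncol(lrr); K <- length(emission$cluster_means)
  if (is.null(logE)) logE <- .emission_array(lrr, baf, emission)
  Tm <- transition_matrix(transition, emission)
  use_dist <- !is.null(transition$distance_scale)
  logT <- log(Tm)
  init <- log(.stationary(Tm))

  delta <- matrix(init, n, K, byrow = TRUE) + logE[, 1, ]
  psi <- array(1L, dim = c(p, n, K))
  for (t in seq_len(p)[-1]) {
    lT <- if (use_dist)
      log(transition_matrix(transition, emission, pos[t] - pos[t - 1])) else logT
    new_delta <- matrix(0, n, K)
    for (j in seq_len(K)) {
      cand <- delta + matrix(lT[, j], n, K, byrow = TRUE)
      best <- max.col(cand, ties.method = "first")
      psi[t, , j] <- best
      new_delta[, j] <- cand[cbind(seq_len(n), best)] + logE[, t, j]
    }
    delta <- new_delta
  }
  path <- matrix(0L, n, p)
  path[, p] <- max.col(delta, ties.method = "first")
  for (t in rev(seq_len(p)[-1]))
    path[, t - 1] <- psi[cbind(t, seq_len(n), path[, t])]
  path
}

#' Posterior state probabilities for one sample's observations
#'
#' Runs the scaled forward-backward algorithm over position-sorted
#' observations and returns the per-probe posterior over emission clusters
#' together with the data log-likelihood (computed independently by the
#' forward and backward passes).
#'
#' @param lrr,baf Numeric observation vectors (`NA` = missing).
#' @param pos Base-pair positions, sorted increasing.
#' @param emission An [emission_model()].
#' @param transition A [transition_model()].
#' @return A list with `gamma` (probe x cluster posterior matrix, rows sum
#'   to 1), `loglik` and `loglik_backward`.
#' @export
forward_backward <- function(lrr, baf = NULL, pos = seq_along(lrr),
                             emission, transition = transition_model()) {
  if (is.null(baf)) baf <- rep(NA_real_, length(lrr))
  if (is.unsorted(pos)) stop("observations must be position-sorted", call. = FALSE)
  fb <- .fb_batch(matrix(lrr, 1), matrix(baf, 1), pos, emission, transition)
  list(gamma = matrix(fb$gamma[1, , ], length(lrr),
                      length(emission$cluster_means)),
       loglik = fb$loglik[1], loglik_backward = fb$loglik_backward[1])
}

# merge a copy-class path into maximal constant runs
.path_to_segments <- function(classes, chrom, pos, mean_post = NULL) {
  runs <- rle(classes)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- data.frame(chrom = chrom[starts], start = pos[starts],
                    end = pos[ends], copy_number = runs$values,
                    n_probes = runs$lengths)
  if (!is.null(mean_post))
    out$mean_posterior <- vapply(seq_along(starts), function(i)
      mean(mean_post[starts[i]:ends[i]]), numeric(1))
  out
}

#' Viterbi copy-number segments for one sample
#'
#' Decodes the maximum a posteriori state path and merges it into maximal
#' runs of constant copy class. Ties in the dynamic program are broken
#' toward the lower copy number, so output is deterministic.
#'
#' @param lrr,baf Observation vectors for one sample.
#' @param probe_map A [probe_map()] aligned with the observations.
#' @param emission An [emission_model()].
#' @param transition A [transition_model()].
#' @return A `data.frame` with `chrom`, `start`, `end` (1-based inclusive),
#'   `copy_number`, `n_probes` and `mean_posterior` (mean posterior
#'   probability of the called class along the segment).
#' @export
viterbi_segments <- function(lrr, baf = NULL, probe_map, emission,
                             transition = transition_model()) {
  if (is.null(baf)) baf <- rep(NA_real_, length(lrr))
  segs <- list()
  for (ch in unique(probe_map$chrom)) {
    idx <- which(probe_map$chrom == ch)
    pos <- probe_map$pos[idx]
    lm1 <- matrix(lrr[idx], 1); bm1 <- matrix(baf[idx], 1)
    logE <- .emission_array(lm1, bm1, emission)
    path <- .viterbi_batch(lm1, bm1, pos, emission, transition, logE = logE)[1, ]
    fb <- .fb_batch(lm1, bm1, pos, emission, transition, logE = logE)
    cls <- emission$state_map[path]
    cg <- .collapse_gamma(fb$gamma, emission$state_map)
    mp <- cg[cbind(1, seq_along(idx), cls + 1L)]
    segs[[ch]] <- .path_to_segments(cls, probe_map$chrom[idx], pos, mp)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# collapse cluster-level gamma (n x p x K) to copy classes 0..4
.collapse_gamma <- function(gamma, state_map) {
  n <- dim(gamma)[1]; p <- dim(gamma)[2]
  out <- array(0, dim = c(n, p, 5L),
               dimnames = list(NULL, NULL, paste0("copy", 0:4)))
  for (c in 0:4) {
    ks <- which(state_map == c)
    if (length(ks))
      out[, , c + 1L] <- apply(gamma[, , ks, drop = FALSE], c(1, 2), sum)
  }
  out
}

# run E-step across all chromosomes of a panel; returns per-chromosome fb
# results plus bookkeeping of probe indices
.estep_panel <- function(panel, emission, transition, baf_logE = NULL) {
  pm <- panel$probe_map
  chroms <- unique(pm$chrom)
  lapply(chroms, function(ch) {
    idx <- which(pm$chrom == ch)
    logE <- .emission_array(panel$lrr[, idx, drop = FALSE],
                            panel$baf[, idx, drop = FALSE], emission)
    fb <- .fb_batch(panel$lrr[, idx, drop = FALSE],
                    panel$baf[, idx, drop = FALSE],
                    pm$pos[idx], emission, transition, logE = logE)
    fb$idx <- idx
    fb
  })
}

#' Fit the population-shared emission model by EM
#'
#' Runs expectation-maximisation over all samples of a cohort jointly: the
#' E-step is the forward-backward pass per sample per chromosome, and the
#' M-step re-estimates the shared LRR emission variance (capped at the 0.25
#' ceiling) and, optionally, the cluster means, pooling posterior weights
#' across the whole population. The population-shared emission is what
#' makes calling "population-aware": every sample's data informs the
#' cluster positions that every other sample is decoded against.
#'
#' @param panel An [intensity_panel()].
#' @param init Initial [emission_model()].
#' @param transition A [transition_model()].
#' @param iters Number of EM iterations (default 15).
#' @param update_means Also re-estimate cluster means (default `FALSE`).
#' @return A list of class `cnv_fit`: `emission` (fitted model),
#'   `transition`, and `posterior`, a `cnv_posterior` holding `gamma`
#'   (sample x probe x copy-class array), `viterbi_path` (sample x probe
#'   copy classes), `loglik_trace` (one value per EM iteration plus the
#'   final likelihood), `probe_map` and `samples`.
#' @export
em_fit <- function(panel, init = emission_model(),
                   transition = transition_model(), iters = 15L,
                   update_means = FALSE) {
  stopifnot(inherits(panel, "intensity_panel"))
  check_count(iters, "iters", min = 1)
  if (nrow(panel$lrr) == 0L) stop("empty cohort", call. = FALSE)
  emission <- init
  K <- length(emission$cluster_means)
  trace <- numeric(0)

  for (it in seq_len(iters)) {
    es <- .estep_panel(panel, emission, transition)
    trace <- c(trace, sum(vapply(es, function(x) sum(x$loglik), numeric(1))))
    num <- 0; den <- 0
    mean_num <- numeric(K); mean_den <- numeric(K)
    for (blk in es) {
      lrr <- panel$lrr[, blk$idx, drop = FALSE]
      for (k in seq_len(K)) {
        g <- blk$gamma[, , k]
        d2 <- (lrr - emission$cluster_means[k])^2
        ok <- !is.na(d2)
        num <- num + sum(g[ok] * d2[ok])
        den <- den + sum(g[ok])
        mean_num[k] <- mean_num[k] + sum(g[ok] * lrr[ok])
        mean_den[k] <- mean_den[k] + sum(g[ok])
      }
    }
    if (update_means) {
      upd <- mean_den > 0
      emission$cluster_means[upd] <- mean_num[upd] / mean_den[upd]
    }
    v <- num / den
    if (v < 1e-6) {
      warning("degenerate emission variance; floored at 1e-6")
      v <- 1e-6
    }
    emission$lrr_var <- min(v, 0.25)
  }

  es <- .estep_panel(panel, emission, transition)
  trace <- c(trace, sum(vapply(es, function(x) sum(x$loglik), numeric(1))))

  n <- nrow(panel$lrr); p <- ncol(panel$lrr)
  gamma <- array(0, dim = c(n, p, 5L),
                 dimnames = list(rownames(panel$lrr), panel$probe_map$probe_id,
                                 paste0("copy", 0:4)))
  viterbi <- matrix(0L, n, p,
                    dimnames = list(rownames(panel$lrr),
                                    panel$probe_map$probe_id))
  for (blk in es)
    gamma[, blk$idx, ] <- .collapse_gamma(blk$gamma, emission$state_map)
  pm <- panel$probe_map
  for (ch in unique(pm$chrom)) {
    idx <- which(pm$chrom == ch)
    path <- .viterbi_batch(panel$lrr[, idx, drop = FALSE],
                           panel$baf[, idx, drop = FALSE],
                           pm$pos[idx], emission, transition)
    viterbi[, idx] <- matrix(emission$state_map[path], n, length(idx))
  }

  posterior <- structure(list(gamma = gamma, viterbi_path = viterbi,
                              loglik_trace = trace, probe_map = pm,
                              samples = rownames(panel$lrr)),
                         class = "cnv_posterior")
  structure(list(emission = emission, transition = transition,
                 posterior = posterior), class = "cnv_fit")
}

#' Decode a cohort with a fixed emission model (no EM)
#'
#' One forward-backward and Viterbi pass under the supplied models; useful
#' when the default calibrated emission parameters are to be applied as-is.
#'
#' @inheritParams em_fit
#' @param emission An [emission_model()].
#' @return A `cnv_posterior` (see [em_fit()]).
#' @export
cnv_call <- function(panel, emission = emission_model(),
                     transition = transition_model()) {
  fit <- em_fit_fixed(panel, emission, transition)
  fit$posterior
}

# single E-step wrapper sharing em_fit's output assembly
em_fit_fixed <- function(panel, emission, transition) {
  stopifnot(inherits(panel, "intensity_panel"))
  if (nrow(panel$lrr) == 0L) stop("empty cohort", call. = FALSE)
  es <- .estep_panel(panel, emission, transition)
  trace <- sum(vapply(es, function(x) sum(x$loglik), numeric(1)))
  n <- nrow(panel$lrr); p <- ncol(panel$lrr)
  gamma <- array(0, dim = c(n, p, 5L),
                 dimnames = list(rownames(panel$lrr), panel$probe_map$probe_id,
                                 paste0("copy", 0:4)))
  viterbi <- matrix(0L, n, p,
                    dimnames = list(rownames(panel$lrr),
                                    panel$probe_map$probe_id))
  for (blk in es)
    gamma[, blk$idx, ] <- .collapse_gamma(blk$gamma, emission$state_map)
  pm <- panel$probe_map
  for (ch in unique(pm$chrom)) {
    idx <- which(pm$chrom == ch)
    path <- .viterbi_batch(panel$lrr[, idx, drop = FALSE],
                           panel$baf[, idx, drop = FALSE],
                           pm$pos[idx], emission, transition)
    viterbi[, idx] <- matrix(emission$state_map[path], n, length(idx))
  }
  posterior <- structure(list(gamma = gamma, viterbi_path = viterbi,
                              loglik_trace = trace, probe_map = pm,
                              samples = rownames(panel$lrr)),
                         class = "cnv_posterior")
  structure(list(emission = emission, transition = transition,
                 posterior = posterior), class = "cnv_fit")
}

#' Joint multi-cohort CNV calling on a shared probe grid
#'
#' Emulates multi-platform integration: probe sets are intersected by
#' (chromosome, position), one emission model is fitted by EM over the
#' stacked samples of all cohorts, with the reference cohort's probe
#' manifest defining the shared grid and cluster calibration, and
#' per-cohort posteriors are returned on that grid.
#'
#' @param panels Named list of [intensity_panel()] objects (>= 1).
#' @param reference_cohort Name of the reference panel in `panels`.
#' @param init,transition,iters As in [em_fit()].
#' @return A list with `emission` (the shared fitted model) and
#'   `posteriors`, a named list of per-cohort `cnv_posterior` objects.
#' @export
joint_call <- function(panels, reference_cohort = names(panels)[1],
                       init = emission_model(),
                       transition = transition_model(), iters = 15L) {
  stopifnot(length(panels) >= 1, reference_cohort %in% names(panels))
  keys <- lapply(panels, function(p) paste(p$probe_map$chrom, p$probe_map$pos))
  shared <- Reduce(intersect, keys)
  if (!length(shared)) stop("empty probe intersection across cohorts",
                            call. = FALSE)
  ref <- panels[[reference_cohort]]
  ref_idx <- which(keys[[reference_cohort]] %in% shared)
  pm <- ref$probe_map[ref_idx, , drop = FALSE]
  shared_keys <- keys[[reference_cohort]][ref_idx]

  lrr <- list(); baf <- list(); sizes <- integer(length(panels))
  for (i in seq_along(panels)) {
    m <- match(shared_keys, keys[[i]])
    lrr[[i]] <- panels[[i]]$lrr[, m, drop = FALSE]
    baf[[i]] <- panels[[i]]$baf[, m, drop = FALSE]
    sizes[i] <- nrow(lrr[[i]])
  }
  stacked <- intensity_panel(probe_map(pm$probe_id, pm$chrom, pm$pos, pm$gc,
                                       pm$population_baf),
                             do.call(rbind, lrr), do.call(rbind, baf),
                             cohort_id = "joint")
  fit <- em_fit(stacked, init = init, transition = transition, iters = iters)

  offsets <- cumsum(c(0L, sizes))
  posts <- lapply(seq_along(panels), function(i) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    structure(list(gamma = fit$posterior$gamma[rows, , , drop = FALSE],
                   viterbi_path = fit$posterior$viterbi_path[rows, ,
                                                             drop = FALSE],
                   loglik_trace = fit$posterior$loglik_trace,
                   probe_map = fit$posterior$probe_map,
                   samples = fit$posterior$samples[rows]),
              class = "cnv_posterior")
  })
  names(posts) <- names(panels)
  list(emission = fit$emission, posteriors = posts)
}

#' Write Viterbi segments of a cohort as a BED-like TSV
#'
#' Segments are emitted in 0-based half-open coordinates (internal 1-based
#' inclusive bounds converted on output) with columns `chrom`, `start`,
#' `end`, `copy_number`, `mean_posterior`, `sample`.
#'
#' @param posterior A `cnv_posterior` from [em_fit()] or [cnv_call()].
#' @param path Output file.
#' @return The written `data.frame`, invisibly.
#' @export
write_segments <- function(posterior, path) {
  pm <- posterior$probe_map
  rows <- list()
  for (s in seq_along(posterior$samples)) {
    for (ch in unique(pm$chrom)) {
      idx <- which(pm$chrom == ch)
      cls <- posterior$viterbi_path[s, idx]
      mp <- posterior$gamma[cbind(s, idx, cls + 1L)]
      seg <- .path_to_segments(cls, pm$chrom[idx], pm$pos[idx], mp)
      seg$sample <- posterior$samples[s]
      rows[[length(rows) + 1L]] <- seg
    }
  }
  out <- do.call(rbind, rows)
  bed <- to_bed_coords(out$start, out$end)
  out$start <- bed$start; out$end <- bed$end
  data.table::fwrite(out[, c("chrom", "start", "end", "copy_number",
                             "mean_posterior", "sample")],
                     path, sep = "\t")
  invisible(out)
}
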