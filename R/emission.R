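#' Emission model for the copy-number HMM
#'
#' Each hidden cluster emits LRR from a Gaussian with the cluster's mean and
#' a shared variance (ceiling 0.25), and BAF from a mixture over the allelic
#' ratios allowed at the cluster's total copy number. The default nine
#' cluster means (-4.5, -0.3, 0, 0.305, 0.528, 0.702, 0.8434, 0.9848,
#' 1.126) are interpreted as the LRR means for total copies 0-8 and
#' collapsed by `state_map` to the five reported call classes 0-4 (copies
#' of four or more map to class 4).
#'
#' @param cluster_means Strictly increasing LRR means, one per cluster.
#' @param lrr_var Shared LRR emission variance, in `(0, 0.25]`.
#' @param baf_sd BAF cluster spread (truncated-Gaussian standard deviation).
#' @param state_map Integer copy class in `0..4` for each cluster.
#' @param copies Total copy number of each cluster (drives the BAF mixture);
#'   defaults to `0, 1, 2, ...` along the clusters.
#' @return A list of class `emission_model`.
#' @export
emission_model <- function(cluster_means = .default_cluster_means,
                           lrr_var = 0.25, baf_sd = 0.04,
                           state_map = pmin(seq_along(cluster_means) - 1L, 4L),
                           copies = seq_along(cluster_means) - 1L) {
  if (any(diff(cluster_means) <= 0))
    stop("cluster_means must be strictly increasing", call. = FALSE)
  if (lrr_var <= 0 || lrr_var > 0.25)
    stop("lrr_var must lie in (0, 0.25]", call. = FALSE)
  if (length(state_map) != length(cluster_means) ||
      any(state_map < 0L | state_map > 4L))
    stop("state_map must give one copy class in 0..4 per cluster", call. = FALSE)
  structure(list(cluster_means = as.numeric(cluster_means),
                 lrr_var = lrr_var, baf_sd = baf_sd,
                 state_map = as.integer(state_map),
                 copies = as.integer(copies)),
            class = "emission_model")
}

# log-density of a Gaussian truncated to [0, 1]
.log_dtnorm01 <- function(x, mean, sd) {
  stats::dnorm(x, mean, sd, log = TRUE) -
    log(stats::pnorm(1, mean, sd) - stats::pnorm(0, mean, sd))
}

# BAF mixture log-density for one total copy number c, vectorised over baf.
# Equal weights over the c + 1 allowed allelic ratios 0/c .. c/c; copy 0
# carries no allelic signal and emits uniformly on [0, 1] (log-density 0).
.baf_logdens <- function(baf, copy, baf_sd) {
  out <- numeric(length(baf))
  ok <- !is.na(baf)
  if (copy == 0L || !any(ok)) {
    out[!ok] <- 0
    return(out)
  }
  ratios <- (0:copy) / copy
  comp <- vapply(ratios, function(r) .log_dtnorm01(baf[ok], r, baf_sd),
                 numeric(sum(ok)))
  comp <- matrix(comp, nrow = sum(ok))
  out[ok] <- row_logsumexp(comp) - log(copy + 1)
  out
}

#' Emission log-density of one observation under one cluster
#'
#' Gaussian log-density of the LRR at the cluster mean plus the BAF mixture
#' log-density at the cluster's copy number. A missing (`NA`) BAF
#' contributes zero (marginalised out); a missing LRR likewise.
#'
#' @param lrr,baf Observed values (`NA` allowed).
#' @param cluster Cluster index (1-based).
#' @param model An [emission_model()].
#' @return The log-density.
#' @export
emission_loglik <- function(lrr, baf, cluster, model) {
  stopifnot(inherits(model, "emission_model"))
  if (cluster < 1L || cluster > length(model$cluster_means))
    stop("invalid cluster index", call. = FALSE)
  if ((!is.na(lrr) && !is.finite(lrr)) || (!is.na(baf) && !is.finite(baf)))
    stop("non-finite intensity values", call. = FALSE)
  ll <- 0
  if (!is.na(lrr))
    ll <- stats::dnorm(lrr, model$cluster_means[cluster],
                       sqrt(model$lrr_var), log = TRUE)
  ll + .baf_logdens(baf, model$copies[cluster], model$baf_sd)
}

# full log-emission array for a cohort: samples x probes x clusters
.emission_array <- function(lrr, baf, model) {
  n <- nrow(lrr); p <- ncol(lrr); K <- length(model$cluster_means)
  sd <- sqrt(model$lrr_var)
  arr <- array(0, dim = c(n, p, K))
  for (k in seq_len(K)) {
    lt <- stats::dnorm(lrr, model$cluster_means[k], sd, log = TRUE)
    lt[is.na(lt)] <- 0
    bt <- matrix(.baf_logdens(as.vector(baf), model$copies[k], model$baf_sd),
                 n, p)
    arr[, , k] <- lt + bt
  }
  arr
}

#' Transition model of the copy-number HMM
#'
#' Distance-independent by default: every cluster stays with probability
#' `stay_prob` and moves to each other cluster with equal probability.
#' `cnv_open_prob`, if given, overrides the total leave-probability of the
#' diploid cluster. If `distance_scale` is set, the stay probability decays
#' with inter-probe distance `d` as `stay_prob^(d / distance_scale)`.
#'
#' @param stay_prob Probability of remaining in the same cluster at the
#'   next probe (default 0.999).
#' @param cnv_open_prob Optional probability of leaving the diploid cluster.
#' @param distance_scale Optional base-pair scale for distance dependence.
#' @return A list of class `transition_model`.
#' @export
transition_model <- function(stay_prob = 0.999, cnv_open_prob = NULL,
                             distance_scale = NULL) {
  check_fraction(stay_prob, "stay_prob")
  if (!is.null(cnv_open_prob)) check_fraction(cnv_open_prob, "cnv_open_prob")
  structure(list(stay_prob = stay_prob, cnv_open_prob = cnv_open_prob,
                 distance_scale = distance_scale),
            class = "transition_model")
}

#' Transition matrix implied by a transition model
#'
#' @param model A [transition_model()].
#' @param emission The [emission_model()] (supplies the number of clusters
#'   and which cluster is diploid).
#' @param d Optional inter-probe distance in base pairs.
#' @return A stochastic `K x K` matrix.
#' @export
transition_matrix <- function(model, emission, d = NULL) {
  K <- length(emission$cluster_means)
  stay <- model$stay_prob
  if (!is.null(model$distance_scale) && !is.null(d))
    stay <- stay^(d / model$distance_scale)
  Tm <- matrix((1 - stay) / (K - 1), K, K)
  diag(Tm) <- stay
  if (!is.null(model$cnv_open_prob)) {
    dip <- which(emission$copies == 2L)[1]
    if (!is.na(dip)) {
      Tm[dip, ] <- model$cnv_open_prob / (K - 1)
      Tm[dip, dip] <- 1 - model$cnv_open_prob
    }
  }
  Tm
}

# stationary distribution of a stochastic matrix (left eigenvector)
.stationary <- function(Tm) {
  e <- eigen(t(Tm))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- abs(v)
  v / sum(v)
}
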