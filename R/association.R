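# assemble an assoc_result; beta is a named vector (one entry per trait)
.assoc_result <- function(model, traits, beta = NULL, se = NULL,
                          statistic = NA_real_, df = NA_integer_,
                          p_raw = NA_real_, p_lrt = NA_real_,
                          n_used = NA_integer_, flag = NA_character_,
                          probe_id = NA_character_, retained = NULL) {
  structure(list(probe_id = probe_id, model = model, traits = traits,
                 beta = beta, se = se, statistic = statistic, df = df,
                 p_raw = p_raw, p_lrt = p_lrt, n_used = n_used,
                 flag = flag, retained = retained),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result [%s] traits=%s stat=%.4g df=%s p=%.3g n=%d%s\n",
              x$model, paste(x$traits, collapse = ","), x$statistic,
              x$df, x$p_raw, x$n_used,
              if (!is.na(x$flag)) paste0(" flag=", x$flag) else ""))
  invisible(x)
}

#' @export
as.data.frame.assoc_result <- function(x, ...) {
  data.frame(probe_id = x$probe_id, model = x$model,
             traits = paste(x$traits, collapse = ","),
             beta = if (is.null(x$beta)) NA_character_ else
               paste(signif(unname(x$beta), 6), collapse = ","),
             statistic = x$statistic, df = x$df, p_raw = x$p_raw,
             n_used = x$n_used, flag = x$flag, stringsAsFactors = FALSE)
}

# listwise deletion across response, predictors and covariates
.complete_rows <- function(...) {
  mats <- list(...)
  ok <- rep(TRUE, NROW(mats[[1]]))
  for (m in mats) {
    if (is.null(m)) next
    ok <- ok & if (is.null(dim(m))) is.finite(m) else
      apply(m, 1L, function(r) all(is.finite(r)))
  }
  ok
}

.as_cov_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  m <- as.matrix(covariates)
  storage.mode(m) <- "double"
  if (nrow(m) != n) stop("covariates must have one row per sample",
                         call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("cov", seq_len(ncol(m)))
  m
}

#' Univariate CNV-phenotype association (standard GWAS model)
#'
#' Fits `glm(trait ~ covariates + dosage, family)` and returns the Wald test
#' on the dosage coefficient. With a Gaussian family and no covariates this
#' is the ordinary correlation t-test.
#'
#' @param trait Numeric (or 0/1) phenotype vector.
#' @param dosage countAll (or corrected LRR) vector for one probe.
#' @param covariates Optional numeric matrix / data.frame of covariates.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param trait_name,probe_id Labels carried into the result.
#' @return An `assoc_result`. Monomorphic dosage or separation in a
#'   binomial fit is flagged, not an error; an exact fit yields the
#'   smallest representable p with flag `"underflow"`.
#' @export
assoc_univariate <- function(trait, dosage, covariates = NULL,
                             family = c("gaussian", "binomial", "poisson"),
                             trait_name = "trait", probe_id = NA_character_) {
  family <- match.arg(family)
  cov <- .as_cov_matrix(covariates, length(trait))
  ok <- .complete_rows(trait, dosage, cov)
  y <- trait[ok]; x <- dosage[ok]
  cv <- if (!is.null(cov)) cov[ok, , drop = FALSE]
  n <- length(y)
  mono <- function(flag) .assoc_result("univariate", trait_name,
                                       n_used = n, flag = flag,
                                       probe_id = probe_id)
  if (n < 3L || stats::var(x) == 0) return(mono("monomorphic"))

  dat <- data.frame(.y = y, .x = x)
  form <- ".y ~ .x"
  if (!is.null(cv)) {
    dat <- cbind(dat, as.data.frame(cv))
    form <- paste(".y ~", paste(colnames(cv), collapse = " + "), "+ .x")
  }
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::as.formula(form), data = dat, family = family),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_flag <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  row <- sm[".x", ]
  p <- unname(row[4]); flag <- NA_character_
  if (sep_flag) flag <- "separation"
  if (is.finite(p) && p == 0) { p <- .Machine$double.xmin; flag <- "underflow" }
  if (!is.finite(p)) { p <- NA_real_; flag <- "degenerate" }
  .assoc_result("univariate", trait_name,
                beta = stats::setNames(unname(row[1]), trait_name),
                se = unname(row[2]), statistic = unname(row[3]),
                df = 1L, p_raw = p, n_used = n, flag = flag,
                probe_id = probe_id)
}

# shared machinery for Gaussian reverse regressions: fit dosage ~ cov + traits,
# compare with dosage ~ cov by exact F test; also report the LR statistic
# n * log(RSS0 / RSS1), whose null distribution is chi-square on df traits.
.reverse_fit <- function(dosage, traits, covariates, model_label, probe_id) {
  traits <- as.matrix(traits)
  storage.mode(traits) <- "double"
  if (is.null(colnames(traits)))
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  cov <- .as_cov_matrix(covariates, nrow(traits))
  ok <- .complete_rows(dosage, traits, cov)
  y <- dosage[ok]
  Tm <- traits[ok, , drop = FALSE]
  cv <- if (!is.null(cov)) cov[ok, , drop = FALSE]
  n <- length(y)
  ncov <- if (is.null(cv)) 0L else ncol(cv)
  if (n < ncol(Tm) + ncov + 2L)
    stop("too few complete samples for the joint model", call. = FALSE)
  if (stats::var(y) == 0)
    return(.assoc_result(model_label, colnames(Tm), n_used = n,
                         flag = "monomorphic", probe_id = probe_id))

  # drop collinear trait columns (aliased against covariates or each other)
  X0 <- cbind(`(Intercept)` = rep(1, n), cv)
  Xf <- cbind(X0, Tm)
  q <- qr(Xf)
  if (q$rank < ncol(Xf)) {
    keep_cols <- q$pivot[seq_len(q$rank)]
    dropped <- setdiff(colnames(Xf)[-seq_len(ncol(X0))],
                       colnames(Xf)[keep_cols])
    dropped <- intersect(dropped, colnames(Tm))
    if (length(dropped)) {
      warning(sprintf("dropping collinear trait(s): %s",
                      paste(dropped, collapse = ", ")))
      Tm <- Tm[, setdiff(colnames(Tm), dropped), drop = FALSE]
      Xf <- cbind(X0, Tm)
    }
  }
  k <- ncol(Tm)
  fit1 <- stats::lm.fit(Xf, y)
  fit0 <- stats::lm.fit(X0, y)
  rss1 <- sum(fit1$residuals^2)
  rss0 <- sum(fit0$residuals^2)
  df_res <- n - ncol(Xf)
  Fstat <- ((rss0 - rss1) / k) / (rss1 / df_res)
  p <- stats::pf(Fstat, k, df_res, lower.tail = FALSE)
  lrt <- n * log(rss0 / rss1)
  flag <- NA_character_
  if (is.finite(p) && p == 0) { p <- .Machine$double.xmin; flag <- "underflow" }
  beta <- fit1$coefficients[colnames(Tm)]
  # per-trait Wald t-tests from the full fit (used by backward selection)
  sigma2 <- rss1 / df_res
  XtXinv <- chol2inv(chol(crossprod(Xf)))
  se_all <- sqrt(diag(XtXinv) * sigma2)
  names(se_all) <- colnames(Xf)
  tvals <- fit1$coefficients[colnames(Tm)] / se_all[colnames(Tm)]
  pvals <- 2 * stats::pt(abs(tvals), df_res, lower.tail = FALSE)
  res <- .assoc_result(model_label, colnames(Tm), beta = beta,
                       se = se_all[colnames(Tm)], statistic = lrt,
                       df = k, p_raw = p, p_lrt = stats::pchisq(
                         lrt, k, lower.tail = FALSE),
                       n_used = n, flag = flag, probe_id = probe_id)
  res$wald_p <- pvals
  res
}

#' Reverse-regression (joint) multivariate association
#'
#' The MultiPhen-style joint model: the CNV dosage is regressed on all
#' phenotypes plus covariates (`glm(dosage ~ phenotypes + covariates)`,
#' Gaussian), and the phenotype block is tested jointly against the
#' covariates-only null. The reported p comes from the exact F test (with a
#' single Gaussian trait and no covariates it coincides with the forward
#' univariate p); `statistic` is the likelihood-ratio value
#' `n*log(RSS0/RSS1)`, asymptotically chi-square on `df` = number of traits
#' (its tail probability is reported as `p_lrt`).
#'
#' @param dosage countAll vector for one probe.
#' @param traits Numeric matrix / data.frame of phenotypes (one column each).
#' @param covariates Optional covariate matrix.
#' @param probe_id Label carried into the result.
#' @return An `assoc_result` with per-trait `beta` and the joint test.
#'   Collinear traits are dropped with a warning (df reduced).
#' @export
joint_reverse <- function(dosage, traits, covariates = NULL,
                          probe_id = NA_character_) {
  .reverse_fit(dosage, traits, covariates, "joint", probe_id)
}

#' Joint model with backward variable selection
#'
#' Starts from the full reverse regression and repeatedly removes the trait
#' with the largest per-coefficient Wald p exceeding `alpha_step`, refitting
#' after each removal, until every retained trait is individually
#' significant or none remain. The final joint test compares the retained
#' set against the covariates-only null (df = retained traits); an empty
#' final set reports p = 1 by convention.
#'
#' @inheritParams joint_reverse
#' @param alpha_step Per-step retention threshold (default 0.05).
#' @return An `assoc_result`; `retained` lists the surviving traits.
#' @export
joint_selection <- function(dosage, traits, covariates = NULL,
                            alpha_step = 0.05, probe_id = NA_character_) {
  traits <- as.matrix(traits)
  if (is.null(colnames(traits)))
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  all_traits <- colnames(traits)
  current <- all_traits
  res <- NULL
  while (length(current)) {
    res <- .reverse_fit(dosage, traits[, current, drop = FALSE], covariates,
                        "joint_selected", probe_id)
    if (!is.na(res$flag) && res$flag == "monomorphic") return(res)
    current <- res$traits               # collinear drops already applied
    worst <- which.max(res$wald_p)
    if (res$wald_p[worst] <= alpha_step) break
    current <- setdiff(current, names(res$wald_p)[worst])
  }
  if (!length(current)) {
    out <- .assoc_result("joint_selected", character(0),
                         statistic = 0, df = 0L, p_raw = 1, p_lrt = 1,
                         n_used = res$n_used, probe_id = probe_id,
                         retained = character(0))
    return(out)
  }
  res$retained <- current
  res
}

#' LRR-based association models
#'
#' The same three models run directly on corrected Log-R ratios instead of
#' countAll dosages (secondary validation of dosage signals without HMM
#' calls). `mode` selects the model; labels are prefixed `lrr_`.
#'
#' @param traits Phenotype vector (univariate mode) or matrix (joint modes).
#' @param lrr Corrected LRR vector for one probe.
#' @param covariates Optional covariate matrix.
#' @param mode `"univariate"`, `"joint"` or `"joint_selected"`.
#' @param ... Passed to the underlying model.
#' @return An `assoc_result` with an `lrr_*` model label.
#' @export
lrr_assoc <- function(traits, lrr, covariates = NULL,
                      mode = c("univariate", "joint", "joint_selected"),
                      ...) {
  mode <- match.arg(mode)
  res <- switch(mode,
    univariate = assoc_univariate(as.vector(traits), lrr, covariates, ...),
    joint = joint_reverse(lrr, traits, covariates, ...),
    joint_selected = joint_selection(lrr, traits, covariates, ...))
  res$model <- paste0("lrr_", res$model)
  res
}
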