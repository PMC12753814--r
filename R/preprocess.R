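#' Regress GC content out of Log-R ratios
#'
#' Per sample, fits ordinary least squares of LRR on the probe GC fraction
#' and replaces LRR by the residuals (so the corrected LRR has zero mean per
#' sample). BAF, the probe map and matrix shapes are untouched.
#'
#' @param panel An [intensity_panel()].
#' @return The corrected panel.
#' @export
gc_correct <- function(panel) {
  stopifnot(inherits(panel, "intensity_panel"))
  gc <- panel$probe_map$gc
  if (stats::var(gc) == 0) {
    warning("constant GC vector: GC regression undefined, panel unchanged")
    return(panel)
  }
  # one shared design, solved for all samples at once
  X <- cbind(1, gc)
  # residual maker applied to t(lrr): (I - X (X'X)^-1 X') per probe column
  coefs <- solve(crossprod(X), crossprod(X, t(panel$lrr)))
  panel$lrr <- panel$lrr - t(X %*% coefs)
  panel
}

#' Remove the genomic wave from Log-R ratios
#'
#' Per sample and per chromosome, fits a local linear regression (loess,
#' degree 1, tricube weights) of LRR on base-pair position with the given
#' span, and subtracts the fitted smooth. This removes the slow sinusoidal
#' "genomic wave" artefact while leaving short CNV excursions (which occupy
#' far less than one bandwidth) largely intact.
#'
#' @param panel An [intensity_panel()].
#' @param span Loess span: fraction of the chromosome's probes in each
#'   local window.
#' @param family `"symmetric"` (default) iterates with Tukey biweight
#'   robustness, so genuine CNV excursions are downweighted rather than
#'   smoothed into the wave estimate; `"gaussian"` is plain least squares.
#' @param min_probes Chromosomes with fewer probes than this are returned
#'   unchanged with a warning.
#' @return The corrected panel.
#' @export
wave_correct <- function(panel, span = 0.3,
                         family = c("symmetric", "gaussian"),
                         min_probes = 10L) {
  family <- match.arg(family)
  stopifnot(inherits(panel, "intensity_panel"))
  pm <- panel$probe_map
  for (ch in unique(pm$chrom)) {
    idx <- which(pm$chrom == ch)
    if (length(idx) < min_probes) {
      warning(sprintf("chromosome %s has < %d probes: wave correction skipped",
                      ch, min_probes))
      next
    }
    pos <- pm$pos[idx]
    for (s in seq_len(nrow(panel$lrr))) {
      y <- panel$lrr[s, idx]
      if (stats::sd(y) < 1e-12) next   # constant series: nothing to remove
      fit <- stats::loess(y ~ pos, span = span, degree = 1, family = family,
                          control = stats::loess.control(surface = "direct"))
      sm <- stats::fitted(fit)
      if (any(!is.finite(sm))) next    # degenerate robust fit
      panel$lrr[s, idx] <- y - sm
    }
  }
  panel
}

#' Principal components of the LRR matrix for use as covariates
#'
#' Computes the top `k` principal-component scores of the (column-centred)
#' sample x probe LRR matrix. These capture residual intensity structure
#' (batch, hybridisation quality) and are entered as association covariates.
#' Sign convention: within each component, the loading of largest magnitude
#' is made positive, so scores are deterministic across platforms.
#'
#' @param panel An [intensity_panel()].
#' @param k Number of components (default 5).
#' @return A sample x `k` score matrix (columns `PC1..PCk`); `k = 0` gives a
#'   zero-column matrix.
#' @export
lrr_pcs <- function(panel, k = 5L) {
  stopifnot(inherits(panel, "intensity_panel"))
  n <- nrow(panel$lrr)
  if (k == 0L)
    return(matrix(numeric(0), n, 0, dimnames = list(rownames(panel$lrr), NULL)))
  X <- scale(panel$lrr, center = TRUE, scale = FALSE)
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-12
  avail <- sum(pos)
  if (k > avail) {
    warning(sprintf("requested %d components but rank is %d; returning %d",
                    k, avail, avail))
    k <- avail
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(panel$lrr), paste0("PC", seq_len(k)))
  scores
}
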