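#' Effective number of independent tests from a trait correlation matrix
#'
#' Computes the eigenvalues of the phenotype correlation matrix and the
#' effective test count
#' `M_effective = 1 + (M - 1) * (1 - Var(lambda) / M)`,
#' where `Var(lambda)` is the sample variance (denominator `M - 1`) of the
#' observed eigenvalues. With that denominator the two analytic limits are
#' exact: independent traits give `M_effective = M` and perfectly
#' correlated traits give `M_effective = 1`. The result is clipped to
#' `[1, M]`.
#'
#' @param cor_matrix Symmetric correlation matrix with unit diagonal,
#'   positive semi-definite within tolerance.
#' @return A list of class `effective_tests` with `M`, `eigenvalues`,
#'   `var_lambda` and `M_effective`.
#' @export
effective_tests <- function(cor_matrix) {
  cor_matrix <- as.matrix(cor_matrix)
  M <- nrow(cor_matrix)
  if (M == 1L)
    return(structure(list(M = 1L, eigenvalues = 1, var_lambda = 0,
                          M_effective = 1), class = "effective_tests"))
  if (!isSymmetric(unname(cor_matrix), tol = 1e-8))
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(cor_matrix) - 1) > 1e-6))
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  lambda <- eigen(cor_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -1e-6)
    stop("correlation matrix must be positive semi-definite", call. = FALSE)
  v <- stats::var(lambda)
  me <- 1 + (M - 1) * (1 - v / M)
  me <- min(max(me, 1), M)
  structure(list(M = M, eigenvalues = lambda, var_lambda = v,
                 M_effective = me), class = "effective_tests")
}

#' @export
print.effective_tests <- function(x, ...) {
  cat(sprintf("effective_tests: M = %d, Var(lambda) = %.4f, M_effective = %.4f\n",
              x$M, x$var_lambda, x$M_effective))
  invisible(x)
}

#' Sidak adjustment with an effective number of tests
#'
#' `p_adjusted = 1 - (1 - p_raw)^M_effective`; monotone in both arguments
#' and never below the raw p.
#'
#' @param p_raw Raw p values in `[0, 1]`.
#' @param m_effective Effective test count (>= 1), either a number or an
#'   `effective_tests` object.
#' @return Adjusted p values in `[p_raw, 1]`.
#' @export
sidak_adjust <- function(p_raw, m_effective) {
  if (inherits(m_effective, "effective_tests"))
    m_effective <- m_effective$M_effective
  if (m_effective < 1) stop("m_effective must be >= 1", call. = FALSE)
  check_fraction(p_raw, "p_raw")
  # expm1/log1p form keeps precision for tiny p
  -expm1(m_effective * log1p(-p_raw))
}
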