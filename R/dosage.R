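#' Expected CNV genotype (countAll) from a copy-class posterior
#'
#' The expected CNV genotype is the posterior-weighted mean copy number over
#' the collapsed copy classes 0-4: a probe called heterozygous-deleted with
#' probability 0.8 and copy-neutral with probability 0.2 has
#' `1*0.8 + 2*0.2 = 1.2`. Values always lie in `[0, 4]`.
#'
#' @param posterior Probability vector over copy classes `0..4` (length 5,
#'   or a matrix with 5 columns); must sum to 1 within `1e-6` per row.
#' @return The countAll value(s) in `[0, 4]`.
#' @export
expected_genotype <- function(posterior) {
  if (is.null(dim(posterior))) posterior <- matrix(posterior, nrow = 1)
  if (ncol(posterior) != 5L)
    stop("posterior must have one probability per copy class 0..4",
         call. = FALSE)
  if (any(posterior < 0)) stop("negative probabilities", call. = FALSE)
  if (any(abs(rowSums(posterior) - 1) > 1e-6))
    stop("posterior rows must sum to 1 within 1e-6", call. = FALSE)
  out <- as.vector(posterior %*% (0:4))
  if (length(out) == 1L) out else out
}

#' Stratify a countAll value into deletion / neutral / duplication
#'
#' Applies the reporting cut-offs: countAll below 1.7 is a deletion, above
#' 2.5 a duplication, anything between is copy-neutral.
#'
#' @param count_all Numeric countAll values in `[0, 4]`.
#' @return A character vector of classes.
#' @export
stratify <- function(count_all) {
  if (any(!is.finite(count_all)) || any(count_all < 0) || any(count_all > 4))
    stop("countAll values must lie in [0, 4]", call. = FALSE)
  ifelse(count_all < 1.7, "deletion",
         ifelse(count_all > 2.5, "duplication", "neutral"))
}

#' Build a dosage matrix from CNV posteriors
#'
#' Converts a cohort's copy-class posteriors to expected CNV genotypes:
#' `count_all` is the expectation over all five classes; `state0_dosage`
#' (deletion-only) and `state2_dosage` (duplication-only) are expectations
#' under the posterior renormalised over classes `{0,1,2}` and `{2,3,4}`
#' respectively. Per-entry `certainty` is the maximum class posterior, and
#' per-probe MAF is computed from hard-classified carriers via [cnv_maf()].
#'
#' @param posterior A `cnv_posterior` from [em_fit()] or [cnv_call()].
#' @return A list of class `dosage_matrix` with sample x probe matrices
#'   `count_all`, `state0_dosage`, `state2_dosage`, `certainty`, the probe
#'   map, per-probe `maf`, and a per-probe logical `masked` (all `FALSE`
#'   until [certainty_filter()] is applied).
#' @export
dosage_matrix <- function(posterior) {
  stopifnot(inherits(posterior, "cnv_posterior"))
  g <- posterior$gamma
  n <- dim(g)[1]; p <- dim(g)[2]
  flat <- matrix(g, n * p, 5L)
  count_all <- matrix(flat %*% (0:4), n, p)

  sub_expect <- function(cols, values) {
    w <- flat[, cols, drop = FALSE]
    s <- rowSums(w)
    out <- as.vector((w %*% values)) / s
    out[s == 0] <- NA_real_
    matrix(out, n, p)
  }
  state0 <- sub_expect(1:3, 0:2)
  state2 <- sub_expect(3:5, 2:4)
  certainty <- matrix(apply(flat, 1L, max), n, p)

  dimnames(count_all) <- dimnames(state0) <- dimnames(state2) <-
    dimnames(certainty) <- list(posterior$samples,
                                posterior$probe_map$probe_id)
  out <- structure(list(count_all = count_all, state0_dosage = state0,
                        state2_dosage = state2, certainty = certainty,
                        probe_map = posterior$probe_map,
                        masked = rep(FALSE, p)),
                   class = "dosage_matrix")
  out$maf <- apply(count_all, 2L, cnv_maf)
  names(out$masked) <- names(out$maf) <- posterior$probe_map$probe_id
  out
}

#' Mask probes whose average calling certainty is too low
#'
#' A probe enters association only if its average certainty (the maximum
#' posterior probability, averaged over samples) reaches the threshold
#' (default 0.5). Masked probes are recorded, not dropped, so the mask is
#' auditable.
#'
#' @param dosage A [dosage_matrix()].
#' @param min_certainty Threshold in `[0, 1]` (default 0.5).
#' @return The dosage matrix with its `masked` vector updated.
#' @export
certainty_filter <- function(dosage, min_certainty = 0.5) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  check_fraction(min_certainty, "min_certainty")
  avg <- colMeans(dosage$certainty)
  dosage$masked <- avg < min_certainty
  names(dosage$masked) <- colnames(dosage$certainty)
  dosage
}

#' Dosage matrix from a synthetic cohort's planted truth
#'
#' Builds the dosage matrix that a perfectly certain caller would produce:
#' each (sample, probe) posterior is a point mass on the true copy class.
#' Useful for exercising association and QTL machinery independently of
#' HMM calling.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A [dosage_matrix()] with `count_all` equal to the true copy
#'   numbers and certainty 1 everywhere.
#' @export
dosage_from_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cm <- cohort$true_copy_numbers
  n <- nrow(cm); p <- ncol(cm)
  gamma <- array(0, dim = c(n, p, 5L),
                 dimnames = list(rownames(cm), colnames(cm),
                                 paste0("copy", 0:4)))
  gamma[cbind(rep(seq_len(n), p), rep(seq_len(p), each = n),
              as.vector(cm) + 1L)] <- 1
  posterior <- structure(list(gamma = gamma, viterbi_path = cm,
                              loglik_trace = numeric(0),
                              probe_map = cohort$intensities$probe_map,
                              samples = rownames(cm)),
                         class = "cnv_posterior")
  dosage_matrix(posterior)
}

#' CNV minor allele frequency from countAll values
#'
#' Samples are hard-classified by nearest-integer copy number; the deletion
#' allele frequency is `(2 n0 + n1) / (2n)` and the duplication allele
#' frequency `(2 n4 + n3) / (2n)`. Each non-reference frequency is folded
#' to at most 0.5 (a frequency of 1 folds to 0) and the larger folded value
#' is the probe's MAF.
#'
#' @param count_all Numeric countAll vector for one probe (NA = masked).
#' @return The MAF in `[0, 0.5]`, or `NA` if every sample is masked.
#' @export
cnv_maf <- function(count_all) {
  x <- count_all[!is.na(count_all)]
  if (!length(x)) return(NA_real_)
  cls <- pmin(pmax(round(x), 0L), 4L)
  n <- length(cls)
  del <- (2 * sum(cls == 0L) + sum(cls == 1L)) / (2 * n)
  dup <- (2 * sum(cls == 4L) + sum(cls == 3L)) / (2 * n)
  max(pmin(del, 1 - del), pmin(dup, 1 - dup))
}

#' Write a dosage matrix and its per-probe summary as TSV
#'
#' @param dosage A [dosage_matrix()].
#' @param path Output file for the probe x sample countAll table; a sidecar
#'   `<path>.summary.tsv` receives per-probe mean certainty, MAF, mask flag
#'   and class counts.
#' @return Invisibly, the summary `data.frame`.
#' @export
write_dosage <- function(dosage, path) {
  tab <- data.table::data.table(probe_id = colnames(dosage$count_all),
                                t(dosage$count_all))
  data.table::fwrite(tab, path, sep = "\t")
  cls <- apply(dosage$count_all, 2L, function(x) {
    s <- stratify(x[!is.na(x)])
    c(deletion = sum(s == "deletion"), neutral = sum(s == "neutral"),
      duplication = sum(s == "duplication"))
  })
  summ <- data.frame(probe_id = colnames(dosage$count_all),
                     mean_certainty = colMeans(dosage$certainty),
                     maf = dosage$maf, masked = dosage$masked,
                     n_deletion = cls["deletion", ],
                     n_neutral = cls["neutral", ],
                     n_duplication = cls["duplication", ])
  data.table::fwrite(summ, paste0(path, ".summary.tsv"), sep = "\t")
  invisible(summ)
}
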