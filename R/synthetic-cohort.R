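#' CNV locus table for the cohort simulator
#'
#' One row per polymorphic copy-number locus to plant in the simulated
#' population. Each locus segregates as a biallelic variant: the
#' non-reference allele is either a deletion or a duplication of the
#' spanned segment, at the stated population allele frequency.
#'
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive bounds of the affected segment.
#' @param allele_type `"deletion"` or `"duplication"`.
#' @param allele_freq Population frequency of the non-reference allele.
#' @return A `data.frame` of class `cnv_locus`.
#' @export
cnv_locus <- function(chrom, start, end, allele_type, allele_freq) {
  if (length(chrom) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), allele_type = character(),
                      allele_freq = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("cnv_locus", "data.frame")
    return(out)
  }
  allele_type <- match.arg(allele_type, c("deletion", "duplication"),
                           several.ok = TRUE)
  if (any(start > end))
    stop("locus start must not exceed end", call. = FALSE)
  check_fraction(allele_freq, "allele_freq")
  out <- data.frame(chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    allele_type = allele_type,
                    allele_freq = as.numeric(allele_freq),
                    stringsAsFactors = FALSE)
  class(out) <- c("cnv_locus", "data.frame")
  out
}

#' Configuration of a simulated SNP-array cohort
#'
#' Bundles everything [simulate_cohort()] needs: the probe manifest, the CNV
#' loci segregating in the population, and the intensity noise/artefact
#' model. Noise defaults emulate a well-behaved Illumina-style bead array:
#' per-probe LRR noise of 0.2 (variance 0.04, comfortably below the 0.25
#' emission-variance ceiling) and BAF cluster spread of 0.04. The GC slope
#' and sinusoidal genomic wave default to zero — the artefact-free baseline —
#' and are switched on where the corrections themselves are being exercised.
#'
#' @param n_samples Number of diploid samples.
#' @param probe_map A [probe_map()].
#' @param loci A [cnv_locus()] table (may have zero rows).
#' @param lrr_sd Standard deviation of Gaussian LRR noise.
#' @param baf_sd Standard deviation of BAF cluster spread.
#' @param gc_slope LRR units added per unit GC fraction.
#' @param wave_amplitude,wave_period Amplitude (LRR units) and period
#'   (base pairs) of the simulated genomic wave.
#' @param seed Mandatory integer seed; fixed seed gives bit-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples, probe_map, loci = NULL,
                          lrr_sd = 0.2, baf_sd = 0.04,
                          gc_slope = 0, wave_amplitude = 0,
                          wave_period = 1e6, seed) {
  check_count(n_samples, "n_samples", min = 1)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.null(loci)) loci <- cnv_locus(character(), integer(), integer(),
                                       character(), numeric())
  if (lrr_sd < 0 || baf_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (wave_period <= 0) stop("wave_period must be > 0", call. = FALSE)
  check_fraction(loci$allele_freq, "allele_freq")
  structure(list(n_samples = as.integer(n_samples), probe_map = probe_map,
                 loci = loci, lrr_sd = lrr_sd, baf_sd = baf_sd,
                 gc_slope = gc_slope, wave_amplitude = wave_amplitude,
                 wave_period = wave_period, seed = as.integer(seed)),
            class = "cohort_config")
}

# probes covered by one locus row; errors if none
.locus_probes <- function(pm, locus) {
  hit <- which(pm$chrom == locus$chrom &
                 pm$pos >= locus$start & pm$pos <= locus$end)
  if (!length(hit))
    stop(sprintf("locus %s:%d-%d covers no probe in the probe map",
                 locus$chrom, locus$start, locus$end), call. = FALSE)
  hit
}

#' Simulate a SNP-array cohort with known CNV haplotypes
#'
#' Draws, per sample and per locus, two independent haplotypes carrying the
#' non-reference allele with probability `allele_freq` (Hardy-Weinberg, no
#' linkage between loci). The total copy number at a probe is
#' `2 + duplication alleles - deletion alleles`, clipped to `[0, 4]`.
#' LRR is emitted as the copy-state cluster mean (-4.5, -0.3, 0, 0.305,
#' 0.528 for copies 0-4) plus a GC term, a sinusoidal genomic wave, and
#' Gaussian noise. BAF is drawn from the allelic-composition mixture: the
#' B-allele count is binomial in the probe's population BAF over the
#' sample's copies, and the observed BAF is the allelic ratio plus truncated
#' Gaussian spread (uniform on `[0, 1]` at copy zero, where no allelic
#' signal exists).
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `intensities`
#'   (an [intensity_panel()]), `true_copy_numbers` (sample x probe integer
#'   matrix), `true_haplotypes` (sample x locus allele counts), `loci` and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pm <- config$probe_map
  n <- config$n_samples
  p <- nrow(pm)
  loci <- config$loci
  locus_idx <- lapply(seq_len(nrow(loci)), function(i) .locus_probes(pm, loci[i, ]))

  with_seed(config$seed, {
    copy <- matrix(2L, n, p)
    hap <- matrix(0L, n, max(1L, nrow(loci)))
    for (i in seq_len(nrow(loci))) {
      alleles <- stats::rbinom(n, 2L, loci$allele_freq[i])
      hap[, i] <- alleles
      delta <- if (loci$allele_type[i] == "deletion") -alleles else alleles
      copy[, locus_idx[[i]]] <- copy[, locus_idx[[i]]] + delta
    }
    copy[copy < 0L] <- 0L
    copy[copy > 4L] <- 4L

    wave <- config$wave_amplitude * sin(2 * pi * pm$pos / config$wave_period)
    lrr <- matrix(.default_cluster_means[copy + 1L], n, p) +
      rep(config$gc_slope * pm$gc + wave, each = n) +
      matrix(stats::rnorm(n * p, 0, config$lrr_sd), n, p)

    pbaf <- matrix(rep(pm$population_baf, each = n), n, p)
    bcount <- matrix(stats::rbinom(n * p, as.vector(copy), as.vector(pbaf)), n, p)
    ratio <- ifelse(copy > 0L, bcount / pmax(copy, 1L), 0)
    baf <- ratio + matrix(stats::rnorm(n * p, 0, config$baf_sd), n, p)
    unif <- matrix(stats::runif(n * p), n, p)
    baf[copy == 0L] <- unif[copy == 0L]
    baf[baf < 0] <- 0
    baf[baf > 1] <- 1

    samples <- sprintf("S%04d", seq_len(n))
    rownames(lrr) <- rownames(baf) <- rownames(copy) <- samples
    colnames(copy) <- pm$probe_id
    panel <- intensity_panel(pm, lrr, baf, cohort_id = "synthetic")
    structure(list(intensities = panel, true_copy_numbers = copy,
                   true_haplotypes = hap, loci = loci, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples x %d probes, %d CNV locus(i)\n",
              nrow(x$true_copy_numbers), ncol(x$true_copy_numbers),
              nrow(x$loci)))
  invisible(x)
}

#' Realized non-reference allele frequency of a planted locus
#'
#' Counts non-reference alleles in the simulated haplotypes; used to check
#' that realized frequencies converge to the configured ones.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param locus Locus row index.
#' @return Realized allele frequency in `[0, 1]`.
#' @export
realized_allele_freq <- function(cohort, locus = 1L) {
  sum(cohort$true_haplotypes[, locus]) / (2 * nrow(cohort$true_haplotypes))
}
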