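#' Probe map for a SNP-array platform
#'
#' A validated probe manifest: one row per genotyping probe with its genomic
#' position (1-based, GRCh37-style chr:pos), local GC fraction and the
#' population B-allele frequency used when simulating allelic intensities.
#'
#' @param probe_id Character vector of unique probe names.
#' @param chrom Character chromosome labels.
#' @param pos Integer base-pair positions (1-based), strictly increasing
#'   within each chromosome.
#' @param gc GC fraction in `[0, 1]` around each probe.
#' @param population_baf Population frequency of the B allele in `[0, 1]`.
#' @return A `data.frame` of class `probe_map`.
#' @export
probe_map <- function(probe_id, chrom, pos, gc, population_baf = 0.5) {
  n <- length(probe_id)
  if (anyDuplicated(probe_id))
    stop("probe ids must be unique", call. = FALSE)
  chrom <- rep_len(chrom, n)
  if (length(pos) != n)
    stop("probe_map fields must have equal length", call. = FALSE)
  gc <- rep_len(gc, n)
  population_baf <- rep_len(population_baf, n)
  check_fraction(gc, "gc")
  check_fraction(population_baf, "population_baf")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("positions must be strictly increasing on chromosome %s", ch),
           call. = FALSE)
  }
  out <- data.frame(probe_id = as.character(probe_id),
                    chrom = as.character(chrom),
                    pos = as.integer(pos),
                    gc = as.numeric(gc),
                    population_baf = as.numeric(population_baf),
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_map", "data.frame")
  out
}

#' Intensity panel: probe map plus LRR and BAF matrices for one cohort
#'
#' The container for raw or corrected SNP-array intensities. `lrr` holds the
#' Log-R ratio (log2 total fluorescence relative to a diploid reference) and
#' `baf` the B-allele frequency; both are sample-by-probe matrices whose
#' columns follow `probe_map` order.
#'
#' @param probe_map A [probe_map()].
#' @param lrr,baf Numeric sample x probe matrices with matching dimensions;
#'   `baf` entries in `[0, 1]` or `NA`.
#' @param cohort_id Cohort label.
#' @return A list of class `intensity_panel`.
#' @export
intensity_panel <- function(probe_map, lrr, baf, cohort_id = "cohort") {
  stopifnot(is.matrix(lrr), is.matrix(baf))
  if (!identical(dim(lrr), dim(baf)))
    stop("lrr and baf must share dimensions", call. = FALSE)
  if (ncol(lrr) != nrow(probe_map))
    stop("number of probe columns must match the probe map", call. = FALSE)
  bv <- baf[!is.na(baf)]
  if (length(bv) && (min(bv) < 0 || max(bv) > 1))
    stop("baf values must lie in [0, 1] or be NA", call. = FALSE)
  colnames(lrr) <- colnames(baf) <- probe_map$probe_id
  if (is.null(rownames(lrr)))
    rownames(lrr) <- rownames(baf) <- sprintf("S%04d", seq_len(nrow(lrr)))
  structure(list(probe_map = probe_map, lrr = lrr, baf = baf,
                 cohort_id = cohort_id),
            class = "intensity_panel")
}

#' @export
print.intensity_panel <- function(x, ...) {
  cat(sprintf("intensity_panel '%s': %d samples x %d probes (%d chromosome(s))\n",
              x$cohort_id, nrow(x$lrr), ncol(x$lrr),
              length(unique(x$probe_map$chrom))))
  invisible(x)
}

#' @export
dim.intensity_panel <- function(x) dim(x$lrr)

# LRR cluster means used both to simulate and to decode copy number.
# The first five entries are the means for total copies 0-4; entries 6-9
# extend the ladder to copies 5-8 for the emission model.
.default_cluster_means <- c(-4.5, -0.3, 0, 0.305, 0.528,
                            0.702, 0.8434, 0.9848, 1.126)
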