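#' Per-region mean methylated and unmethylated read counts
#'
#' Averages read counts over the positions inside each region (1-based
#' inclusive), per region across all samples pooled: positions are averaged
#' first within each sample's track, then sample means are averaged — with
#' a single track the two conventions coincide.
#'
#' @param track A `methylation_track` (columns `chrom`, `pos`, `meth`,
#'   `unmeth`, optionally `sample`).
#' @param regions `data.frame(name, chrom, start, end)`, 1-based inclusive.
#' @return A `data.frame` with per-region `mean_meth`, `mean_unmeth`,
#'   `n_positions`, and `empty` flag (means `NA` when no position falls in
#'   the region).
#' @export
region_mean_counts <- function(track, regions) {
  if (is.null(track$sample)) track$sample <- "S0001"
  if (any(regions$start > regions$end))
    stop("region start must not exceed end", call. = FALSE)
  out <- regions
  out$mean_meth <- NA_real_
  out$mean_unmeth <- NA_real_
  out$n_positions <- 0L
  out$empty <- TRUE
  for (i in seq_len(nrow(regions))) {
    hit <- track$chrom == regions$chrom[i] &
      track$pos >= regions$start[i] & track$pos <= regions$end[i]
    if (!any(hit)) next
    sub <- track[hit, , drop = FALSE]
    per_sample_m <- tapply(sub$meth, sub$sample, mean)
    per_sample_u <- tapply(sub$unmeth, sub$sample, mean)
    out$mean_meth[i] <- mean(per_sample_m)
    out$mean_unmeth[i] <- mean(per_sample_u)
    out$n_positions[i] <- length(unique(sub$pos))
    out$empty[i] <- FALSE
  }
  out
}

#' Flag regions with high methylation activity
#'
#' Regions whose mean methylated read count strictly exceeds the threshold
#' (default 700) are returned, ordered deterministically by chromosome and
#' start; a mean of exactly 700 is not flagged.
#'
#' @param region_table Output of [region_mean_counts()].
#' @param threshold Mean methylated read-count threshold (default 700).
#' @return The flagged subset of `region_table`.
#' @export
flag_high <- function(region_table, threshold = 700) {
  hit <- !is.na(region_table$mean_meth) & region_table$mean_meth > threshold
  out <- region_table[hit, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Exploratory methylation-wave score
#'
#' Operationalises the periodic "methylation wave" phenomenon: the
#' methylated-count series in a window is linearly detrended, its
#' autocorrelation function computed, and the dominant period read off the
#' first local maximum lag (converted to base pairs via the median position
#' spacing). The amplitude is half the peak-to-trough range of a running-
#' mean smooth of the detrended series. Adding a constant offset leaves the
#' score unchanged. This is an exploratory descriptor, not a test.
#'
#' @param track A single-sample `methylation_track` (or one sample's rows).
#' @param window Optional `c(start, end)` restricting positions (1-based
#'   inclusive); default uses the whole track.
#' @param min_points Minimum number of positions required (else `NA` score).
#' @return A list with `period` (base pairs), `amplitude` (reads) and
#'   `n_points`.
#' @export
wave_score <- function(track, window = NULL, min_points = 8L) {
  if (!is.null(track$sample) && length(unique(track$sample)) > 1L)
    stop("wave_score expects a single sample's track", call. = FALSE)
  sub <- track
  if (!is.null(window))
    sub <- track[track$pos >= window[1] & track$pos <= window[2], ,
                 drop = FALSE]
  n <- nrow(sub)
  if (n < min_points)
    return(list(period = NA_real_, amplitude = NA_real_, n_points = n))
  y <- sub$meth
  pos <- sub$pos
  detr <- stats::residuals(stats::lm(y ~ pos))
  spacing <- stats::median(diff(pos))

  ac <- stats::acf(detr, lag.max = n - 2L, plot = FALSE)$acf[-1]
  period <- NA_real_
  for (l in seq_along(ac)) {
    if (l > 1 && l < length(ac) && ac[l] > ac[l - 1] && ac[l] >= ac[l + 1] &&
        ac[l] > 0) {
      period <- l * spacing
      break
    }
  }
  k <- max(3L, min(7L, n %/% 4L))
  sm <- stats::filter(detr, rep(1 / k, k), sides = 2)
  sm <- sm[!is.na(sm)]
  amplitude <- if (length(sm)) (max(sm) - min(sm)) / 2 else 0
  list(period = period, amplitude = amplitude, n_points = n)
}

#' Mean methylated-count tracks of two sample groups
#'
#' Helper for comparing wave phase between groups: returns the per-position
#' mean methylated counts of each group (positions must align) and their
#' correlation — anti-phase groups anti-correlate.
#'
#' @param track A multi-sample `methylation_track`.
#' @param group_a,group_b Character vectors of sample ids.
#' @return A list with `mean_a`, `mean_b`, `pos` and `correlation`.
#' @export
group_mean_tracks <- function(track, group_a, group_b) {
  mean_of <- function(ids) {
    sub <- track[track$sample %in% ids, , drop = FALSE]
    agg <- tapply(sub$meth, sub$pos, mean)
    agg[order(as.numeric(names(agg)))]
  }
  a <- mean_of(group_a); b <- mean_of(group_b)
  stopifnot(identical(names(a), names(b)))
  list(mean_a = unname(a), mean_b = unname(b),
       pos = as.numeric(names(a)),
       correlation = stats::cor(unname(a), unname(b)))
}

#' Read a methylation track from TSV, and regions from BED
#'
#' The track TSV has columns `chrom`, `pos`, `meth`, `unmeth` (optionally
#' `sample`); BED regions are 0-based half-open on disk and converted to
#' the package's 1-based inclusive convention on read.
#'
#' @param path Input file.
#' @return A `methylation_track` data.frame, or a regions `data.frame`.
#' @export
read_methylation <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("chrom", "pos", "meth", "unmeth")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (any(dt$meth < 0 | dt$unmeth < 0))
    stop("read counts must be non-negative", call. = FALSE)
  out <- as.data.frame(dt)
  class(out) <- c("methylation_track", "data.frame")
  out
}

#' @rdname read_methylation
#' @export
read_regions_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  conv <- from_bed_coords(dt[[2]], dt[[3]])
  data.frame(name = if (ncol(dt) >= 4) dt[[4]] else
    sprintf("region%d", seq_len(nrow(dt))),
    chrom = dt[[1]], start = conv$start, end = conv$end,
    stringsAsFactors = FALSE)
}
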