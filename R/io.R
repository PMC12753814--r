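#' Write an intensity panel as a GenomeStudio-style final report
#'
#' One row per probe x sample with tab-delimited columns `SNP Name`,
#' `Sample ID`, `Chr`, `Position`, `Log R Ratio`, `B Allele Freq`. A
#' sidecar `<path>.probes.tsv` preserves the probe map's GC and population
#' BAF so a write-then-read round trip is lossless.
#'
#' @param panel An [intensity_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_final_report <- function(panel, path) {
  pm <- panel$probe_map
  n <- nrow(panel$lrr)
  long <- data.table::data.table(
    `SNP Name` = rep(pm$probe_id, each = n),
    `Sample ID` = rep(rownames(panel$lrr), times = nrow(pm)),
    Chr = rep(pm$chrom, each = n),
    Position = rep(pm$pos, each = n),
    `Log R Ratio` = as.vector(panel$lrr),
    `B Allele Freq` = as.vector(panel$baf))
  data.table::fwrite(long, path, sep = "\t")
  data.table::fwrite(pm, paste0(path, ".probes.tsv"), sep = "\t")
  invisible(path)
}

#' Read a GenomeStudio-style final report into an intensity panel
#'
#' Columns are matched by name (order-insensitive); a missing mandatory
#' column or a duplicated (probe, sample) row is an error. Missing
#' intensities are kept as `NA` and marginalised by the HMM. If the sidecar
#' probe file written by [write_final_report()] exists, its GC and
#' population BAF are restored; otherwise both default to 0.5.
#'
#' @param path Input file.
#' @param cohort_id Cohort label for the panel.
#' @return An [intensity_panel()].
#' @export
read_final_report <- function(path, cohort_id = "cohort") {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("SNP Name", "Sample ID", "Chr", "Position", "Log R Ratio",
            "B Allele Freq")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(dt[, c("SNP Name", "Sample ID")]))
    stop("duplicated (probe, sample) rows in final report", call. = FALSE)

  probes <- unique(dt[, c("SNP Name", "Chr", "Position")])
  probes <- probes[order(probes$Chr, probes$Position), ]
  samples <- sort(unique(dt[["Sample ID"]]))

  side <- paste0(path, ".probes.tsv")
  if (file.exists(side)) {
    pm_dt <- data.table::fread(side, sep = "\t")
    pm_dt <- pm_dt[match(probes[["SNP Name"]], pm_dt$probe_id), ]
    pm <- probe_map(pm_dt$probe_id, pm_dt$chrom, pm_dt$pos, pm_dt$gc,
                    pm_dt$population_baf)
  } else {
    pm <- probe_map(probes[["SNP Name"]], probes$Chr, probes$Position,
                    gc = 0.5, population_baf = 0.5)
  }

  pi <- match(dt[["SNP Name"]], pm$probe_id)
  si <- match(dt[["Sample ID"]], samples)
  lrr <- matrix(NA_real_, length(samples), nrow(pm),
                dimnames = list(samples, pm$probe_id))
  baf <- lrr
  lrr[cbind(si, pi)] <- dt[["Log R Ratio"]]
  baf[cbind(si, pi)] <- dt[["B Allele Freq"]]
  intensity_panel(pm, lrr, baf, cohort_id = cohort_id)
}

#' Write the planted truth of a synthetic cohort as TSV
#'
#' @param cohort A [simulate_cohort()] result.
#' @param path Output file for the sample x probe true copy numbers; the
#'   planted loci go to `<path>.loci.tsv`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  tab <- data.table::data.table(sample = rownames(cohort$true_copy_numbers),
                                cohort$true_copy_numbers)
  data.table::fwrite(tab, path, sep = "\t")
  data.table::fwrite(cohort$loci, paste0(path, ".loci.tsv"), sep = "\t")
  invisible(path)
}

#' Read an expression matrix and sidecar annotation into a panel
#'
#' The expression TSV has probe rows (`probe_id` column, then one column
#' per sample); the annotation TSV maps probes to genes and coordinates.
#'
#' @param paths Named character vector of per-region expression TSVs.
#' @param annotation_path Annotation TSV (`probe_id`, `gene`, `chrom`,
#'   `start`, `end`).
#' @return An `expression_panel`.
#' @export
read_expression <- function(paths, annotation_path) {
  ann <- as.data.frame(data.table::fread(annotation_path, sep = "\t"))
  mats <- lapply(paths, function(p) {
    dt <- data.table::fread(p, sep = "\t")
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt[[1]]
    m
  })
  if (is.null(names(mats)))
    names(mats) <- sprintf("region%d", seq_along(mats))
  structure(list(regions = mats, annotation = ann),
            class = "expression_panel")
}

#' Write an expression panel as per-region TSVs plus annotation
#'
#' @param panel An `expression_panel`.
#' @param dir Output directory.
#' @return Named vector of written region paths, invisibly.
#' @export
write_expression <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(panel$regions), function(r) {
    p <- file.path(dir, paste0("expression_", r, ".tsv"))
    m <- panel$regions[[r]]
    data.table::fwrite(data.table::data.table(probe_id = rownames(m), m),
                       p, sep = "\t")
    p
  }, character(1))
  data.table::fwrite(panel$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t")
  invisible(paths)
}

#' Write association results as a fixed-column TSV
#'
#' Column order: probe, chrom, pos, model, traits, beta, statistic, df,
#' p_raw, p_adj, maf, n. A Manhattan-ready export (chrom, pos, -log10 p)
#' is written alongside when `manhattan = TRUE`.
#'
#' @param results List of `assoc_result` objects (or a prebuilt
#'   `data.frame` with the columns above).
#' @param probe_map A [probe_map()] supplying chrom/pos per probe.
#' @param path Output file.
#' @param maf Optional named per-probe MAF vector.
#' @param p_adj Optional adjusted p values aligned with `results`.
#' @param manhattan Also write `<path>.manhattan.tsv`.
#' @return The written `data.frame`, invisibly.
#' @export
write_assoc_results <- function(results, probe_map, path, maf = NULL,
                                p_adj = NULL, manhattan = TRUE) {
  if (!is.data.frame(results))
    results <- do.call(rbind, lapply(results, as.data.frame))
  m <- match(results$probe_id, probe_map$probe_id)
  out <- data.frame(probe = results$probe_id,
                    chrom = probe_map$chrom[m], pos = probe_map$pos[m],
                    model = results$model, traits = results$traits,
                    beta = results$beta, statistic = results$statistic,
                    df = results$df, p_raw = results$p_raw,
                    p_adj = if (is.null(p_adj)) NA_real_ else p_adj,
                    maf = if (is.null(maf)) NA_real_ else
                      unname(maf[results$probe_id]),
                    n = results$n_used, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  if (manhattan) {
    mh <- data.frame(chrom = out$chrom, pos = out$pos,
                     neglog10p = -log10(out$p_raw))
    data.table::fwrite(mh, paste0(path, ".manhattan.tsv"), sep = "\t")
  }
  invisible(out)
}
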