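#' Cis CNV-eQTL scan over gene windows
#'
#' Pairs every unmasked CNV probe lying within a gene boundary extended by
#' `window_bp` on both sides (1-based inclusive interval arithmetic) with
#' every expression probe of that gene, and tests each pair in each tissue
#' region with the univariate model (`expression ~ covariates + dosage`).
#' Each CNV probe also carries the annotation of the gene whose body
#' contains it, so a probe inside gene A that falls within the window of a
#' neighbouring gene B produces an A-dosage-to-B-expression test — the raw
#' material of the reciprocal scan.
#'
#' @param dosage A [dosage_matrix()] (apply [certainty_filter()] first if
#'   masking is wanted).
#' @param expression An `expression_panel` from [simulate_expression()] or
#'   [read_expression()]; its annotation must map expression probes to genes.
#' @param genes `data.frame(gene, chrom, start, end)` with 1-based
#'   inclusive gene boundaries.
#' @param window_bp Window in base pairs around each gene (default 5000).
#' @param covariates Optional covariate matrix (samples in dosage order).
#' @return A `data.frame` with one row per (region, gene, expression probe,
#'   CNV probe): effect, t statistic, df, `p_raw`, sample count, and the
#'   CNV probe's own gene (`cnv_gene`, `NA` if intergenic).
#' @export
cis_qtl <- function(dosage, expression, genes, window_bp = 5000,
                    covariates = NULL) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  pm <- dosage$probe_map
  ann <- expression$annotation

  shared <- intersect(rownames(dosage$count_all),
                      colnames(expression$regions[[1]]))
  if (!length(shared)) stop("no overlapping samples between panels",
                            call. = FALSE)
  ca <- dosage$count_all[shared, , drop = FALSE]
  cov <- if (!is.null(covariates))
    as.matrix(covariates)[match(shared, rownames(dosage$count_all)), ,
                          drop = FALSE]

  # gene body containing each CNV probe (window not applied here)
  cnv_gene <- rep(NA_character_, nrow(pm))
  for (i in seq_len(nrow(genes))) {
    inside <- pm$chrom == genes$chrom[i] &
      pm$pos >= genes$start[i] & pm$pos <= genes$end[i]
    cnv_gene[inside & is.na(cnv_gene)] <- genes$gene[i]
  }

  rows <- list()
  for (region in names(expression$regions)) {
    em <- expression$regions[[region]][, shared, drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      cnv_idx <- which(pm$chrom == g$chrom &
                         pm$pos >= g$start - window_bp &
                         pm$pos <= g$end + window_bp &
                         !dosage$masked)
      expr_ids <- ann$probe_id[ann$gene == g$gene]
      expr_ids <- intersect(expr_ids, rownames(em))
      for (cp in cnv_idx) {
        x <- ca[, cp]
        for (ep in expr_ids) {
          res <- assoc_univariate(em[ep, ], x, covariates = cov,
                                  trait_name = ep,
                                  probe_id = pm$probe_id[cp])
          rows[[length(rows) + 1L]] <- data.frame(
            region = region, gene = g$gene, expr_probe = ep,
            cnv_probe = pm$probe_id[cp], cnv_gene = cnv_gene[cp],
            beta = if (is.null(res$beta)) NA_real_ else unname(res$beta),
            statistic = res$statistic, df = res$df, p_raw = res$p_raw,
            n_used = res$n_used, flag = res$flag,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(region = character(), gene = character(),
                      expr_probe = character(), cnv_probe = character(),
                      cnv_gene = character(), beta = numeric(),
                      statistic = numeric(), df = integer(),
                      p_raw = numeric(), n_used = integer(),
                      flag = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect reciprocal CNV-dosage / expression gene pairs
#'
#' A pair (A, B) is reciprocal when dosage of a CNV probe inside gene A
#' associates with expression of gene B and dosage of a probe inside B
#' associates with expression of A, both below the p threshold. Pairs are
#' reported once, ordered lexicographically, with the best p of each
#' direction.
#'
#' @param qtl A [cis_qtl()] result table.
#' @param p_threshold Significance threshold applied to both directions.
#' @return `data.frame(gene_a, gene_b, p_ab, p_ba)` sorted by pair.
#' @export
reciprocal_scan <- function(qtl, p_threshold = 1e-4) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      p_ab = numeric(), p_ba = numeric(),
                      stringsAsFactors = FALSE)
  if (p_threshold <= 0 || !nrow(qtl)) return(empty)
  hits <- qtl[!is.na(qtl$p_raw) & !is.na(qtl$cnv_gene) &
                qtl$cnv_gene != qtl$gene & qtl$p_raw < p_threshold, ,
              drop = FALSE]
  if (!nrow(hits)) return(empty)
  # best p per directed (cnv_gene -> expr gene) pair
  key <- paste(hits$cnv_gene, hits$gene, sep = "\r")
  best <- tapply(hits$p_raw, key, min)
  dirs <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  out <- list()
  for (i in seq_len(nrow(dirs))) {
    a <- dirs[i, 1]; b <- dirs[i, 2]
    if (a >= b) next                       # report each unordered pair once
    back <- which(dirs[, 1] == b & dirs[, 2] == a)
    if (length(back))
      out[[length(out) + 1L]] <- data.frame(gene_a = a, gene_b = b,
                                            p_ab = unname(best[i]),
                                            p_ba = unname(best[back]),
                                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
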