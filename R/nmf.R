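#' Derived expression matrices: region average and concatenated full set
#'
#' `ave_all` averages the probe x sample expression matrices of all regions
#' elementwise (samples aligned by column order); `full_set` concatenates
#' them column-wise with region-tagged sample names. These are the two
#' derived matrices over which gene programs are factorised alongside the
#' per-region matrices.
#'
#' @param panel An `expression_panel`.
#' @return A probe x sample matrix.
#' @export
ave_all <- function(panel) {
  mats <- panel$regions
  d <- dim(mats[[1]])
  for (m in mats)
    if (!identical(dim(m), d))
      stop("regions must share probe and sample dimensions", call. = FALSE)
  Reduce(`+`, mats) / length(mats)
}

#' @rdname ave_all
#' @export
full_set <- function(panel) {
  mats <- panel$regions
  for (r in names(mats))
    colnames(mats[[r]]) <- paste(r, colnames(mats[[r]]), sep = ".")
  do.call(cbind, mats)
}

#' Extract the expression sub-matrix for one gene window
#'
#' Selects expression probes whose coordinates overlap the gene boundary
#' extended by `window_bp` on each side, with closed (1-based inclusive)
#' intervals: a probe exactly at `boundary + window_bp` is included.
#'
#' @param expr Probe x sample expression matrix.
#' @param annotation `data.frame(probe_id, chrom, start, end)` for the rows
#'   of `expr` (point probes may set `end = start`).
#' @param gene One-row `data.frame(gene, chrom, start, end)` or a gene name
#'   present in `annotation$gene`.
#' @param window_bp Window size in base pairs (default 5000).
#' @return The probe-subset matrix (0 rows, flagged via attribute
#'   `empty = TRUE`, when no probe falls in the window).
#' @export
gene_window_matrix <- function(expr, annotation, gene, window_bp = 5000) {
  if (is.character(gene)) {
    if (!"gene" %in% names(annotation) || !gene %in% annotation$gene)
      stop(sprintf("gene '%s' not in annotation", gene), call. = FALSE)
    rows <- annotation[annotation$gene == gene, ]
    gene <- data.frame(gene = gene, chrom = rows$chrom[1],
                       start = min(rows$start), end = max(rows$end))
  }
  lo <- gene$start - window_bp
  hi <- gene$end + window_bp
  ends <- if ("end" %in% names(annotation)) annotation$end else annotation$start
  hit <- annotation$chrom == gene$chrom & ends >= lo & annotation$start <= hi
  out <- expr[match(annotation$probe_id[hit], rownames(expr)), , drop = FALSE]
  if (!nrow(out)) attr(out, "empty") <- TRUE
  out
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimises the Frobenius reconstruction error `||X - W H||` with the
#' classical multiplicative update rules, from a seeded uniform-random
#' start. The error trace is non-increasing by construction of the updates.
#'
#' @param X Non-negative probe x sample matrix.
#' @param rank Factorization rank (`<= min(dim(X))`).
#' @param seed Integer seed for the random initialisation.
#' @param max_iter Maximum update sweeps.
#' @param tol Relative error-change convergence tolerance.
#' @return A list with `W` (probe x rank), `H` (rank x sample), the final
#'   relative `error` and the per-iteration `error_trace`.
#' @export
nmf_factorize <- function(X, rank, seed = 1L, max_iter = 200L, tol = 1e-9) {
  X <- as.matrix(X)
  if (any(X < 0))
    stop("NMF input must be non-negative; shift the matrix first",
         call. = FALSE)
  if (rank > min(dim(X)))
    stop("rank must not exceed either dimension of X", call. = FALSE)
  eps <- .Machine$double.eps
  nx <- norm(X, "F")
  with_seed(seed, {
    W <- matrix(stats::runif(nrow(X) * rank), nrow(X), rank)
    H <- matrix(stats::runif(rank * ncol(X)), rank, ncol(X))
    trace <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
      W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
      err <- norm(X - W %*% H, "F") / nx
      trace <- c(trace, err)
      if (is.finite(prev) && prev - err < tol * max(prev, eps)) break
      prev <- err
    }
    list(W = W, H = H, error = trace[length(trace)], error_trace = trace)
  })
}

#' Consensus NMF clustering over random restarts
#'
#' Runs [nmf_factorize()] `n_runs` times (run `i` seeded `base_seed + i`),
#' hard-assigns each probe to its argmax program per run, builds the
#' consensus matrix (fraction of runs in which two probes co-assign), and
#' cuts an average-linkage hierarchical clustering of `1 - consensus` into
#' `rank` consensus clusters.
#'
#' @param X Non-negative probe x sample matrix with row names.
#' @param rank Number of programs.
#' @param n_runs Number of restarts (default 50, >= 2).
#' @param base_seed Base seed; restart `i` uses `base_seed + i`.
#' @param max_iter Update sweeps per run.
#' @return A list of class `nmf_consensus` with the `consensus` matrix,
#'   `clusters` (consensus cluster id per probe), `assignments` (probe x
#'   run program indices), `rank`, `n_runs` and the best run's factors.
#' @export
nmf_consensus <- function(X, rank, n_runs = 50L, base_seed = 1L,
                          max_iter = 200L) {
  check_count(n_runs, "n_runs", min = 2)
  X <- as.matrix(X)
  p <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("probe", seq_len(p))
  assignments <- matrix(0L, p, n_runs,
                        dimnames = list(rownames(X), NULL))
  best <- NULL
  for (i in seq_len(n_runs)) {
    fit <- nmf_factorize(X, rank, seed = base_seed + i, max_iter = max_iter)
    assignments[, i] <- max.col(fit$W, ties.method = "first")
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  consensus <- matrix(0, p, p, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n_runs)) {
    same <- outer(assignments[, i], assignments[, i], `==`)
    consensus <- consensus + same
  }
  consensus <- consensus / n_runs
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  clusters <- stats::cutree(hc, k = rank)
  structure(list(consensus = consensus, clusters = clusters,
                 assignments = assignments, rank = rank, n_runs = n_runs,
                 best_fit = best),
            class = "nmf_consensus")
}

# Align one run's program labels to the consensus clusters by greedy
# one-to-one maximum-overlap matching (program labels are arbitrary per
# restart; without alignment occurrence counts would be meaningless).
.align_labels <- function(run_labels, consensus_clusters, rank) {
  ov <- matrix(0L, rank, rank)
  for (p in seq_len(rank)) for (c in seq_len(rank))
    ov[p, c] <- sum(run_labels == p & consensus_clusters == c)
  map <- integer(rank)
  free_p <- seq_len(rank); free_c <- seq_len(rank)
  while (length(free_p)) {
    sub <- ov[free_p, free_c, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    map[free_p[ij[1]]] <- free_c[ij[2]]
    free_p <- free_p[-ij[1]]; free_c <- free_c[-ij[2]]
  }
  map[run_labels]
}

#' Per-probe program occurrence counts across ranks
#'
#' For each rank's consensus result, aligns every restart's program labels
#' to the consensus clusters (greedy maximum-overlap matching, since raw
#' labels are arbitrary per restart) and counts how many restarts place
#' each probe in each program. The per-probe "relative importance" summary
#' is the fraction of restarts (across all ranks) in which the probe lands
#' in its modal program.
#'
#' @param consensus_list Named or unnamed list of [nmf_consensus()] results
#'   computed on the same probe set (typically ranks 2..6).
#' @return A list of class `program_table`: `counts`, a `data.frame` with
#'   `probe_id`, `rank`, `program`, `count`, `consensus_cluster`; and
#'   `importance`, the per-probe summary.
#' @export
program_counts <- function(consensus_list) {
  probes <- rownames(consensus_list[[1]]$assignments)
  for (cc in consensus_list)
    if (!identical(rownames(cc$assignments), probes))
      stop("all ranks must be computed on the same probe set", call. = FALSE)
  rows <- list()
  modal_frac <- matrix(0, length(probes), length(consensus_list))
  for (j in seq_along(consensus_list)) {
    cc <- consensus_list[[j]]
    aligned <- apply(cc$assignments, 2L, .align_labels,
                     consensus_clusters = cc$clusters, rank = cc$rank)
    cc$assignments <- matrix(aligned, nrow(cc$assignments),
                             dimnames = dimnames(cc$assignments))
    for (pr in seq_len(cc$rank)) {
      cnt <- rowSums(cc$assignments == pr)
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = probes, rank = cc$rank, program = pr, count = cnt,
        consensus_cluster = unname(cc$clusters),
        stringsAsFactors = FALSE)
    }
    modal_frac[, j] <- apply(cc$assignments, 1L, function(a)
      max(tabulate(a, cc$rank))) / cc$n_runs
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  importance <- data.frame(probe_id = probes,
                           relative_importance = rowMeans(modal_frac),
                           stringsAsFactors = FALSE)
  structure(list(counts = counts, importance = importance),
            class = "program_table")
}

#' Shift a matrix to non-negativity for NMF input
#'
#' Subtracts the global minimum when the matrix contains negative values
#' (log-scale expression often does); otherwise returns the input
#' unchanged.
#'
#' @param X Numeric matrix.
#' @return A non-negative matrix.
#' @export
nonneg_shift <- function(X) {
  m <- min(X)
  if (m < 0) X - m else X
}
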