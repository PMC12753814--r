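#' Validate a pipeline run configuration
#'
#' Accepts a list, or a path to a YAML/JSON file, describing one synthetic
#' end-to-end run. Mandatory: `seed` and `out_dir`. Defaults mirror the
#' pipeline's reporting conventions: certainty threshold 0.5, MAF filter
#' 0.01, stratification cut-offs 1.7 / 2.5, methylation flag threshold 700,
#' gender always a covariate, LRR principal components optional.
#'
#' @param x A list or a file path.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  if (is.null(x$seed)) stop("config must name a seed for stochastic stages",
                            call. = FALSE)
  if (is.null(x$out_dir)) stop("config must name out_dir", call. = FALSE)
  defaults <- list(n_samples = 200L, n_probes = 300L, probe_spacing = 2000L,
                   allele_freq = 0.3, allele_type = "deletion",
                   lrr_sd = 0.2, baf_sd = 0.04, gc_slope = 0,
                   wave_amplitude = 0, wave_period = 1e6,
                   em_iters = 15L, wave_span = 0.3,
                   min_certainty = 0.5, min_maf = 0.01,
                   n_lrr_pcs = 0L, use_gender = TRUE,
                   models = c("univariate", "joint", "joint_selected"),
                   trait_betas = c(trait1 = 0.8, trait2 = 0),
                   trait_sd = 1, methylation = FALSE,
                   meth_threshold = 700)
  for (nm in names(defaults)) if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  if (is.null(x$cnv_start_probe))
    x$cnv_start_probe <- max(2L, round(x$n_probes / 3))
  if (is.null(x$cnv_n_probes))
    x$cnv_n_probes <- max(5L, round(x$n_probes / 12))
  if (x$cnv_start_probe + x$cnv_n_probes - 1L > x$n_probes)
    stop("planted CNV extends beyond the probe grid", call. = FALSE)
  check_fraction(x$min_certainty, "min_certainty")
  check_fraction(x$min_maf, "min_maf", 0, 0.5)
  check_fraction(x$allele_freq, "allele_freq")
  structure(x, class = c("run_config", "list"))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes simulate, GC correct, wave correct, EM-fit CNV calling, dosage
#' conversion with certainty and MAF filtering, phenotype simulation,
#' the configured association models per probe, and the effective-tests
#' Sidak correction; optionally a methylation stage. Every stage's
#' parameters and seed are logged in a JSON manifest, and deterministic
#' stages reproduce byte-identical outputs under the same config.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return The output directory path, invisibly; results land there as
#'   TSVs plus `manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- simulate -------------------------------------------------------------
  pos <- seq(1e5, by = cfg$probe_spacing, length.out = cfg$n_probes)
  pm <- probe_map(sprintf("p%04d", seq_len(cfg$n_probes)), "chr1", pos,
                  gc = 0.35 + 0.3 * (sin(pos / 5e5) + 1) / 2)
  lo_idx <- cfg$cnv_start_probe:(cfg$cnv_start_probe + cfg$cnv_n_probes - 1L)
  loci <- cnv_locus("chr1", pos[min(lo_idx)], pos[max(lo_idx)],
                    cfg$allele_type, cfg$allele_freq)
  cc <- cohort_config(cfg$n_samples, pm, loci, lrr_sd = cfg$lrr_sd,
                      baf_sd = cfg$baf_sd, gc_slope = cfg$gc_slope,
                      wave_amplitude = cfg$wave_amplitude,
                      wave_period = cfg$wave_period, seed = cfg$seed)
  cohort <- simulate_cohort(cc)
  write_final_report(cohort$intensities,
                     file.path(cfg$out_dir, "final_report.tsv"))
  write_truth(cohort, file.path(cfg$out_dir, "truth.tsv"))

  # --- preprocess -----------------------------------------------------------
  panel <- gc_correct(cohort$intensities)
  panel <- wave_correct(panel, span = cfg$wave_span)
  pcs <- if (cfg$n_lrr_pcs > 0) lrr_pcs(panel, cfg$n_lrr_pcs)

  # --- call + dosage --------------------------------------------------------
  fit <- em_fit(panel, iters = cfg$em_iters)
  write_segments(fit$posterior, file.path(cfg$out_dir, "segments.bed"))
  dm <- certainty_filter(dosage_matrix(fit$posterior), cfg$min_certainty)
  write_dosage(dm, file.path(cfg$out_dir, "dosage.tsv"))

  # --- phenotypes + covariates ---------------------------------------------
  locus_probes <- which(pm$pos >= loci$start & pm$pos <= loci$end)
  causal <- dm$count_all[, locus_probes[1]]
  traits <- lapply(names(cfg$trait_betas), function(nm)
    trait_spec(nm, "quantitative", beta = cfg$trait_betas[[nm]],
               sd = cfg$trait_sd))
  pheno <- simulate_phenotypes(causal, traits, seed = cfg$seed + 1L)
  gender <- with_seed(cfg$seed + 2L, stats::rbinom(cfg$n_samples, 1L, 0.5))
  cov <- if (cfg$use_gender) cbind(gender = gender)
  if (!is.null(pcs)) cov <- cbind(cov, pcs)
  tm <- as.matrix(pheno[, -1, drop = FALSE])

  # --- association + correction --------------------------------------------
  keep <- which(!dm$masked & !is.na(dm$maf) & dm$maf >= cfg$min_maf)
  results <- list()
  for (j in keep) {
    x <- dm$count_all[, j]
    pid <- pm$probe_id[j]
    if ("univariate" %in% cfg$models)
      for (tn in colnames(tm))
        results[[length(results) + 1L]] <-
          assoc_univariate(tm[, tn], x, cov, trait_name = tn, probe_id = pid)
    if ("joint" %in% cfg$models)
      results[[length(results) + 1L]] <- joint_reverse(x, tm, cov,
                                                       probe_id = pid)
    if ("joint_selected" %in% cfg$models)
      results[[length(results) + 1L]] <- joint_selection(x, tm, cov,
                                                         probe_id = pid)
  }
  et <- effective_tests(stats::cor(tm))
  p_raw <- vapply(results, `[[`, numeric(1), "p_raw")
  n_probes_tested <- length(keep)
  p_adj <- sidak_adjust(p_raw, et$M_effective * max(1L, n_probes_tested))
  tab <- write_assoc_results(results, pm,
                             file.path(cfg$out_dir, "association.tsv"),
                             maf = dm$maf, p_adj = p_adj)
  jsonlite::write_json(list(M = et$M, eigenvalues = et$eigenvalues,
                            var_lambda = et$var_lambda,
                            M_effective = et$M_effective,
                            n_probes_tested = n_probes_tested),
                       file.path(cfg$out_dir, "effective_tests.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- optional methylation stage ------------------------------------------
  if (isTRUE(cfg$methylation)) {
    mp <- seq(1e5, by = 100L, length.out = 500L)
    regions <- data.frame(name = c("high1", "high2", "bg"),
                          chrom = "chr1",
                          start = c(mp[50], mp[300], mp[400]),
                          end = c(mp[90], mp[340], mp[440]))
    track <- simulate_methylation(mp, "chr1", n_samples = 4,
                                  base_meth = 30,
                                  regions = data.frame(
                                    start = regions$start[1:2],
                                    end = regions$end[1:2],
                                    meth_mean = 900),
                                  seed = cfg$seed + 3L)
    rm_tab <- region_mean_counts(track, regions)
    flagged <- flag_high(rm_tab, cfg$meth_threshold)
    data.table::fwrite(rm_tab, file.path(cfg$out_dir, "methylation_regions.tsv"),
                       sep = "\t")
    data.table::fwrite(flagged, file.path(cfg$out_dir, "methylation_flagged.tsv"),
                       sep = "\t")
  }

  # --- manifest -------------------------------------------------------------
  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "cnvdosage",
                   version = as.character(utils::packageVersion("cnvdosage")),
                   seed = cfg$seed,
                   config_digest = unname(tools::md5sum(cfg_path)),
                   fitted_lrr_var = fit$emission$lrr_var,
                   n_probes_tested = n_probes_tested,
                   n_results = length(results),
                   top_p = if (nrow(tab)) min(tab$p_raw, na.rm = TRUE) else NA)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cfg$out_dir)
}
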