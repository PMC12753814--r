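# cnvdosage

Population-level copy-number variant (CNV) analysis from SNP-array
intensities, for statistical geneticists who want to treat common CNVs the
way GWAS treats SNPs: call them across a whole cohort at once, convert the
calls into per-probe *dosages*, and regress phenotypes or expression on
those dosages.

## What it does

SNP bead arrays report two intensity channels per probe: the Log-R ratio
(LRR, log-scale total intensity, which shifts with copy number) and the
B-allele frequency (BAF, the allelic ratio, whose cluster structure changes
with the allelic composition at each copy number). `cnvdosage` implements:

- **Intensity normalisation** — per-sample GC regression, robust
  local-regression ("genomic wave") removal, and LRR principal components
  for use as association covariates.
- **Population-shared-emission HMM calling** — a hidden Markov model over
  LRR/BAF with nine emission clusters at means
  `-4.5, -0.3, 0, 0.305, 0.528, 0.702, 0.8434, 0.9848, 1.126` (total
  copies 0–8, collapsed to call classes 0–4), shared variance capped at
  0.25, fitted by EM across *all samples jointly* (15 iterations by
  default), with exact forward–backward posteriors, Viterbi segments, and
  joint multi-cohort calling on an intersected probe grid.
- **Expected CNV genotypes ("countAll")** — the posterior-weighted mean
  copy number per probe, `countAll = Σ_k k·P(copy = k) ∈ [0, 4]`; e.g. a
  probe with P(copy 1) = 0.8 and P(copy 2) = 0.2 has countAll
  `1·0.8 + 2·0.2 = 1.2`. Includes stratification into
  deletion (< 1.7) / neutral / duplication (> 2.5), a mean-certainty
  filter (≥ 0.5), and carrier-based CNV allele frequencies.
- **MultiPhen-style association** — the standard univariate GLM
  (`phenotype ~ covariates + dosage`), the reverse (joint) regression
  (`dosage ~ phenotypes + covariates`, tested jointly), and backward
  variable selection; all three also run directly on corrected LRR.
- **Effective-tests Šidák correction** —
  `M_eff = 1 + (M − 1)(1 − Var(λ)/M)` from the eigenvalues λ of the trait
  correlation matrix, then `p_adj = 1 − (1 − p)^{M_eff}`.
- **cis CNV-eQTL scans** with a ±5-kb gene window and reciprocal-pair
  detection (dosage of gene A driving expression of gene B and vice
  versa).
- **Consensus NMF gene programs** — multiplicative-update NMF over
  expression matrices (per region, region-averaged `aveALL`, or
  concatenated full set), 50 restarts per rank, consensus clustering, and
  per-probe program occurrence counts across ranks 2–6.
- **Methylation region summaries** — per-region mean bisulfite read
  counts, flagging of high-methylation regions (mean methylated count
  > 700), and an exploratory periodic "methylation wave" score.
- **A synthetic-cohort generator** that plants CNV haplotypes at known
  allele frequencies, emits LRR/BAF with configurable GC and wave
  artefacts, and links phenotypes, expression and methylation tracks to
  the planted truth — so the whole pipeline is testable end to end
  without any external data.

## Worked example

```r
library(cnvdosage)

# a 200-sample cohort with a 41-probe deletion at allele frequency 0.30
pm   <- probe_map(sprintf("p%03d", 1:500), "chr1",
                  seq(1e5, by = 2000, length.out = 500), gc = 0.4)
loci <- cnv_locus("chr1", pm$pos[200], pm$pos[240], "deletion", 0.30)
coh  <- simulate_cohort(cohort_config(200, pm, loci, seed = 4))

fit <- em_fit(coh$intensities, init = emission_model(lrr_var = 0.08),
              iters = 15)
fit$emission$lrr_var
#> [1] 0.03988497

dm <- certainty_filter(dosage_matrix(fit$posterior))
dm$maf[220]                                   # probe inside the deletion
#> p220
#> 0.31
realized_allele_freq(coh)                     # planted truth
#> [1] 0.31

ph  <- simulate_phenotypes(dm$count_all[, 220],
                           trait_spec("seizures", beta = 0.6), seed = 5)
res <- assoc_univariate(ph$seizures, dm$count_all[, 220],
                        trait_name = "seizures")
res
#> assoc_result [univariate] traits=seizures stat=5.652 df=1 p=5.48e-08 n=200
sidak_adjust(res$p_raw, effective_tests(diag(1))$M_effective)
#> [1] 5.478667e-08
```

The EM fit recovers the emission variance (truth 0.04) from a 2× misspecified
start, the called minor allele frequency at the deletion probe equals the
realized planted frequency (0.31), and the dosage–phenotype association is
recovered at `p ≈ 5×10⁻⁸`.

`run_pipeline(list(seed = 1, out_dir = "out"))` runs the whole chain —
simulate → GC/wave correction → EM calling → dosage + filters →
association → Šidák correction — and writes TSV results plus a JSON
manifest with seeds and a config digest.

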