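# txeffort — transcription effort analysis for bulk expression profiles

Most transcriptome studies ask which genes change between conditions and
skip a more basic question: **how is a transcriptome's output distributed
across its genes?** `txeffort` is an R package for answering it. It is
aimed at researchers profiling organisms with modest genomic resources —
one library per condition, a draft genome, a KOG functional annotation —
who want a quantitative description of their transcriptional landscape
and a reproducible way to compare culture conditions.

The central statistic is **transcription effort**: the percentage of a
sample's total (per-million-normalized) transcription attributable to a
gene or gene group,

```
E(g, s) = 100 · x(g, s) / Σ_g' x(g', s)
```

On top of it the package provides:

* per-million normalization of count matrices (`normalize_per_million()`),
* ranked cumulative-effort curves and their logarithmic least-squares fit
  `effort ≈ a·ln(rank) + b` with R² (`cumulative_effort_curve()`,
  `fit_log_curve()`),
* concentration statistics — the minimal number of top genes reaching an
  effort threshold, expressed-gene fractions, the 20/80 Pareto summary
  (`min_genes_for_effort()`, `concentration_summary()`, `pareto_summary()`),
* effort decomposition by KOG functional category and by named gene sets
  in GMT format — pathways, secondary-metabolite clusters, aroma genes
  (`kog_profile()`, `gene_set_effort()`, `top_genes_in_set()`),
* pairwise condition comparisons: Pearson r and R² on linear per-million
  values plus a strict twofold-limit fold-change outlier rule with
  pseudocount (`pairwise_correlation()`, `fold_change_outliers()`),
* a calibrated synthetic-transcriptome generator (lognormal body +
  truncated Pareto tail, paired conditions, planted outliers, annotation
  and gene-set structure) with a parameter-recovery harness, so the whole
  pipeline is testable offline (`synthetic_config()`,
  `generate_transcriptome()`, `parameter_recovery_suite()`),
* an assembled report and a command-line front end
  (`effort_report()`, `inst/cli/txeffort.R`).

## Worked example

The package ships a small fixture: the per-million values of the ten most
expressed genes of a *Tuber borchii* mycelium transcriptome in four
culture media (WPG, WPGY, PDB, MPY), 18 genes in total.

```r
library(txeffort)
top10 <- read_expression_matrix(
  system.file("extdata", "tbo_top10_tpm.tsv", package = "txeffort"),
  unit = "per_million", partial = TRUE)

round(gene_effort(top10, "990338", "WPG"), 2)
#> [1] 5.97
sapply(sample_ids(top10), function(s) min_genes_for_effort(top10, s, 10))
#>  WPG WPGY  PDB  MPY
#>    3    3    7    8
```

The chaperone gene 990338 alone carries 5.97% of the WPG sample's entire
transcription, and 10% of the total is reached by just 3 genes in the
woody-plant media versus 7–8 in the complex media — the transcriptome is
strongly concentrated on a handful of genes.

The same analysis runs at genome scale on a synthetic transcriptome with
known structure:

```r
cfg <- synthetic_config(seed = 1)    # 12,346 genes, 4 conditions
pm  <- normalize_per_million(generate_transcriptome(cfg)$matrix)

fit_log_curve(cumulative_effort_curve(pm, "WPG"))
#> log fit: effort ~ 13.39 * ln(rank) + -21.37   (R^2 = 0.9866, n = 10869)
min_genes_for_effort(pm, "WPG", 80)
#> [1] 1846
pairwise_correlation(pm, "WPG", "WPGY")
#> WPG vs WPGY (all, n = 12346): r = 0.9962, r^2 = 0.9924
```

The cumulative curve is logarithmic to R² ≈ 0.99, fewer than 2000 of the
12,346 genes carry 80% of the transcription (≈15% of the catalog), and
the paired conditions correlate at r ≈ 0.996 — the heavy-tailed,
paired-design structure the generator is calibrated to emulate.

The command line exposes the same operations:

```sh
Rscript inst/cli/txeffort.R concentration \
  --matrix inst/extdata/tbo_top10_tpm.tsv --unit per_million --partial \
  --thresholds 10
# sample WPG: k = 3 genes reach 10% effort
# ...
```

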