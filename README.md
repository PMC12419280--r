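# extremoseq

Gene-burden analysis for **extreme-phenotype exome studies** of
quantitative traits. The package is aimed at analysts who have an
extreme-tail versus trait-normal cohort design — for example, extremely
low serum triglycerides (TG ≤ 0.45 mmol/L) against normal-TG controls —
with genotypes and variant annotations already called upstream, and who
want a reproducible path from those inputs to a ranked table of candidate
genes.

It provides, as composable functions:

* **Cohort selection and baseline statistics** — `select_extremes()`
  picks the trait-extreme and control groups (greedy sex/age matching
  optional); `baseline_table()` builds the per-trait comparison table with
  a Shapiro–Wilk normality gate choosing between the pooled-variance
  t-test (mean ± SD) and the rank-sum test (median, IQR), chi-square for
  sex; `pooled_mean()`, `cohens_d()` and `ttest_power()` cover the pooled
  column and the post hoc power of the design.
* **Variant classification** — `classify_region()` assigns the
  fifteen-category ANNOVAR-style region taxonomy (including the four
  cross-gene compound categories) and `classify_function()` the nine
  codon-resolved functional classes; `indel_length_table()` bins signed
  InDel lengths.
* **Prioritization cascade** — `run_cascade()` applies database flagging,
  deleteriousness (six predictor columns), population frequency (four
  databases, strict caps) and site-quality gates, with per-stage attrition
  reporting; every threshold lives in `filter_config()` and defaults to
  the published rules.
* **Gene burden** — `collapse_gene()` collapses each gene into per-group
  wild/het/hom (A, B, C) counts; `carrier_rate_statistic()` computes the
  carrier-rate ratio

  `r = (carriers_e / n_e) / (carriers_c / n_c)`

  truncated to three decimals (the extreme-group carrier count itself when
  controls have zero carriers); `fisher_two_sided()` is an exact
  hypergeometric test (doubling convention by default, minimum-likelihood
  by flag); `rank_genes()` produces the top-k table.
* **Synthetic cohorts** — `simulate_cohort()` generates phenotype tables,
  annotated variants and genotype matrices with *planted* gene-level
  carrier enrichment, so the whole pipeline is testable without any
  individual-level data. Determinism: one seed, byte-identical outputs.
* **IO and pipeline** — VCF 4.2 (GT), annotation TSV, phenotype CSV,
  quality-matrix TSV, gene-score TSV readers/writers; `run_pipeline()`
  runs cohort → cascade → burden end to end and writes a seed-stamped
  manifest. A thin CLI lives at `inst/cli/extremoseq.R`.

## Worked example

```r
library(extremoseq)

cfg <- simulation_config(
  n_extreme = 111, n_control = 102, n_genes = 50, sites_per_gene = 3,
  planted_genes = data.frame(gene = c("GENE0007", "GENE0031"),
                             p_extreme = c(0.10, 0.08),
                             p_control = c(0.005, 0.005),
                             hom_fraction = 0.03),
  seed = 42)
res <- run_pipeline(pipeline_config(out_dir = "out", seed = 42,
                                    simulate = cfg))
head(res$ranked, 5)
```

```
     gene snv_count carrier_samples a_extreme b_extreme c_extreme a_control b_control c_control  rate          p
 GENE0031         3              11       101         9         1       101         1         0 9.189 0.01452873
 GENE0007         3               8       104         6         1       101         1         0 6.432 0.08491771
 GENE0035         3               4       111         0         0        98         4         0 0.000 0.10194584
 GENE0002         3               3       108         3         0       102         0         0 3.000 0.27936644
 GENE0038         3               2       111         0         0       100         2         0 0.000 0.45628488
```

Both planted genes rank on top: GENE0031 has 10 carriers among 111
extreme-group samples against 1 of 102 controls, a carrier-rate ratio of
9.189 with an exact-test p of 0.015. The A/B/C columns are wild-type,
heterozygous and homozygous sample counts per group (samples with all
calls missing at a gene are dropped from that gene's table, so group
totals can sit just below the enrolled sizes).

The baseline table from the same run shows the selection working — TG
separates by construction, the other traits follow their configured
group distributions:

```
         trait      extreme      control       pooled       test            p
 sex (male, %)    53 (47.7)    49 (48.0)   102 (47.9) chi-square 1.000000e+00
           age 20.52 (1.90) 20.89 (1.67) 20.85 (1.85)   rank-sum 1.271192e-01
            tg  0.39 (0.05)  1.43 (0.18)  0.44 (1.03)   rank-sum 2.185382e-36
            tc  3.53 (0.60)  4.72 (0.32)  4.10 (0.77)          t 1.581866e-43
```

And the design's post hoc power at a conservative Cohen's d of 0.65:

```r
ttest_power(0.65, 111, 102, alpha = 0.05)
#> 0.9970864
```

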