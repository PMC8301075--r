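# dosagemeta

Cross-platform meta-analysis of case/control gene-expression studies, built
around the analysis design used to detect gene-dosage effects (e.g. trisomy
21) in induced pluripotent stem cells: several small studies on different
platforms — log-intensity microarrays and RNA-seq counts — that individually
have modest power but jointly pinpoint a consistent dysregulation signal.

## What it computes

**Per-study differential expression.** Array studies are tested with an
empirical-Bayes moderated t-statistic: the per-gene pooled variance s²_g
(df d_g) is shrunk toward a prior s²₀ estimated by moment matching on
log s²_g,

    s̃²_g = (d₀·s²₀ + d_g·s²_g) / (d₀ + d_g),
    t_g = log2FC_g / sqrt(s̃²_g·(1/n₁ + 1/n₂))  ~  t(d₀ + d_g).

Count studies are tested with a negative-binomial likelihood-ratio test
(library-size offsets, moment dispersion shrunk toward the all-gene median,
χ²₁ reference). Per-study DEGs are called at BH q ≤ 0.05.

**Signed Z-score meta-analysis.** Each study's two-sided p-value and fold
change direction become a signed Z,

    Z_i = sign(log2FC_i) · Φ⁻¹(1 − p_i/2),

combined with sample-size weights w_i = √n_i:

    Z = Σ w_i·Z_i / sqrt(Σ w_i²),   p = 2·(1 − Φ(|Z|)).

A gene is called significantly dysregulated when it (1) holds q ≤ 0.01 after
BH correction over all genes entering the meta-analysis, (2) is assayed in at
least two datasets, and (3) is non-significant in a between-study
heterogeneity test (Cochran's Q on the signed Z's; HetP > 0.05).

**Over-representation analysis.** Up-, down-, and combined gene lists are
tested against GMT gene-set collections with the upper-tail hypergeometric
test; each row reports Size, Expected = Size·(DEGs/universe), Observed,
Ratio = Observed/Expected, p, and BH-adjusted p.

**Bioenergetics utilities.** Closed-form companions for the mitochondrial
functional assays used alongside such transcriptomic studies: the
Grynkiewicz Fura-2 calibration [Ca²⁺] = K_d·β·(R−R_min)/(R_max−R) with
K_d = 224 nM, FCCP peak-over-basal percentages, Seahorse Mito Stress
respiratory indices (non-mitochondrial, basal, ATP-linked, maximal, spare),
and percent-of-control normalization.

A synthetic multi-platform generator (`simulation_config()`,
`simulate_studies()`, `write_fixture_set()`) emulates a published four-study
trisomy-21 iPSC compendium — two array studies (6/3 and 12/15 samples) and
two RNA-seq studies (3/4 and 3/3) with overlapping 16k–21k-gene panels — with
a known cis block at 1.5× dosage, so the whole pipeline is testable with no
external data.

## Worked example

A reduced-size demo (2.8k-gene universe, same four-study shapes):

```r
library(dosagemeta)

design <- default_study_design()
design$panel_size <- c(2000L, 1600L, 2100L, 1700L)
cfg <- simulation_config(studies = design, universe_size = 2800L, seed = 42)

fx  <- file.path(tempdir(), "fixtures")
out <- file.path(tempdir(), "run")
pc  <- fixture_pipeline_config(cfg, fx, out)
run <- run_pipeline(pc, quiet = TRUE)
run
```

    <pipeline_run> 4 studies -> 2778 genes entered, 171 included (102 up / 69 down)
    # A tibble: 4 × 3
      study_id  n_genes n_deg
      <chr>       <int> <int>
    1 S1_array     2000   119
    2 S2_rnaseq    1600    99
    3 S3_array     2100   129
    4 S4_rnaseq    1700   108
    top enriched (up): POS_chr21, SET_random_04, SET_random_10, SET_random_12, POS_chr8

2,778 gene symbols were measured in at least one study; 171 pass the
three-criterion filter (102 up, 69 down). The upregulated list is dominated
by the simulated trisomic chromosome, exactly as a dosage effect should
behave:

```r
format_ora_table(run$enrichment$up)[1:3, c("set","size","expected","observed","ratio","p_adjusted")]
```

    # A tibble: 3 × 6
      set            size expected observed ratio p_adjusted
      <chr>         <int>    <dbl>    <int> <dbl>      <dbl>
    1 POS_chr21        56     2.06       50 24.3    1.30e-69
    2 SET_random_04   286    10.5        16  1.52   1   e+ 0
    3 SET_random_10   229     8.41       12  1.43   1   e+ 0

Of the 56 chr21 genes in the background, 50 are recovered in the
upregulated list against 2.06 expected by chance. `tidy()` and `glance()`
methods expose every result as a tibble; `autoplot()` draws the
volcano-style meta plot and the ORA dot plot. A thin command-line wrapper
(`inst/cli/dosagemeta.R`) exposes `simulate`, `validate`, `de`, `meta`,
`enrich`, `calcium`, `ocr`, and `run-all` subcommands.

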