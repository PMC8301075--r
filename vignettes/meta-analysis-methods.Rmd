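---
title: "Methods: signed Z-score meta-analysis of gene-dosage expression studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed Z-score meta-analysis of gene-dosage expression studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosagemeta)
```

## The problem

Trisomy 21 adds a third copy of chromosome 21, so genes on that chromosome
are expected near 1.5× expression (a *cis* dosage effect), with sparser,
heterogeneous *trans* effects elsewhere. Individual iPSC expression studies
of this contrast are small (3–15 samples per arm) and sit on different
platforms, so no single study is decisive. dosagemeta implements the
standard remedy: analyse each study with a platform-appropriate
differential-expression test, harmonize identifiers to shared gene symbols,
and combine the per-study evidence with a signed, sample-size-weighted
Z-score meta-analysis, followed by over-representation analysis of the
resulting gene lists.

## Per-study differential expression

**Arrays.** For log2 intensities, the two-group contrast is tested with an
empirical-Bayes moderated t-statistic. With per-gene pooled variance
$s_g^2$ on $d_g = n - 2$ df, the moderated variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and
$t_g = \widehat{\Delta}_g / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$ on
$d_0 + d_g$ df. The prior $(d_0, s_0^2)$ is estimated by moment matching on
$\log s_g^2$: under the hierarchical model, $s_g^2 \sim s_0^2
F(d_g, d_0)$, so the mean and variance of $\log s_g^2$ identify $s_0^2$ and
$d_0$ through digamma/trigamma functions; the trigamma inverse is solved by
Newton iteration. When the observed log-variance spread is no larger than
the sampling noise, $d_0$ is effectively infinite; we cap it at $10^6$,
which is numerically the complete-shrinkage normal-reference limit. In the
test suite this estimator is cross-checked against the established
empirical-Bayes implementation on shared data and agrees to near machine
precision, while remaining an independent implementation; the $d_0 = 0$
limit is verified against the ordinary pooled t-test to $10^{-10}$.

**Counts.** RNA-seq studies are tested with a negative-binomial
likelihood-ratio test. Library-size factors are column-sum ratios to the
geometric-mean library and enter as offsets. The NB dispersion is a per-gene
moment estimate from pooled within-group variances of normalized counts,
$\hat\varphi_g = \max\{0, (v_g - m_g)/m_g^2\}$, shrunk toward the all-gene
median with weight 0.8 — a deliberately strong shrinkage that matches the
generator's constant-dispersion model and keeps the per-gene test close to
nominal at n = 6–27. Group means under the null and alternative are fitted
by a Newton iteration on the scalar log-mean, vectorized over genes, and
$2\,\Delta\ell$ is referred to $\chi^2_1$. At dispersion zero the model is
exactly Poisson. log2 fold changes use normalized group means with a 0.5
pseudo-count so they remain finite. This is a documented simplification of
quasi-likelihood NB pipelines (no tagwise APL dispersions, no QL F-test);
its per-gene type-I error is verified by simulation to lie in roughly
[0.03, 0.07] at nominal 0.05, and its fold changes track an established NB
engine closely in the tests. The meta-analysis stage consumes only
(log2FC, p, n) and is agnostic to this engine choice.

All p-values are clamped to $[10^{-300}, 1]$ before any quantile transform
so downstream normal quantiles stay finite.

## Harmonization

Probes map to gene symbols through a probe map; unmapped probes are dropped
with a logged count. Multi-probe genes collapse under a configurable rule —
default `max_mean` (keep the highest-average-expression probe, common array
practice), with `first` and element-wise `median` as alternatives. Symbols
are opaque case-sensitive strings; alias resolution is out of scope. Genes
measured in a single study are *retained* through the meta-analysis and only
excluded by the inclusion filter, so the per-criterion exclusion tallies are
meaningful.

## Meta-analysis and the inclusion filter

Each study contributes $Z_i = \mathrm{sign}(\mathrm{log2FC}_i)\,
\Phi^{-1}(1 - p_i/2)$; the combined score is $Z = \sum_i w_i Z_i /
\sqrt{\sum_i w_i^2}$ with $w_i = \sqrt{n_i}$ (an effective-sample-size
option $w_i = \sqrt{4/(1/n_{case} + 1/n_{ctrl})}$ is available). A gene is
included when (1) its BH q over all genes entering the meta-analysis is
$\le 0.01$, (2) it is assayed in $\ge 2$ datasets, and (3) its
heterogeneity p exceeds 0.05. Ties resolve exactly as the thresholds read:
$\le$ for q, $>$ for HetP.

Two points were genuinely open and are our design decisions:

* **Heterogeneity statistic.** The external method the filter descends from
  does not publish its formula. We use Cochran's Q on the signed Z's with
  unit variances (equal inverse-variance weights), $Q = \sum_i (Z_i - \bar
  Z)^2 \sim \chi^2_{k-1}$. It is swappable behind `heterogeneity_test()`.
  Note the filter's intrinsic cost: under perfect homogeneity it still
  excludes 5% of true positives by construction.
* **FDR universe.** Whether BH preceded or followed the two-dataset
  restriction is not stated; the default computes BH over all genes with
  $k \ge 1$ and filters afterwards (`fdr_scope = "all"`), matching the
  order in which the criteria are listed; `fdr_scope = "min_studies"` is
  the alternative.

## Over-representation analysis

For a gene set with `size` members in the background universe and
`observed` members in a DEG list of size $n$ from a universe of size $N$:
`expected` $= \mathrm{size} \cdot n/N$, `ratio` = observed/expected, and
$p = P(X \ge \mathrm{observed})$, $X \sim$ Hypergeometric$(N,
\mathrm{size}, n)$, with BH adjustment across the collection. The ratio of
expected to size is a single background proportion across all rows — the
property that makes a published ORA table's columns mutually consistent and
lets one reconstruct its background size from any row. The default universe
is the genes that entered the meta-analysis intersected with the genes
annotated in the collection (`universe_policy = "annotated"`), because
published ORA backgrounds are typically annotation-limited; `"entered"`
uses every gene in the meta-analysis. Permutation-based combined enrichment
scores are intentionally not implemented; the hypergeometric arithmetic is
the reproducible core.

## The synthetic-data generator

The generator emulates the statistical structure of a published four-study
T21-iPSC compendium: studies of 6/3, 3/4, 12/15 and 3/3 case/control
samples on two platforms, with panels of 20,534 / 16,214 / 21,037 / 17,251
genes drawn from a 28,000-symbol universe (union coverage ≈ 27.7k). Every
gene has a latent log2 abundance $b_g \sim N(9, 1)$ shared by both
platforms; arrays observe $b_g$ + group effect + $N(0, \sigma)$, counts
observe NB with mean $2^{b_g} \cdot \mathrm{fold}^{\mathrm{group}} \cdot
\mathrm{libsize}$ and constant dispersion. The cis block (2% of the
universe, labelled chr21) carries a linear 1.5× fold in cases — dosage
applied on the linear scale before noise; trans genes (8% of the rest)
carry $N(0, 0.5)$ log2 effects. Probe maps add duplicate probes (rate 0.1,
independently re-measured rows) and unmapped control probes (2%).

The unpublished noise parameters were fixed once, a priori, by an analytic
power calculation: for a cis gene, the expected per-study signed Z is
$0.585/(\sigma_{\mathrm{eff}}\sqrt{1/n_1 + 1/n_2})$, and defaults were
chosen so each study contributes comparable evidence ($|E[Z]| \approx
4$–$5$): array residual SD 0.18 (6/3 study) and 0.30 (12/15 study,
a different platform), NB dispersion 0.012 (biological CV ≈ 0.11, typical
of isogenic cell-line clones). Comparable per-study evidence mirrors the
fact that all four real studies detected the dosage signal, and it keeps
true cis genes from being systematically discarded by the heterogeneity
criterion — a real failure mode of Z-based heterogeneity filters when study
power varies widely, which users analysing real data should keep in mind.

What the generator does *not* emulate: batch effects, paired designs,
covariates, gene–gene correlation, mean–variance trends on arrays,
count-depth-dependent dispersion, and annotation ambiguity beyond simple
duplicate/unmapped probes. Passing tests therefore demonstrate the
pipeline's arithmetic and its operating characteristics under a clean
dosage model, not robustness to those real-data complications.

## Bioenergetics computations

The Fura-2 calibration uses the Grynkiewicz equation
$[\mathrm{Ca}^{2+}] = K_d\,\beta\,(R - R_{min})/(R_{max} - R)$ with
$K_d = 224$ nM for Fura-2; $\beta$ defaults to 1 with a warning when a
record does not supply it. Ratios at or above $R_{max}$ are a saturation
error rather than an infinite concentration. OCR indices follow the
standard Mito Stress definitions; whether the basal reading is the last
pre-oligomycin measurement or the segment mean is configurable
(`baseline_stat`, default `"last"`), since instrument conventions differ.
Percent-of-control normalization divides by the control mean and multiplies
by 100, so the control group averages exactly 100. Group statistics on the
resulting per-well indices are left to general-purpose tools.

## Numerical and testing choices

Degenerate inputs never raise mid-pipeline: zero-variance array genes and
all-zero count genes are flagged with p = 1; a single-study gene gets
Q = 0, HetP = 1, flagged. Newton steps in the NB fit are clamped to ±3 on
the log scale for stability at extreme starting values. The test suite runs
the reduced designs (universes of 500–3,000 genes with proportionally
shrunk panels) for module tests, and exercises the full-size default design
once in the end-to-end checks; null-calibration checks use 2,000 genes and
20 seeds. These sizes were chosen so the whole suite completes in well
under a minute of compute per file while keeping Monte-Carlo error far
inside the asserted tolerances.

## Known limitations

* The heterogeneity formula may differ from the external meta-analysis
  tool's internal computation; only the filter's contract (HetP > 0.05) is
  preserved.
* The NB engine is a calibrated simplification, not a re-implementation of
  quasi-likelihood F-tests; for very small counts or strong outliers the
  established engines are preferable.
* No alias/ortholog resolution; harmonization assumes a consistent symbol
  vocabulary across probe maps.
* Published headline gene counts from the real compendium depend on the
  original data and are emulated only qualitatively by the generator.
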