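---
title: "Curve group analysis: models, choices and operating characteristics"
author: "curvegroup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curve group analysis: models, choices and operating characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvegroup)
```

## The statistical problem

In a prospective cohort with a nested case-control design, blood samples are
collected years before any diagnosis. Each eventual case is matched to a
cancer-free control (here: on birth year and sampling batch), and laboratory
processing keeps each pair together, so the analysis unit is the pair and
batch effects cancel within it. For gene $g$ and pair $p$ the datum is the
log2 expression difference $X_{g,p}$ between case and control. Pairs carry a
stratum $s$ (a clinical subgroup) and a time period $t \in \{1,\dots,T\}$,
with $t = 1$ the period nearest diagnosis.

Prediagnostic signals are weak and spread over many genes: no single gene is
expected to reach significance after multiple-testing correction. Curve
group analysis therefore tests *collective* hypotheses — is there development
over time in a stratum? does development differ between strata? — using gene
counts and gene-set averages as statistics, and permutation for inference.

## Curve groups and inclusion criteria

Within stratum $s$, gene $g$ has per-period means $\bar X_{g,t,s}$. Its
*curve group* is the strict ordering of these means, written as the rank
string read from the farthest to the nearest period; with $T = 3$ the six
groups are 123, 132, 213, 231, 312, 321, and "123" means monotone increase
toward diagnosis. Exactly tied means (probability zero for continuous data,
but possible in synthetic edge cases) yield no label: groups are defined
only for strict orderings, and `ordering_label()` returns `NA`
deterministically rather than breaking the tie arbitrarily.

A labelled gene becomes a *member* of its group only if its extreme period
means genuinely differ, judged by a two-sided Welch $t$-test between the
pair values of the smallest-mean and largest-mean periods:

* **criterion 1** — membership if $p_{g,c} < \alpha$ (default
  $\alpha = 0.01$); used for the within-stratum trend tests. The test is
  two-sided because the compared periods are data-chosen extremes, making a
  one-sided test anti-conservative in direction.
* **criterion 2** — the $M$ genes with smallest $p_{g,c}$ *among the genes
  whose ordering is $c$* (default $M = 100$); used to select gene sets for
  the curve-group variable. Restricting the ranking to ordering-$c$ genes is
  an interpretive choice: membership of a group presupposes carrying its
  ordering. Ties at the $M$-th smallest $p$ break by lexicographic gene id,
  for determinism. When fewer than $M$ genes carry the ordering, all are
  taken and downstream averages divide by the actual count.

Degenerate zero-variance samples are resolved by the continuous limit:
equal means give $p = 1$, unequal means $p = 0$.

## The permutation tests

All p-values are $(K+1)/(N+1)$ with $K$ the number of the $N$ randomized
datasets whose statistic is at least as extreme as the observed one (ties
count as extreme, a conservative choice; the attainable minimum is
$1/(N+1)$; default $N = 1000$). Randomization permutes *labels*, never the
expression vectors themselves, so each pair's joint gene vector — and hence
the inter-gene correlation structure — is preserved under the null. Counts
per period and per stratum are preserved exactly (sampling without
replacement), matching a design with fixed cell sizes.

* **Trend within a stratum** (`trend_test_stratum()`): statistic = member
  count, globally and per group, under criterion 1. Null: permute the
  stratum's pairs between periods; redefine the curve groups from scratch
  for every randomization. The seven tests (global + one per group for
  $T = 3$) share one null ensemble: the ensemble is a property of the
  randomization scheme, sharing makes the p-values mutually consistent, and
  it halves the computation. "Expected counts" are the means of the null
  counts from the same ensemble — the only null summary available. No
  multiple-testing adjustment is applied across the seven tests: the design
  aggregates over genes precisely to avoid per-gene testing, and raw
  permutation p-values are reported.
* **Curve-group variable between strata** (`z_strata_test()`): the variable
  $Z_{c,s,p}$ is the mean of $X_{g,p}$ over the criterion-2 set $G_{c,s}$,
  computed for every pair regardless of stratum. The observed statistic is
  the two-sample Welch $t$ between the two strata's $Z$ values (all periods,
  or one period); the choice of Welch $t$ is a design decision — the
  comparison statistic is unnamed in the method's description, but the
  permutation null makes the distributional form immaterial, and Welch is
  consistent with the other two-sample steps. Null: permute pairs between
  the two strata within each period and *re-select* $G_{c,s}$ from the
  permuted data each time, so selection bias is inside the null. The
  p-value is two-sided on $|t|$.
* **$L_k$ between strata** (`lk_test()`): per gene and period the Welch
  $t$-statistic $T_{g,t}$ between strata; $F_g = \sum_t w_t |T_{g,t}|$;
  $L_k$ = sum of the $k$ largest $F_g$. Default equal weights $w_t = 1/T$;
  `"proportional"` weights $n_t / \sum n_t$ and custom vectors are
  available. The default grid $k \in \{10, 50, 100, 200, 500, 1000\}$
  (clipped to the gene count) spans the regime where diffuse signal
  accumulates. Genes with zero variance in both strata and unequal means
  have infinite $t$; they are flagged, excluded from the top-$k$ sums to
  keep $L_k$ finite, and reported in the result.

Reproducibility: each randomization $i$ draws its permutation from a seed
derived deterministically from the master seed and $i$
(`derive_seed()`), so results are independent of execution order and
increasing $N$ extends rather than reshuffles the ensemble. Reports
re-computed with the same seed are bit-for-bit identical, and every CLI run
writes a manifest from which `rerun` reproduces outputs byte-identically.

## Preprocessing

The generic steps for paired two-channel-free microarray data are provided:
quantile normalization on the original scale (every column forced to the
reference distribution of row-wise means of the column-sorted matrix; tied
values share the mean reference value over their rank span, which makes the
operation deterministic and idempotent on tie-free data), a presence filter
retaining features detected in at least $\lceil f \cdot n \rceil$ samples
(1 % of 882 individuals gives 9), collapse to one probe per gene (highest
mean intensity wins, ties to the lexicographically smallest probe id — the
selection rule is otherwise unconstrained, and this one is common,
deterministic and reproducible), and the paired log2 differences themselves.
Missing values are rejected at load time rather than imputed: every
downstream statistic assumes a complete matrix, and silent imputation would
distort the permutation null.

## The synthetic-data generator

`generate_dataset()` draws
$$X_{g,p} = \mu_{g,t(p),s(p)} + b_g f_p + \varepsilon_{g,p},$$
with $\varepsilon \sim N(0, \sigma^2)$, a pair-level latent factor
$f_p \sim N(0,1)$ with loadings $b_g \sim N(0, \tau^2)$, and planted means
$\mu = \delta(\mathrm{rank}_c(t) - (T+1)/2)$ for a signal gene with label
$c$ (centred so the marginal mean is zero and only the time effect is
planted), zero for background genes. A constant `stratum_shift` in selected
strata supports strata-difference scenarios. This is the simplest mechanism
with the two properties the method relies on: null genes fluctuating around
a constant over time, and genes correlated within a pair (which the
label-permutation null must preserve).

What it does **not** emulate: heavy-tailed or gene-specific noise scales,
more than one correlation factor, probe-level artefacts, batch effects
(removed by the paired design), drop-out, or missingness. Passing
calibration and power checks on these data therefore shows the inferential
machinery is sound under the design's assumptions — not that real cohort
data meet those assumptions.

Default study conditions used throughout the test-suite calibration and the
acceptance script: 500 genes, one or two strata with 20 pairs per stratum
per period, $T = 3$, noise SD 1 (calibration) or 0.5 with 50 signal genes
(power), 199 randomizations per test and 200 Monte-Carlo replicates per
rate. These sizes give Monte-Carlo standard errors around 0.015 on a 5 %
rate while keeping a full calibration run in minutes on one CPU; they are
the generator's fixed conditions, not tuning knobs.

## Known limitations

* The number of curve groups grows as $T!$: four periods already need 24
  groups, diluting per-group counts; labels are limited to single digits
  ($T \le 9$), far beyond practical designs.
* The trend statistic counts member genes, so it has no notion of effect
  direction beyond the ordering; a stratum where half the signal genes rise
  and half fall still rejects globally but spreads counts over groups.
* Criterion-2 selection inside every randomization makes the $Z$ test
  $O(N)$ assignment runs; this is vectorized but still the dominant cost.
* Permutation p-values are discrete: with $N = 199$ the attainable levels
  are multiples of $1/200$, which the calibration envelopes account for.
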