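# curvegroup

Permutation-based **curve group analysis** of longitudinal gene expression
from matched case-control pairs.

In prospective cohorts with a nested case-control design, each future case is
matched to a healthy control and the analysis unit is the pair: for gene *g*
and pair *p* the datum is the log2 expression difference
*X*<sub>*g,p*</sub> = log2(case) − log2(control). Pairs carry a *stratum*
(e.g. lymph node status, detection category) and a *time period*
*t* = 1, …, *T* (1 = nearest diagnosis). The scientific questions are: does
differential expression *develop over time* before diagnosis within a
stratum, and does that development *differ between strata*? Individual gene
effects are typically far too weak to detect; curve group analysis aggregates
weak signals over many genes without per-gene multiple testing.

## The method

**Curve groups.** Within a stratum *s*, gene *g* has per-period means
*X̄*<sub>*g,t,s*</sub>. Its curve group is the strict ordering of these
means, written as a string of ranks read from the farthest to the nearest
period: with *T* = 3 there are 3! = 6 groups (123, 132, 213, 231, 312, 321);
"123" is a monotone increase toward diagnosis. A gene joins its group only if
the smallest and largest period means differ by a two-sided Welch
(unequal-variance) t-test, either with p below α (criterion 1, default
α = 0.01) or by being among the *M* smallest p-values of its group
(criterion 2, default *M* = 100).

**Trend test within a stratum.** The global statistic is the total number of
member genes across all groups; each group's count gives a per-group
statistic (7 tests for *T* = 3). The null distribution randomizes the
stratum's pairs between time periods, redefining curve groups for every
randomization; each pair's gene vector stays intact, so inter-gene
correlation is preserved. P-values are (K+1)/(N+1), K = null statistics at
least as extreme out of N randomizations (default N = 1000).

**Comparing two strata.** Two statistics:

* the curve-group variable
  *Z*<sub>*c,s,p*</sub> = |G<sub>c,s</sub>|⁻¹ Σ<sub>g∈G<sub>c,s</sub></sub> *X*<sub>*g,p*</sub>,
  the per-pair mean over the genes G<sub>c,s</sub> selected for group *c*
  from stratum *s* by criterion 2 — computed for pairs of *any* stratum and
  compared between the two strata (Welch t, two-sided permutation p);
* the curve-group-free statistic
  *L*<sub>*k*</sub> = Σ<sub>g∈G<sub>k</sub></sub> *F*<sub>*g*</sub> with
  *F*<sub>*g*</sub> = Σ<sub>t</sub> *w*<sub>t</sub> |*T*<sub>*g,t*</sub>|,
  the sum of the *k* largest per-gene weighted absolute between-strata
  t-statistics (default equal weights *w*<sub>t</sub> = 1/*T*).

Both null models randomize pairs between the two strata within each period
and re-run the whole selection pipeline per randomization.

## Worked example

```r
library(curvegroup)

cfg <- simulation_config(
  n_genes = 300,
  design = uniform_design("node_positive", n_periods = 3, pairs_per_period = 20),
  n_signal = 30, signal_labels = "123", delta = 0.6,
  noise_sd = 0.8, factor_loading_sd = 0.3, seed = 2024)
d <- generate_dataset(cfg)

trend_test_stratum(d$x, d$annotation, "node_positive",
                   alpha = 0.01, n_perm = 999, seed = 7)
#> Within-stratum trend test, stratum 'node_positive'
#>   inclusion criterion 1, alpha = 0.01 ; N = 999 randomizations, seed = 7
#>   label observed expected p_value
#>  global       31      7.6   0.001
#>     123       28      1.3   0.001
#>     132        1      1.2   0.668
#>     213        2      1.2   0.333
#>     231        0      1.2   1.000
#>     312        0      1.3   1.000
#>     321        0      1.4   1.000
```

30 genes were planted with a monotone increase toward diagnosis (label
"123", spacing 0.6 log2 units per rank) among 270 null genes. The test
recovers 28 of them in group 123 against an expected null count of about
1.3, and the global count of 31 members against about 7.6 expected gives the
smallest attainable p-value, 1/(999+1). The other groups stay at their null
expectation.

The same analyses run from the shell via the CLI (a thin wrapper in
`inst/cli/curvegroup`): subcommands `simulate`, `preprocess`, `assign`,
`trend-test`, `strata-test`, each writing a JSON manifest that `rerun
--manifest` replays byte-identically.

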