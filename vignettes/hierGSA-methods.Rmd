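---
title: "Hierarchical set/subset testing with a diagonal T2 and a residual bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical set/subset testing with a diagonal T2 and a residual bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierGSA)
```

## The problem

Pathway databases partition genes (or CpGs, proteins, ...) into pre-defined
*sets*, and each set further into biologically meaningful *subsets* — e.g. a
signalling pathway split by the processes its genes take part in. Given a
two-group (or paired) expression study, a biologist wants to know which sets
are differentially expressed, and, inside each significant set, which of its
subsets carry the signal — with a guarantee on the overall family-wise error
rate (FWER) across *all* sets and subsets tested. hierGSA implements a
self-contained procedure for exactly this: every decision uses only the
genes of the subset under test, not a comparison against the rest of the
genome.

## The statistic

For a subset of p genes, with group means $\bar{x}_1, \bar{x}_2$, per-gene
sample variances on the diagonals of $S_1, S_2$ (denominator $n_i - 1$),

$$T^2_{diag} = (\bar x_1 - \bar x_2)'
  \left\{\tfrac{Diag(S_1)}{n_1} + \tfrac{Diag(S_2)}{n_2}\right\}^{-1}
  (\bar x_1 - \bar x_2)
  = \sum_{g=1}^{p} \frac{(\bar x_{1g} - \bar x_{2g})^2}
                        {s^2_{1g}/n_1 + s^2_{2g}/n_2},$$

the sum of squared per-gene Welch $t$ statistics. Dropping the off-diagonal
covariance terms is deliberate: the classical Hotelling $T^2$ requires
inverting a $p \times p$ covariance matrix, which is singular whenever
$p \ge n_1 + n_2 - 2$ — the common case for gene sets — and unstable well
before that. The diagonal form needs no inversion, stays defined for any
$p$, and allows the two groups *unequal* variances. `full_t2()` implements
the full-covariance analogue
$(\bar x_1-\bar x_2)'(S_1/n_1+S_2/n_2)^{-1}(\bar x_1-\bar x_2)$ for
comparison; it refuses ill-conditioned inputs (2-norm condition number above
`cond_ceiling`, default 1e12) rather than resorting to a pseudo-inverse,
because a silent Moore–Penrose fallback changes the statistic's meaning.

For paired designs the package uses the one-sample analogue on per-pair
differences, $\sum_g n\,\bar d_g^2 / s^2_{d,g}$. The two-sample form does
not dictate this choice uniquely; we adopt the one-sample-on-differences
form as the natural modification and treat it as a design assumption.

## The null distribution: a residual bootstrap

Gene expression is neither normal nor homoscedastic, and genes within a
subset are correlated, so no usable closed-form null exists. The package
simulates the null by a residual bootstrap:

1. form the weighted grand mean
   $\bar{\bar X} = (n_1 \bar X_1 + n_2 \bar X_2)/(n_1+n_2)$;
2. replace sample $j$ of group $i$ by
   $X^*_{ij} = \bar{\bar X} + (X_{ij} - \bar X_i)$ — the *null population*,
   in which both groups have mean exactly $\bar{\bar X}$ but keep their own
   dispersion and correlation structure;
3. draw, per replicate, $n_i$ subjects with replacement *within* each group
   from this population and recompute the statistic for every subset.

Residuals are taken once, against the original group means, and are not
re-centred per resample. Resampling within groups is the point: pooling the
two groups (the "standard" bootstrap) imposes identical distributions on
both groups under the null and breaks down when the groups share means but
differ in covariance — the heteroscedastic null that this procedure is
designed to survive.

The p-value is $(1 + \#\{b : T^{*}_b \ge T_{obs}\})/(B+1)$. The add-one
convention keeps p-values strictly positive and the test valid; the
smallest attainable p-value is $1/(B+1)$, which matters below.

All subsets are evaluated on the *same* $B$ resamples. This leaves every
marginal p-value untouched (each subset's null distribution is identical to
what a private resampling stream would give) and costs $O(B)$ resampling
instead of $O(B \cdot \#subsets)$; the Bonferroni argument below holds
under arbitrary dependence, so sharing is safe for error control. We also
verified empirically that it is not conservative in practice: at the
reference null condition (normal, homoscedastic, $n=40$, $K=5$) the
simulated FWER with shared resamples was 0.043 (SE 0.006, 1000 runs,
B = 5000), indistinguishable from the nominal behaviour — as expected,
since the FWER is a union of rare events and is nearly additive in their
marginal probabilities whatever their joint law.

Degenerate resamples (a gene drawn constant within a group at small $n$)
are handled by flooring bootstrap variances at $10^{-12} \times$ the
largest observed gene variance; observed statistics are never floored — a
gene with zero variance in both groups is a hard error instead, because
the statistic is simply undefined there.

## The hierarchical decision rule

With $K$ sets, set $S_k$ holding $m_k$ subsets with raw bootstrap p-values
$P_{k,j}$:

* set-level adjusted p-value: $P^*_k = \min_j \, m_k P_{k,j}$ (capped at 1);
* declare set $S_k$ significant iff $P^*_k < \alpha/K$;
* declare subset $S_{k,j}$ significant iff $P_{k,j} < \alpha/(K m_k)$.

Both inequalities are strict, exactly as the rule is stated. A set is
significant precisely when one of its subsets is, and a union bound over
the $K m_k$ subset tests shows the overall FWER is at most $\alpha$ under
any dependence. Using the subset structure is what buys power: evidence
concentrated in a small subset is diluted in a whole-set statistic but
survives the $m_k$-fold correction.

The FDR variant (`hierarchical_fdr_test()`) replaces the set-level rule
with Benjamini–Hochberg step-up at level $\alpha$ on the $K$ adjusted
p-values (selection by $\le$, the standard step-up convention). The rule
for subsets inside the $R$ selected sets is not determined by the set-level
construction; we adopt the two-stage threshold
$P_{k,j} \le R\alpha/(K m_k)$, scaling the subset cut by the number of
selected sets, and label the report `"fdr-two-stage"` so the choice is
visible.

## Choosing B

The deepest subset threshold is $\alpha/(K \max_k m_k)$, while the smallest
attainable bootstrap p-value is $1/(B+1)$. If $1/(B+1)$ exceeds the
threshold, those subsets can never be rejected no matter how strong the
signal, and both FWER and power are silently biased down. With
$\alpha = 0.05$, $K = 5$ and $m_k$ up to 16, the threshold is
$6.25 \times 10^{-4}$, so $B \ge 1600$; the default $B = 5000$ keeps every
threshold attainable with effective levels within a few percent of nominal.
This is why the simulation work below reduces the number of *runs*, never
the number of bootstrap replicates.

## The simulation framework

`run_study()` estimates the FWER ($\delta = 0$) or power ($\delta > 0$) of
the complete pipeline. Each run redraws the whole design: $m_k \sim$
U$\{5..16\}$ subsets per set, subset sizes $\sim$ U$\{5..10\}$ (disjoint
gene blocks — overlap is permitted in analysis mode, but the simulation
design prescribes none), per-gene SDs from $\{0.1, 0.5, 1, 1.25, 1.5\}$ and
per-subset intraclass correlations from $\{0, 0.25, 0.5, 0.75, 0.9\}$.
Four families emulate the kinds of data the method targets:

* **normal** — intraclass-correlated multivariate normal per subset block;
  heteroscedastic mode draws each group's $\sigma$/$\rho$ independently;
* **lognormal** — exponentiated normal draws, equal covariances (skewed,
  positive intensities);
* **beta** — $Z_g = U_g/(U_g + V)$ with $U_g \sim \chi^2(a_g)$,
  $a_g \in \{4,5\}$ per gene, and one $V \sim \chi^2(b)$, $b \in \{1,2\}$,
  shared per subset: marginally Beta$(a_g/2, b/2)$ with means between
  $4/6$ and $5/6$, the shared denominator inducing within-subset
  dependence — a methylation-proportion emulator. The df draws are shared
  between groups (independent draws would shift the means and break the
  null), and the family has no mean-shift parameter, so it appears only in
  FWER mode;
* **mixture** — $0.2\,N(\mathbf 0, \Sigma_1) + 0.8\,N(\mathbf 1, \Sigma_2)$
  per sample vector; we read the two covariances as the two mixture
  components (independent draws in heteroscedastic mode, the same mixture
  in both treatment groups), which is the reading under which the null
  holds by construction.

The treatment group shifts *every* gene's mean by $\delta$ (the
all-alternative reading of the power design; on the log scale for the
lognormal family). Per-run seeds derive from the master seed, so a
configuration reproduces bit for bit, and paired-seed comparisons (e.g.
diagonal vs full statistic in `run_table3_comparison()`, which fixes
subset size — we use 20 genes with $n = 40 > 20$ so the full statistic is
well defined) see identical data.

What the generators do *not* emulate: mean-variance coupling of counts,
outliers/contamination, batch effects, between-subset correlation, and
realistic pathway overlap. Tests passing under these generators show
correct error control under heteroscedastic, skewed, bounded and mixture
data with block dependence — not under every failure mode of real
experiments.

## What the simulation study shows — and two caveats

With the default design the test suite and `scripts/acceptance.R` find the
procedure's FWER at $\alpha = 0.05$, $n = 40$, $K = 5$ close to nominal for
normal data (homoscedastic and heteroscedastic) and for the beta family,
and *conservative* — never inflated — everywhere else. Two structural
effects are worth understanding:

1. **Resampling conservatism under extreme shapes.** For heavily skewed or
   strongly separated bimodal data, resamples that duplicate an extreme
   observation inflate the upper tail of the bootstrap null; e.g. for iid
   log-normal data with log-scale SD 1.5 ($n = 40$), the bootstrap null's
   99.9% quantile is roughly three times the true null's, and the
   single-subset p-value ECDF at 0.05 drops to about 0.02. The same
   mechanism affects the mixture family when small-$\sigma$ genes put the
   two components many SDs apart. Error control is preserved (the test
   only loses power); practitioners with strongly skewed intensities may
   prefer to log-transform before testing.

2. **Power saturation under absolute shifts.** The power design shifts
   every treatment-group gene by the same absolute $\delta$ while per-gene
   SDs range down to 0.1, so $\delta = 0.5$ is already a 5-SD effect on
   the smallest-variance genes and the probability of at least one
   rejection saturates at 1 even at $n = 10$. Simulated power is therefore
   informative mainly through its dose–response *shape* at much smaller
   $\delta$, or under standardized effect sizes (shift $\delta \sigma_g$),
   which delay but do not remove the saturation. The fixed-subset-size
   diagonal-vs-full comparison inherits this: at $\delta \ge 0.5$ both
   arms sit at power 1 and only the null ($\delta = 0$) condition and the
   non-strict dominance comparisons are informative.

## Numerical and scale choices

* Variance denominator $n_i - 1$ everywhere ("usual" sample covariance).
* The bootstrap engine (C++) accumulates means and variances in one sweep
  per resample; all resample indices are drawn from R's RNG under
  `set.seed(seed)`, sequentially, so results are independent of the
  evaluation order and reproducible from the single seed.
* Reported simulation scale: the reference design is $R = 1000$ runs and
  $B = 5000$ bootstrap replicates. The package's test suite and the
  acceptance script run $R$ of 60–300 (stated with each result, tolerances
  of 3 binomial SEs at the executed $R$) while keeping $B = 5000$ for the
  threshold-attainability reason above; the fixed-subset-size comparison
  uses $B = 2000$ ($1/(B+1) = 5.0\times10^{-4} < 6.25\times10^{-4}$, still
  attainable).
* Adjusted p-values can exceed 1 as written; they are capped. The report
  also carries $K P^*_k$ (capped) as an "overall" ranking scale; decisions
  derive only from the quoted rules.

## Known limitations

* The procedure tests pre-defined subsets only; it does not discover
  data-driven subsets, and an effect spread thinly over a large set with no
  concentrated subset can be missed.
* Bootstrap p-values have resolution $1/(B+1)$; with many sets/subsets, B
  must grow accordingly (see above), which is the main computational cost.
* The full-covariance statistic is offered for comparison, not
  recommended: it requires $n_i$ to exceed the subset size and loses power
  even when defined.
* The paired-mode statistic and the FDR subset rule are reasonable
  conventions for contracts the underlying two-sample construction leaves
  open; both are flagged in code and output.
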