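---
title: "Measuring variability of ancestry membership with FST/FSTmax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring variability of ancestry membership with FST/FSTmax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
set.seed(1)
```

```{r}
library(admixvar)
library(dplyr)
```

## The statistic

Model-based clustering programs such as STRUCTURE and ADMIXTURE summarize
genetic structure in a *Q matrix*: one row per individual, one column per
statistical ancestry cluster, entries $q_{ki} \ge 0$ with each row summing
to 1. A natural question when comparing such plots is *how variable* the
membership vectors within a group of individuals are — are all individuals
similarly admixed, or does membership differ strongly from person to
person?

`admixvar` answers this by treating each individual's membership vector as
if it were the allele-frequency vector of a subpopulation, and each cluster
as an allele. With $I$ individuals and $K$ clusters,

$$H_S = 1 - \frac{1}{I}\sum_{i=1}^{I}\sum_{k=1}^{K} q_{ki}^2, \qquad
  H_T = 1 - \sum_{k=1}^{K}\Big(\frac{1}{I}\sum_{i=1}^{I} q_{ki}\Big)^2,
  \qquad F_{ST} = \frac{H_T - H_S}{H_T}.$$

$F_{ST}$ is 0 exactly when all rows are identical, but its attainable
maximum depends on the configuration: it is constrained by $I$ and by $M$,
the mean membership of the highest-membership cluster (the analog of the
frequency of the most frequent allele). Writing $\sigma_1 = IM$, the
constrained maximum $F_{ST}^{\max}$ equals 1 exactly when $\sigma_1$ is an
integer in $1, \dots, I-1$, and is otherwise strictly below 1, with closed
forms in $\sigma_1$, $\lfloor\sigma_1\rfloor$, $\{\sigma_1\}$ and (for
$\sigma_1 < 1$) $J = \lceil 1/\sigma_1 \rceil$. The package reports the
normalized ratio

$$\frac{F_{ST}}{F_{ST}^{\max}} \in [0, 1],$$

which is comparable across matrices with different $I$, $K$ and mean
membership.

```{r}
q <- q_matrix(rbind(c(1, 0), c(0.5, 0.5)))
q_stat(q)
```

This 2x2 matrix is itself a maximizing configuration: $F_{ST} = 1/3$ equals
the bound for $I = 2$, $M = 0.75$, so the ratio is 1.

### The bound and its constructive witness

`fst_max()` evaluates the closed form of the bound; `fst_max_witness()`
independently *constructs* the extremal Q matrix — for $1 < \sigma_1 < I$:
$\lfloor\sigma_1\rfloor$ individuals fully in the top cluster, one
individual split $(\{\sigma_1\}, 1-\{\sigma_1\})$ between the top cluster
and a private cluster, and every other individual alone in its own private
cluster; for $0 < \sigma_1 \le 1$: every individual private, with $J - 1$
coefficients equal to $\sigma_1$ and one equal to $1-(J-1)\sigma_1$ — and
evaluates $F_{ST}$ on it. The two routes agree to $10^{-12}$ over a dense
$(I, M)$ grid, and the test suite asserts this; extracted renderings of the
closed form are easily corrupted, so the constructive value is the
authoritative cross-check. Integer $\sigma_1$ is detected with tolerance
$10^{-9}$; both adjacent branches converge to 1 at integers, so boundary
misclassification is harmless.

```{r}
w <- fst_max_witness(3, 0.5)
w$witness
c(closed = fst_max(3, 0.5), constructive = w$value, exact = 8/11)
```

Degenerate input is a typed error, not a silent zero: a monomorphic matrix
(every individual fully in the same cluster, $H_T = 0$) has no defined
$F_{ST}$, and `q_stat(allow_degenerate = TRUE)` (or the command-line flag)
must be used to obtain an `NA` row instead. All statistics are invariant to
row and column permutations and to appending all-zero columns, so columns
of inferred clusters that received no membership can be kept or dropped
freely.

## Comparing groups: row bootstrap and rank tests

To compare the variability of two or more groups, the package resamples
individuals (rows) with replacement, recomputes the ratio on each replicate
matrix, and compares the resulting bootstrap distributions with a two-sided
Wilcoxon rank-sum test (pairs) or a Kruskal–Wallis test plus all pairwise
rank-sum tests (three or more groups). `b = 1000` replicates per group is
the conventional choice; p-values use the normal approximation with tie
correction, which at these sample sizes is indistinguishable from exact
enumeration. Pairwise p-values are reported unadjusted by default, with
Bonferroni and Benjamini–Hochberg available by argument.

```{r}
qs <- list(
  admixed = simulate_q(50, alpha = 3, lam = c(2/3, 1/3), seed = 11),
  source  = simulate_q(50, alpha = 30, lam = c(9/10, 1/10), seed = 12)
)
boots <- bootstrap_groups(qs, b = 500, seed = 13)
tidy(boots)
compare_groups(boots)
```

A bootstrap replicate can occasionally be monomorphic (when one
fully-assigned individual is resampled $I$ times); such replicates are kept
with ratio 0 and counted in `n_degenerate` (with a warning) rather than
dropped, so `b` is never silently reduced. One master seed drives
everything; per-group streams are derived from the master seed and the
group's position, so appending a group never perturbs the draws of earlier
groups, and identical inputs reproduce identical distributions and
p-values.

## The Dirichlet generative model

For validation the package simulates Q matrices with known variability:
each row is an independent draw from a Dirichlet distribution with
parameter vector $\alpha\lambda$, where $\lambda$ (summing to 1) sets the
parametric mean membership of each cluster and the concentration $\alpha$
controls variability through

$$\operatorname{Var}(q_k) = \frac{\lambda_k(1-\lambda_k)}{\alpha + 1}.$$

Sampling normalizes independent gamma variates. At extremely small $\alpha$
(e.g. $1/99$) a whole row of gamma draws can underflow to zero in double
precision; such rows are redrawn and counted, while rows with *some* zero
entries are the correct vertex limit and are kept. `alpha_from_variance()`
inverts the variance map, so experiments can be parameterized directly by
the variance.

Three validation experiments mirror the study conditions:

**Variance sweep.** With $\lambda = (2/3, 1/3)$, $I = 50$, $K = 2$ and 45
variances $\{0.001\} \cup \{0.005, 0.010, \dots, 0.220\}$ (the preset
`sweep_variances()`, spanning nearly all of $(0, 2/9)$), the mean ratio is
linear in the parametric variance. A zero-intercept ordinary least squares
fit recovers slope $\approx 1/(\lambda_1\lambda_2) = 4.5$ with
zero-intercept $R^2 \approx 99\%$ ($R^2$ computed against the through-origin
model, $1 - \mathrm{RSS}/\sum y^2$, matching the zero-intercept fit). The
acceptance script runs this at 100 replicates per variance (4500 matrices),
which takes a few seconds and estimates the slope to well within a percent;
the in-suite quick check uses 40 replicates.

```{r}
sw <- variance_sweep(reps = 25, seed = 14)
sweep_fit(sw)
autoplot(sw)
```

**Expectation law.** The expected ratio under this model is approximately
$1/(\alpha+1)$ — independent of $\lambda$ and of $K$. `expectation_check()`
verifies it by Monte Carlo:

```{r}
expectation_check(c(1, 99), lam = c(2/3, 1/3), reps = 300, seed = 15)
```

The law is an approximation, and its accuracy degrades at the
extreme-variance end: at $\alpha = 1/99$ the simulated mean ratio is
$\approx 0.996$ against a predicted $0.990$, a bias far larger than the
Monte-Carlo standard error at realistic replicate counts (individual
matrices at this $\alpha$ sit at ratios 0.997–1.000). Tests of the law at
a fixed number of standard errors therefore fail at that endpoint — a
property of the approximation itself, not of the estimator — and the
package documents rather than hides this.

**Null calibration.** The rank test feeds $b$ bootstrap replicates into the
test as if they were independent observations. Its p-values are uniform
under the null in the following sense: when two independent bootstrap
distributions are drawn from the *same* underlying Q matrix,
`calibration_experiment()` recovers a Uniform(0,1) p-value distribution
(Kolmogorov–Smirnov check). If instead two matrices are *independently
simulated* from the same Dirichlet specification (`resimulate = TRUE`), the
test reliably detects the realized difference between the two finite
samples and p-values pile up near zero — with $b = 200$ about 90% fall
below 0.05. The test is therefore a comparison of the variability of the
*observed samples*, not of the generating populations; significant results
between small groups should be read with that distinction in mind. Power
against genuinely different variabilities is essentially 1: matrices
simulated at the opposite ends of the variance range are distinguished in
every repetition.

```{r}
pv <- calibration_experiment(3, c(2/3, 1/3), n_tests = 100, b = 100,
                             seed = 16)
mean(pv$p_value < 0.05)
```

## What the generator does and does not emulate

The Dirichlet model produces exchangeable individuals with a common mean
membership and a single variability parameter. Real inference output
violates this in ways the validation cannot probe: membership estimates are
correlated across individuals (shared loci, shared inference run), clusters
may be poorly resolved or label-switched between runs (this package never
aligns clusters across files — use a dedicated alignment tool first), and
uncertainty in the Q matrix itself is ignored (rows are treated as exact).
Passing the simulation experiments shows the statistic and test behave as
designed for exchangeable membership vectors of known variability; it does
not certify the inference software upstream.

## Numerical and design choices

- **Row-sum tolerance** `1e-3` on input: STRUCTURE/ADMIXTURE print 3–6
  decimals, so printed rows rarely sum to exactly 1. Rows within tolerance
  are renormalized to exact unit sums; rows outside it are errors, as are
  negative entries and all-zero rows.
- **Fixed-`M` normalization:** $F_{ST}^{\max}$ is always evaluated at the
  sample $M$ of the analyzed matrix itself; no external $M$ is accepted.
- **Ratio clamping:** the ratio is clamped to $[0, 1]$; identical rows give
  $H_S = H_T$ and floating-point cancellation can otherwise produce a tiny
  negative.
- **All-ties rank test:** if every bootstrap value in both groups is equal
  the rank-sum p-value is defined as 1 (the normal approximation is 0/0
  there).
- **Problem sizes:** the bundled experiments use 45 variances x 100
  replicates for the sweep, 500 replicates per concentration for the
  expectation law, and 500 repetitions x 200 bootstrap replicates for
  calibration — large enough that Monte-Carlo error is a small fraction of
  each tolerance, and each runs in seconds on a single core.
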