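---
title: "Candidate-gene evaluation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene evaluation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megexpress)
```

# The problem

Whether a small set of candidate genes contributes to a complex disease
can be interrogated at three levels that use entirely different data:
inherited variation (GWAS summary statistics), transcript abundance in
the affected tissue (multiple public case-control expression studies),
and transcript abundance in an accessible proxy tissue (a purpose-made
case-control comparison). `megexpress` implements all three arms for the
motivating case — the PPAR-encoding genes *PPARA*, *PPARD* and *PPARG*
in schizophrenia — but every arm is parameterised by plain tables, so
any candidate-gene set can be run through it.

This vignette documents the statistical models, the defaults and why
they were chosen, the behaviour of the synthetic-data generator, and the
numerical conventions at edge cases.

# Arm 1: variant lookup in GWAS summary statistics

A locus is a 1-based, closed interval on a named chromosome; a variant
matches the locus when its chromosome agrees and its base-pair position
lies inside the interval, endpoints included. BED input (0-based,
half-open) is converted at the reader (`read_loci(format = "bed")`), so
a single convention holds everywhere downstream.

For the variants of a locus three quantities are reported:

* **q-value** — Benjamini–Hochberg step-up,
  $q_{(i)} = \min_{j \ge i} \left( p_{(j)} \, m / j \right)$, clipped at 1.
  The denominator count $m$ may be the full genome-wide number of tests
  even when only the in-locus subset is materialised, because the
  correction of a candidate region is made against the whole scan.
  Benjamini–Yekutieli is available behind `method = "BY"`.
* **rank** — 1 plus the number of variants in the full scan with
  strictly smaller p-value. Ties share the minimal rank; an average-rank
  option exists but the minimal rank is the default because it gives the
  conservative (worst-case) answer to "how many variants beat this one".
* **rank percentage** — $100 \cdot \mathrm{rank} / m$.

An empty locus is reported with `n_snps = 0` and missing minima rather
than an error, since an absent signal is itself a result.

# Arm 2: expression mega-analysis

"Mega-analysis" here means meta-analysis in which the effect sizes are
recomputed from each study's original expression matrix instead of being
copied from publications. The effect size is the log fold change

$$\mathrm{LFC} = \bar{x}_{\text{case}} - \bar{x}_{\text{control}}$$

on log2-transformed intensities, with within-study variance in the Welch
(unpooled) form $v = s^2_c/n_c + s^2_k/n_k$ using $n-1$ standard
deviations. Welch is the default because the emulated studies have
unequal group sizes and no reason to assume equal group variances; a
pooled-variance option is provided and tested, as either convention is
defensible and published work rarely states which was used.

Pooling uses inverse-variance weights. Under the fixed-effect model
(FEM), $w_i = 1/v_i$, $\hat\theta = \sum w_i y_i / \sum w_i$,
$\mathrm{Var}(\hat\theta) = 1/\sum w_i$. Heterogeneity is measured by
Cochran's Q with FEM weights; its expectation under homogeneity is
$df = k - 1$, and

$$I^2 = \begin{cases} 0 & Q \le df \\ 100\,(Q - df)/Q & Q > df.
\end{cases}$$

`p_Q` is the upper-tail $\chi^2_{df}$ probability of Q — the probability
that the observed dispersion is within-study noise only. The
**model-selection rule** follows the clamping rule exactly: FEM when
$Q \le df$, otherwise the random-effects model (REM) with the
DerSimonian–Laird between-study variance

$$\hat\tau^2 = \max\!\left(0,\ \frac{Q - df}
  {\sum w_i - \sum w_i^2 / \sum w_i}\right)$$

and weights $w_i^\ast = 1/(v_i + \hat\tau^2)$. DerSimonian–Laird was
fixed as the sole REM estimator (rather than REML) because it is the
classic closed-form moment estimator: it keeps the engine exactly
reproducible by a brute-force oracle, which is how the engine is tested.
At the boundary the two models coincide: $Q \le df$ forces
$\hat\tau^2 = 0$ and REM output equals FEM output exactly, a reduction
property asserted in the test suite.

The pooled effect is reported with a two-sided normal (Wald) test and
$\hat\theta \pm 1.96\,\mathrm{se}$ intervals; a t-based test is not
offered, keeping the p-value consistent with the 1.96-based CI.
Per-study weights are normalised as $w_i / \sum w_i$, so they lie in
$(0,1)$ and sum to one — the convention used for forest-plot weight
bars. A single-study "pool" is defined as $Q = 0$, $df = 0$, $I^2 = 0$,
FEM: one of a set of studies may simply lack a gene, and the engine
pools whatever effects it receives, reporting $k$.

## Covariate regression

Per-study effects are regressed on study-level descriptors by ordinary,
unweighted least squares: total sample size and study age
(`reference_year - publication year`, reference year configurable,
default 2020) enter numerically; country and sample source enter as
integer category codes, producing exactly one coefficient and one
p-value per factor. Integer coding of a multi-level factor is
statistically crude — it imposes an arbitrary ordering — and is kept as
the default only because a single per-factor p-value is the reporting
convention this pipeline mirrors; `encoding = "onehot"` gives proper
dummy coding with a per-factor partial F-test and is the recommended
setting for new analyses. The fit is unweighted (not a meta-regression);
a precision-weighted variant was considered and rejected as the default
because the emulated analysis used a plain regression. With ~13 studies
and 4 covariates the residual degrees of freedom are few; the fit warns
when fewer than 5 remain. Constant columns are dropped with a warning;
genuine rank deficiency is a hard error naming the collinear terms —
never a silently regularised fit.

# Arm 3: two-group comparison and power

The proxy-tissue arm compares cases and controls per gene with
equal-variance one-way ANOVA (two groups), whose F is the square of the
pooled t statistic — an identity the suite checks to $10^{-10}$. Welch
is available behind a flag. Degenerate inputs follow fixed conventions:
zero within-group variance with equal means returns $p = 1$; with
unequal means the $p \to 0$ limit is reported as the smallest
representable double, with a warning, so downstream thresholding still
works. A gene is called differentially expressed only when **both**
$|\mathrm{LFC}| \ge 1$ and $p < 0.05$ hold; the two thresholds are
exposed as parameters. Comparisons run overall and, optionally, within
sex strata; a stratum with fewer than two samples in either group is
skipped with a logged reason rather than producing meaningless variance
estimates.

Design adequacy is checked with the exact power of the two-sided,
equal-n two-sample t-test, computed from the noncentral t distribution
with noncentrality $\delta/(s\sqrt{2/n})$ on $2n-2$ degrees of freedom.
`sample_size_for_power()` scans n upward and returns the smallest group
size reaching the target power. The default target is 0.80 — the
conventional choice where no target is stated — and is a parameter. For
the motivating design (detect $|\mathrm{LFC}| \ge 1$ against a
genome-wide LFC standard deviation of 0.5 at $\alpha = 0.05$) the
smallest adequate group size is 6 at power 0.80 (the non-integer
solution is 5.09, which is why "at least 5 per group" is sometimes
quoted for the same inputs).

# The synthetic-data generator

All inputs are simulated, so the full pipeline is testable without any
external download.

* **Expression studies.** For study $i$ and gene $g$, controls are
  $N(\mu_g, \sigma^2)$ and cases are
  $N(\mu_g + \delta_g + u_{ig}, \sigma^2)$ with
  $u_{ig} \sim N(0, \tau^2)$ — heterogeneity enters as a study-level
  random shift of the case effect only, exactly the structure the REM
  pooling model assumes. One row per gene; Gaussian on the log2 scale,
  since the emulated data are log2 microarray intensities.
* **GWAS table.** Null variants draw $p \sim U(0,1)$, with chromosome
  chosen proportionally to length from a configurable table (default:
  chromosomes 3, 6, 22 at full GRCh38 lengths — the chromosomes housing
  the three PPAR loci) and position uniform along the chromosome.
  Optional signal loci place a fixed number of variants inside a region
  with $p \sim \mathrm{Beta}(a, 1)$, enriched near zero for $a < 1$.
* **Proxy-tissue study.** Gaussian samples from per-gene, per-group
  means and SDs; the packaged parameterisation
  (`pbmc_reference_stats()`) uses published group summary statistics as
  inputs, with group sizes 19/18.

Seeds are explicit single integers and split by a documented rule
(study $i$ uses `seed + i`); equal seeds give bit-identical output, a
property asserted in the tests and exploited by the pipeline's
determinism guarantee. Default per-study group sizes in the packaged
pipeline configuration come from the real studies' case/control counts
(`brain_study_descriptors()`). Publication years are not part of those
descriptors, so the generator draws them from a configurable range
(default 2008–2017, the span typical of the emulated series); the
within-group SD defaults to 1 on the log2 scale and $\tau^2$ to 0,
values chosen for testability — the variance structure of the real
datasets is unknown.

What the generator deliberately does **not** emulate: probe-level
structure and probe-to-gene mapping, batch and platform effects,
correlated genes, non-Gaussian intensity noise, and genotype-level data
(only summary p-values are simulated). Passing tests therefore
demonstrate that the statistics are computed correctly under the model's
own assumptions, not that real microarray data satisfy those
assumptions.

# Input handling conventions

Expression matrices arrive as TSV (first column gene symbol, header
sample ids) with a sample sheet (`sample_id`, `group`, `sex`). Columns
are reordered to sheet order; matrix samples missing from the sheet are
dropped with a count; a sheet sample missing from the matrix is an error
naming the id. Duplicate gene symbols are averaged (median by option)
with a warning — the pipeline works at gene level and takes no position
on probe mapping. Scale detection applies `log2(x + 1)` when the 99th
percentile exceeds 30 (log2 intensities rarely exceed ~20; the threshold
is configurable), is idempotent, and errors on negative values in a
matrix judged linear-scale. Per-gene statistics use pairwise-complete
observations; a gene contributes to a study only if both groups retain
at least 2 values. Quantile normalisation is available as an optional
pre-step but off by default.

# Validation problem sizes

The test suite validates the engine against independently coded
brute-force oracles on 500 random small pooling problems (agreement to
$10^{-10}$), checks 95% CI coverage over 1,000 simulated homogeneous
13-study meta-analyses with 30 samples per group (coverage within
95% ± 2%), effect recovery at 10 fixed seeds, BH against an $O(n^2)$
step-up on 1,000 random vectors, the F = t² identity on 1,000 problems,
null p-value uniformity at 10,000 replicates, and the null
false-positive rate of the comparison arm on 1,000 null genes. These
sizes were chosen to bound Monte-Carlo error well below the asserted
tolerances while keeping a full run in well under a minute per block.

# Known limitations

* The integer coding of categorical covariates (the reporting-driven
  default) makes those coefficients depend on level order; use
  `encoding = "onehot"` for inference you intend to defend.
* DerSimonian–Laird underestimates $\tau^2$ dispersion at small k; no
  Knapp–Hartung adjustment is applied, consistent with the Wald test
  convention.
* The DEG rule's fixed LFC threshold of 1 (a two-fold change) is a
  convention, not an inference; it interacts with array dynamic range.
* The GWAS arm treats variants as independent: no LD-aware gene-based
  testing, no liftover, no allele-direction handling.
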