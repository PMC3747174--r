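---
title: "Comparing gene lists through functional profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing gene lists through functional profiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goCompare)
```

## The problem

A routine endpoint of a high-throughput experiment is a list of genes --
differentially expressed genes, a disease gene set, a signature. Two such
lists (from two conditions, two studies, two platforms) are often compared
through their *functional profiles*: the frequencies with which their genes
are annotated in a target set of $s$ Gene Ontology classes, typically the
classes cutting one ontology at a fixed depth.

Two features make this comparison statistically awkward:

1. **GO classes overlap.** A gene annotated to several classes is counted in
   each of them, so the $2 \times s$ table of class counts is *not* a
   partition of the genes and the textbook chi-square homogeneity test does
   not apply (its actual size can drift far from the nominal level, in
   either direction).
2. **The lists may share genes.** Two lists of sizes $n$ and $m$ can share
   $k$ genes, $0 \le k \le \min(n, m)$, making the two observed profiles
   correlated.

The common alternative -- testing every class separately with Fisher's exact
test and adjusting for multiplicity -- controls the family-wise error but
pays for it in power, badly so when counts are sparse across many classes
(deep GO levels). `goCompare` implements a single *global* test of profile
equality that accounts for both complications, together with the
class-by-class analysis and a decision procedure that combines the two.

## Expanded and contracted profiles

The device that restores a tractable sampling model is the **expanded
profile**: instead of the $s$ overlapping class counts, count genes by their
*exact* combination of classes. A gene annotated to exactly $\{A_1\}$ falls
in one cell, a gene annotated to exactly $\{A_1, A_2\}$ in another, and so
on. These cells are mutually exclusive, so the vector of cell counts is
multinomial. The ordinary ("contracted") profile
$\hat P = (\hat p_{1\cdot}, \dots, \hat p_{s\cdot})'$ is a linear image of
the expanded profile: $\hat p_{i\cdot}$ sums the frequencies of all cells
containing class $i$ (entries may sum to more than 1).

```{r}
ann <- annotation_index(
  list(g1 = "A1", g2 = c("A1", "A2"), g3 = c("A2", "A3"), g4 = "A3"))
e <- build_expanded(paste0("g", 1:4), ann)
e$counts
contract(e)$p
```

By default genes with no annotation among the target classes are excluded
from $n$ and reported; `include_unannotated = TRUE` keeps them in an
explicit empty cell instead, so that frequencies are relative to the whole
list. Neither choice is canonical (list "size" is ambiguous when some genes
are unannotated); the exclusion default treats the profile as a statement
about annotated genes only. Duplicate identifiers within a list are
collapsed with a warning.

## The global test

Dissimilarity is the squared Euclidean distance between contracted profiles,
$d(\hat P, \hat Q) = \sum_i (\hat p_{i\cdot} - \hat q_{i\cdot})^2$, and the
test of $H_0 : d(P, Q) = 0$ against $d(P, Q) > 0$ uses

$$V_{n,m} = \frac{nm}{n+m}\, d(\hat P, \hat Q).$$

Because the expanded profile is multinomial, the centred, scaled pair
$\sqrt{nm/(n+m)}\,(\hat P - P, \hat Q - Q)$ is asymptotically normal with a
$2s \times 2s$ covariance $\Sigma_{PQ}$. When the lists share $k$ genes, the
three component profiles (shared, exclusive to A, exclusive to B) are
independent multinomials and $\Sigma_{PQ}$ assembles from blocks

$$A = \tfrac{k}{n}\Sigma_{P_0} + \tfrac{n-k}{n}\Sigma_{P_1},\quad
  B = \Sigma_{P_0},\quad
  C = \tfrac{k}{m}\Sigma_{P_0} + \tfrac{m-k}{m}\Sigma_{Q_1},$$

weighted as $[[\tfrac{m}{n+m}A, \tfrac{k}{n+m}B],
[\tfrac{k}{n+m}B', \tfrac{n}{n+m}C]]$, where each single-profile covariance
has entries $\sigma_{ii} = p_{i\cdot}(1 - p_{i\cdot})$ and
$\sigma_{ij} = p_{ij\cdot} - p_{i\cdot}p_{j\cdot}$ ($p_{ij\cdot}$ the joint
two-class marginal). All covariances are plug-in estimates from the observed
samples; no pooling under $H_0$ is applied by default (the plug-in
estimator is the one whose calibration the package's simulations verify).
`compare_profiles(pooled = TRUE)` instead estimates one covariance from the
concatenation of both lists and uses it for every component -- a variant
some practitioners expect under $H_0$, provided for comparison only.
Zero-size components ($k = 0$, $n = k$, $m = k$) are dropped rather than
evaluated, so no 0/0 weights arise.

Under $H_0$, $V_{n,m}$ is asymptotically distributed as
$\sum_{i=1}^{s} \beta_i \chi^2_{1,i}$ with weights $\beta_i$ the non-zero
eigenvalues of $\Im_{2s}\Sigma_{PQ}$, where
$\Im_{2s} = [[I_s, -I_s], [-I_s, I_s]]$. Writing $\Im_{2s} = K'K$ with
$K = [I_s, -I_s]$ shows the non-zero eigenvalues equal those of the
$s \times s$ symmetric matrix
$K \Sigma_{PQ} K' = (mA - kB - kB' + nC)/(n+m)$, which is what
`null_betas()` diagonalises -- both cheaper and numerically better behaved
than the unsymmetric $2s \times 2s$ product (the equivalence is tested
against the literal product on random instances). Eigenvalues below
$10^{-12}$ of the largest in magnitude are truncated to zero; anything more
negative indicates an indefinite estimate and is clipped with a warning.

```{r}
ann2 <- annotation_index(
  list(g1 = "A1", g2 = c("A1", "A2"), g3 = c("A2", "A3"), g4 = "A3",
       g5 = "A2", g6 = c("A1", "A3"), g7 = "A1", g8 = c("A2", "A3")))
compare_lists(paste0("g", 1:5), paste0("g", 4:8), ann2, warn_small = FALSE)
```

Two identical annotated lists give $V = 0$, an all-zero spectrum and
p-value 1 (the degenerate-null convention; `qf_upper_tail()` warns when the
spectrum is entirely zero). When $s = 1$ the whole construction collapses,
exactly, to the squared unpooled two-proportion $z$ statistic referred to
$\chi^2_1$ -- an identity the test suite asserts to $10^{-10}$.

## Computing the mixture distribution

Tail probabilities of $\sum_i \beta_i \chi^2_{1,i}$ are computed internally
with a layered strategy, targeting $10^{-6}$ absolute accuracy or better:

* equal weights: exactly, as a scaled $\chi^2_s$;
* otherwise an Imhof-type numerical inversion of the characteristic
  function (adaptive quadrature of the oscillatory integrand), accepted
  when the quadrature's error estimate is below $10^{-7}$ -- in practice it
  is usually below $10^{-10}$ for $s \ge 3$;
* a Ruben-type series representation as a non-negative mixture of central
  chi-square distribution functions, whose truncation error is bounded by
  the unassigned mixture weight (at most 20,000 terms); it covers the
  small-$s$, moderate-spread spectra where the quadrature error estimate is
  weakest;
* a deterministic, seeded Monte-Carlo estimate ($10^6$ draws, warning
  emitted) for pathological spectra, e.g. eigenvalue ratios beyond $10^6$
  where the series underflows and the integrand decays too slowly.

Quantiles (`qf_quantile()`) bracket the root with the stochastic bounds
$\beta_{\max}\chi^2_1 \le \sum_i \beta_i \chi^2_{1,i} \le
\beta_{\max}\chi^2_s$ and refine by `uniroot` to $10^{-12}$.

## Confidence interval and power

Under the alternative, $\sqrt{nm/(n+m)}\,(d(\hat P,\hat Q) - d(P,Q))$ is
asymptotically $N(0, \sigma^2)$ with
$\sigma^2 = 4\,(P-Q, Q-P)'\,\Sigma_{PQ}\,(P-Q, Q-P)$, which reduces to
$4\,\delta' R\, \delta$ with $\delta = P - Q$ and $R$ the same reduced
matrix as above. The reported interval is

$$d(\hat P, \hat Q) \pm z_\alpha\, \hat\sigma\, \sqrt{1/n + 1/m},$$

with nominal coverage $1 - 2\alpha$ ($z_\alpha$ the one-sided normal
quantile, read literally from the interval's definition; the package's
coverage simulations at the default design point confirm ~0.90 empirical
coverage at $\alpha = 0.05$). The lower limit is deliberately **not**
truncated at zero -- near $H_0$ the normal approximation is two-sided around
a boundary value and a negative lower limit is informative about its
accuracy. When $\hat P = \hat Q$ the interval degenerates to $[0, 0]$; a
zero $\hat\sigma$ with positive distance triggers a warning.

`approx_power()` applies the same normal approximation to the rejection
region: the test rejects when $\hat d$ exceeds
$c = v(\alpha, s)\,(n+m)/(nm)$, with $v(\alpha, s)$ the null-mixture
quantile evaluated at the *population* covariance, so

$$\text{power} \approx 1 - \Phi\!\left(\frac{c - d}
  {\sigma\sqrt{1/n + 1/m}}\right).$$

This construction is first-order: it ignores the chi-square-shaped
component of $\hat d$'s distribution, so it is accurate for moderate and
large separations (the suite checks $\pm 0.05$ agreement with a
5000-replicate simulation at $d = 0.06$, $s = 10$, $n = m = 200$) but
*underestimates* rejection rates when $d$ is within a few null standard
deviations of zero. For such near-null alternatives a direct
`run_scenario()` simulation is the honest tool.

## The combined decision procedure

`combined_procedure()` implements the recommended flow:

1. Global test. Not significant: stop, report `no_difference` -- no
   class-by-class tests are run, so the procedure's type I error is the
   global test's.
2. Per-class Fisher tests with Holm adjustment. Any significant class:
   report `classes_identified`.
3. Global significant but no class survives Holm: either point at the
   class with the smallest *unadjusted* p-value (`"suggest"`, default) or
   recommend repeating the analysis at a less specific level
   (`"uplevel"`).

Step 3 is what the global test buys beyond gatekeeping: with many sparse
classes the evidence of difference can be real while no single 2x2 table
carries it through a family-wise correction.

Two caveats are inherited from standard practice and documented rather than
"fixed". The per-class 2x2 Fisher tables count a shared gene in both list
columns, which is the field's convention for overlapping lists but not an
exact independence model. And the two-sided Fisher p-value is defined by
summing table probabilities at or below the observed one (the `fisher.test`
convention); sidedness is a choice.

The chi-square homogeneity comparator (`chisq_homogeneity()`) is included
*as the invalid baseline*: a textbook 2x$s$ Pearson test on contracted
counts with $s' - 1$ degrees of freedom after dropping classes empty in
both lists. Its miscalibration under class overlap is demonstrated, not
repaired.

## The simulation engine and the synthetic populations

`run_scenario()` replays the type-I-error/power study design: each
replicate draws the shared component once (a single multinomial of size
$k$ reused in both lists -- the only coupling consistent with the
decomposition identities and the cross-block $B = \Sigma_{P_0}$) and the
exclusive components independently, assembles the pair, and applies all
four procedures. Everything derives from one `set.seed` at scenario start;
the engine is serial, so this is exactly reproducible.

The default synthetic population (`synthetic_population()`) is a
deterministic construction emulating what annotation at a fixed GO level
looks like: Zipf-type ($1/i$) class weights, genes annotated in one to
three *adjacent* classes (pair cells at weight $0.35/i$, triple cells at
$0.15/i$) so that classes genuinely overlap, and by default a 10%
unannotated fraction. Alternatives are generated by exponential tilting
(`perturb_population()`), which moves the population smoothly along a fixed
direction -- convenient for nested-alternative power curves.

What this generator does **not** emulate: the real GO dependence structure
(overlap only between adjacent classes here, versus arbitrary sibling and
ancestor sharing), the finite-universe hypergeometric sampling of real
enrichment designs, annotation bias and incompleteness, and inter-gene
dependence within a list. Calibration results under this generator
therefore support the distributional theory (multinomial cells, plug-in
covariance, mixture null), not robustness to those real-data features.

Default problem sizes in the package's own checks were chosen as desk-scale
analogues of the study design: null calibration at $s = 20$,
$n = m = 150$, $k = 0$ with 2000 replicates; CI coverage at $s = 8$,
$n = m = 250$ with 1000 replicates; block-covariance validation at
$s = 4$ with $10^5$ vectorised replicates; the quadratic-form engine
against $10^7$-draw Monte-Carlo oracles. Rates are judged with binomial
standard errors.

## Ontology handling

`read_obo()` parses the minimal OBO 1.4 subset needed here (ids, names,
namespaces, `is_a`, `part_of`, obsoletes, `alt_id`). The level convention:
the namespace root is **level 1**, so "level 2" means the root's children,
and a term reachable at several depths is assigned its *minimum* `is_a`
depth. The convention is stated prominently because "GO level" has no
universal definition; all of the package's level numbers follow it.
Projection (`project_annotations()`) maps each gene's terms to their
ancestor-or-self closure intersected with the cut; `is_a` only by default,
`part_of` behind a flag (including it changes profiles and is a modelling
choice, not a correction). Obsolete terms annotate nothing; alternate ids
resolve to their primary term first. Class order is fixed
lexicographically so profile coordinates are reproducible.

## Known limitations

* All inference is asymptotic; `compare_lists()` warns when
  $\min(n, m) < 30$ or some class has an expected count below 5. There is
  no exact or permutation version of the global test.
* The null spectrum uses plug-in covariance estimates; with many empty
  classes the estimate is rank-deficient, handled by eigenvalue truncation
  rather than regularisation (no shrinkage option).
* The confidence interval and the power approximation are first-order
  normal; both degrade near $H_0$ (see above).
* Equivalence ("the profiles are the same for practical purposes") is a
  different inferential goal and is not provided; rejection failure is not
  evidence of equivalence.
* Identifier matching is verbatim and case-sensitive; no synonym or
  cross-species resolution.
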