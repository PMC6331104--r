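---
title: "Methods and design of toxrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of toxrank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxrank)
```

# The problem

Toxicogenomics panels profile a model system (e.g. primary hepatocytes or
whole rat liver) under many compounds, each at several dose levels
(vehicle control, low, middle, high) and post-administration timepoints,
with few biological replicates. Genes relevant to organ toxicity are
expected to respond in many of the toxic compounds, while any single
compound also perturbs much idiosyncratic biology. `toxrank` turns each
compound's time-course screen into a ranking of one fixed gene universe
and aggregates those rankings into a consensus prioritization, which is
then benchmarked against positive gene sets mined from literature
annotations.

# Per-compound screen: two-step regression

For one compound, sample metadata provide dose group, time and replicate.
The full design contains an intercept, polynomial time terms
$t, t^2, \dots, t^d$ with $d = \min(3, \#\text{timepoints} - 1)$, and for
every non-control dose group a dummy plus dummy×time interactions. Time is
rescaled to unit range before taking powers: with raw hours up to 24,
$t^3$ spans four orders of magnitude and the cross-products become badly
conditioned, while the F- and t-statistics are invariant to the scaling.
Dose groups absent for a particular compound (panels sometimes lack a
low-dose arm) simply contribute no columns.

*Step 1* fits the full model by OLS to every gene and tests it against
the intercept-only model by the F-statistic. The null hypothesis is "no
change over time in any group and no treatment dependence"; a gene with a
shared time drift therefore passes step 1 and must be sorted out in step
2, which is exactly the division of labour intended: step 1 finds genes
with *any* structure, step 2 isolates *treatment-dependent* structure.
P-values are BH-adjusted across genes and thresholded at FDR 0.01.

*Step 2* runs two-way backward stepwise selection per passing gene:
repeatedly drop the least significant coefficient while its t-test
p-value exceeds $\alpha = 0.05/n$ ($n$ = coefficient count of the full
model, 16 in the standard four-timepoint design), after each removal
offering every excluded variable re-entry if its p-value would be at or
below $\alpha$. The intercept is never removed. A gene is **selected**
(modulated) when it passed step 1, its selected model retains at least
one significant dose-related coefficient (a dummy or an interaction —
time-only models do not distinguish treatment from control), and the
selected model's $R^2 \ge 0.6$.

Numerical choices: zero-variance genes get p = 1 and $R^2 = 0$ rather
than errors; rank-deficient designs drop aliased columns and record them;
the stepwise loop is capped at four times the column count to exclude
pathological cycling. A `denoise` hook is exposed on `deAnalysis()` for
users who wish to plug a noise-removal procedure in front of the fits; the
default is a pass-through.

# Extended partial ranking

Selected genes are ordered by decreasing $R^2$, ties broken by the
selected model's F-test p-value, residual ties by midrank. All other
genes share a single tied bottom rank. Two conventions for that block are
defensible given only "the same lowest rank": the midrank of the
remaining positions (default — it conserves the rank sum $N(N+1)/2$ and
keeps MEAN aggregation unbiased), or rank $N$ (`bottomRank = "max"`,
the convention used by robust-rank-aggregation software for absent
genes). The choice matters: with a midranked block at normalized rank
≈ 0.5 in *every* list, a never-selected gene's ranks look "coincidentally
concordant" to an order-statistic score, which depresses RRA's contrast
between weak true signals and the null block (see Limitations). The
interpretation of "P-value of the adjusted model" as the model F-test
p-value (rather than the minimum coefficient p-value) is a tie-break
only and does not affect selection.

# Aggregation methods

All methods consume the gene × compound matrix of normalized ranks
$r = \text{rank}/N \in (0, 1]$.

- **MEAN**: score is the row mean; significance from the exact Irwin–Hall
  CDF of the rank sum (alternating-series form for $m \le 50$ terms,
  normal approximation $N(m/2, m/12)$ beyond, where the series loses
  digits and the approximation error is negligible), BH-adjusted across
  genes. The adjustment is monotone, so it never changes the order; it is
  applied for fidelity of the reported q-values.
- **NC**: the number of lists whose modulated set contains the gene, as
  produced by the compound's screen (no dose filter by default; the
  screen already integrates over doses through the design).
- **RRA**: $\rho = \min_k P(U_{(k)} \le r_{(k)})$ with
  $U_{(k)} \sim \text{Beta}(k, m-k+1)$, score $\min(1, m\rho)$
  (Bonferroni over the $m$ order indices), BH across genes.
- **STUART**: the joint probability
  $Q = P(U_{(1)} \le r_{(1)}, \dots, U_{(m)} \le r_{(m)})$ via the
  classical recursion $V_k = \sum_{i=1}^{k} (-1)^{i-1} V_{k-i}
  r_{m-k+1}^i / i!$, $Q = m!\,V_m$. The recursion is exact but
  alternating; it is restricted to $m \le 60$ lists, far beyond any
  realistic compound panel. An optional extra $m!$ scaling matches a
  convention used by some implementations and never changes the order.
- **BIRRA**: iterative Bayes-factor reweighting. Per iteration the top
  $\lceil \pi N \rceil$ genes of the current consensus are putative
  positives; for each list and cumulative rank bin $b$ (ranks
  $\le b/B$), $\text{BF}_{c,b} = \frac{(\#\text{pos} + 1)/(\pi N + 1)}
  {(\#\text{neg} + 1)/((1-\pi)N + 1)}$ with pseudo-count 1 smoothing; log
  Bayes factors are monotonized to be non-increasing in bin depth by a
  running maximum from the deepest bin (evidence for being a positive
  cannot grow as the rank worsens); each gene is rescored by the sum over
  lists of its bin's log BF, and the iteration stops when the rank vector
  is unchanged or after `maxIter`. Defaults: 50 bins, prior 0.05, 10
  iterations. Convergence is declared on the full midranked rank vector,
  making the procedure deterministic.
- **AR**: the per-gene median of the five ranks above, re-ranked. The
  median is what makes AR robust to one aberrant method.

All final rankings use midrank ties.

# Literature positives and evaluation

Gene–topic association is the upper tail of the hypergeometric
distribution (one-tailed Fisher's exact test in the enrichment
direction — the direction is implied by selecting over-represented
genes). The background is a declared universe *count*: the natural
background (every indexed abstract) is not an enumerable local set, so
the test takes its size as a parameter; a switch restricts the background
to abstracts annotated to at least one gene for users who prefer a
conditional background. Genes are tested only if they have at least one
abstract. Candidates require BH FDR ≤ 0.05, at least three supporting
abstracts, and a one-to-one ortholog (from homolog groups containing
exactly one gene of each taxon).

ROC curves traverse tied rank blocks as single straight segments, and the
trapezoidal area equals the midrank Mann–Whitney statistic, so partial
rankings are handled without arbitrary tie-breaking. Spearman's rho is
the Pearson correlation of midrank vectors with the large-sample t
approximation for its p-value. Rank combinations are plain sums
(consistent dysregulation across systems) and differences (system
contrasts); `topK()` includes a tie block straddling the boundary
entirely and reports the realized size, which on strongly partial
rankings can be much larger than k — a property of the ranking, not a
defect of the selection rule.

# What the synthetic data emulate

`simulationConfig()` mirrors a single-dose design: four dose groups, four
timepoints (3, 9, 12, 24 h), three biological replicates — the full
in-vivo arm of the standard panel layout. Defaults: 2,000 genes, 20
compounds of which 16 carry signal (a panel dominated by toxicants with a
non-toxic minority), 100 planted toxicity genes, each responding in a
given toxic compound with probability 0.6, maximal shift 2.0 log2 units
at high dose and late time, residual SD 0.5.

Responsive genes shift by `effectSize` × dose weight × time profile, with
ordinal dose weights (0, 1/3, 2/3, 1) and a monotone saturating time
profile scaled to [0, 1]; the rate constant (tmax/8) makes the response
largely established by the earliest measurement, as is typical of acute
transcriptional responses to a single dose. Response direction is random
per gene × compound. The literature generator gives every gene a few
background abstracts and plants ≥3 topic abstracts on a configurable
fraction of the planted genes; a `backgroundTopicRate` of zero produces
the clean separation used by exact-recovery tests.

The generator deliberately does **not** emulate: probe-level microarray
physics or normalization artifacts; batch effects; replicate correlation;
and — importantly — compound-specific off-target response (each toxic
compound perturbs only its planted subset, nothing idiosyncratic).
Because of the last point, all toxic compounds modulate similarly sized
gene sets, so the severe *imbalance* of differentially expressed set
sizes seen in real panels (tens to thousands of genes per compound) never
arises; consequently the known weakness of MEAN aggregation under
imbalance is not reproduced by these fixtures — on them MEAN performs on
par with the exact order-statistic methods. Passing tests therefore
demonstrate correctness of the machinery and recoverability of planted
signal, not real-data superiority of any method.

Under the default effect and noise levels the selected-model $R^2$ of a
truly responsive gene concentrates around 0.65 (a variance decomposition
of the planted signal against noise SD 0.5 bounds its expectation near
0.68), right above the 0.6 filter, so per-compound recovery of responsive
genes settles around 65–75% rather than near-complete — the test suite's
recovery bounds are set accordingly.

# Problem sizes and runtime

The test suite and the acceptance script run the full protocol at 2,000
genes × 20 compounds × 48 samples (seconds per compound for the screen;
the whole pipeline in well under a minute), Monte-Carlo oracle
comparisons at 10⁵–10⁶ draws, and null calibrations over 50 replicates of
500 × 10 rank matrices. These sizes give stable statistics while keeping
a full run cheap to reproduce.

# Known limitations

- The two-step screen is this package's own OLS implementation of the
  two-step polynomial regression idea; it is not bit-compatible with any
  particular external tool (different pivoting, stepwise tie-breaking and
  p-value conventions will move borderline genes).
- RRA on midrank-tied partial rankings loses contrast for genes with few
  informative lists, because the shared bottom block mimics concordance
  (its normalized rank ≈ 0.5 in every list beats the uniform null's
  order statistics at k = m). The `bottomRank = "max"` convention
  eliminates this at the cost of biasing MEAN; a principled joint
  treatment of ties in order-statistic aggregation is out of scope.
- Fisher tests against a declared universe count ignore abstract-level
  dependence (one abstract mentioning many genes).
- The stepwise selection inherits the usual caveats of significance-based
  model search; its role here is ranking, not inference on coefficients.
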