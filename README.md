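# toxrank

Prioritizing genes for organ-specific drug toxicity from multi-compound
toxicogenomics panels.

Toxicogenomics resources profile gene expression in model systems (human
or rat hepatocytes, rat liver, rat kidney) after administration of many
compounds at several dose levels and timepoints. A single compound's
screen says little about toxicity in general; the interesting genes are
those that respond across *many* toxic compounds in a given model system.
`toxrank` implements a complete protocol for this integration problem:

1. **Per-compound time-course differential expression.** For each gene, a
   global polynomial model of (scaled) time with dose-group dummies and
   dose×time interactions is fitted by OLS; the model F-test p-values are
   BH-adjusted across genes (cut-off 0.01), and surviving genes go through
   two-way backward stepwise selection at the per-coefficient threshold
   0.05/n (n = number of model coefficients). A gene counts as modulated
   when it passes the global test, keeps at least one significant
   treatment coefficient, and its selected model reaches R² ≥ 0.6.
2. **Extended partial ranking.** Modulated genes are ranked by R² of the
   adjusted model (ties broken by its p-value, residual ties by midrank);
   all remaining genes share one tied bottom rank, so each compound yields
   a full-universe ranking with rank sum N(N+1)/2.
3. **Rank aggregation across compounds** by six methods:
   - `MEAN` — average normalized rank, with significance from the exact
     Irwin–Hall distribution of a sum of uniforms;
   - `NC` — number of compounds that modulated the gene;
   - `RRA` — robust rank aggregation: per gene, the sorted normalized
     ranks r₍₁₎ ≤ … ≤ r₍ₘ₎ are scored by
     ρ = min₍ₖ₎ P(U₍ₖ₎ ≤ r₍ₖ₎) with U₍ₖ₎ ~ Beta(k, m−k+1), Bonferroni-
     corrected by m;
   - `STUART` — the joint probability
     Q = P(U₍₁₎ ≤ r₍₁₎, …, U₍ₘ₎ ≤ r₍ₘ₎), computed by the exact
     order-statistic recursion;
   - `BIRRA` — Bayesian iterative rank reweighting: cumulative-bin Bayes
     factors against the current consensus' putative positive set
     (defaults: 50 bins, prior 0.05, ≤10 iterations);
   - `AR` — the per-gene median of the five ranks above, re-ranked.
4. **Literature benchmark.** Organ-specific positive gene sets are built
   from gene–abstract annotations by one-tailed Fisher's exact tests of
   gene–topic co-occurrence against a declared abstract universe
   (BH FDR ≤ 0.05, ≥ 3 supporting abstracts, one-to-one ortholog filter).
5. **Evaluation and comparison.** ROC/AUC of each aggregated ranking
   against the positive set (tied blocks traversed as straight segments;
   AUC equals the midrank-corrected Mann–Whitney statistic), Spearman
   correlation between model systems, rank sums ("all") and rank
   differences ("A>B") for cross-model contrasts, and top-k selection.

Because the real inputs (microarray archives, abstract databases, homolog
tables) are external resources, the package ships a first-class synthetic
data module: multi-compound panels with a planted, dose- and
time-dependent toxicity signature, plus literature annotations in which
planted genes are enriched for topic abstracts. Every stage of the
protocol is validated end-to-end against this recoverable ground truth.

## Worked example

```r
library(toxrank)

cfg <- readPipelineConfig(NULL, list(outdir = "demo", seed = 42L,
  n_genes = 500L, n_compounds = 8L, n_toxic_compounds = 6L,
  n_planted = 40L, universe_size = 10000L, top_k = 50L))
runPipeline(cfg)

read.delim("demo/auc_summary.tsv")
#>   method   auc
#> 1   MEAN 0.975
#> 2     NC 0.975
#> 3    RRA 0.775
#> 4 STUART 0.975
#> 5  BIRRA 0.975
#> 6     AR 0.975
```

The pipeline simulated an 8-compound panel (6 compounds carrying signal in
a 40-gene planted set), screened each compound for treatment-dependent
time-course changes, aggregated the eight partial rankings with all six
methods, rebuilt the positive set from the synthetic literature (all 40
planted genes recovered as candidates), and scored each ranking against
it. An AUC of 0.975 means a planted gene outranks a random background gene
97.5% of the time; RRA is lower here because the large tied bottom block
of partial rankings weakens its order-statistic score — the reason the
median-of-methods `AR` ranking is the recommended readout.

The same machinery is exposed as plain functions, e.g. the RRA score of a
gene ranked near the top in two of three lists:

```r
m <- matrix(c(0.02, 0.05, 0.9,    # geneA: strong in 2 of 3 lists
              0.6, 0.55, 0.48),   # geneB: unremarkable
            nrow = 2, byrow = TRUE,
            dimnames = list(c("geneA", "geneB"), NULL))
geneScores(aggregateRRA(m))
#>   geneA   geneB
#> 0.02175 0.64800
```

A thin command-line wrapper is installed at `inst/scripts/toxrank`
(`toxrank all --outdir out --seed 1`, or any single stage:
`simulate | de | rank | aggregate | literature | evaluate | combine`).

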