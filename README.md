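# scpbench

Benchmarking of post-quantification data-analysis workflows for
DIA-based single-cell proteomics.

After a DIA search engine (DIA-NN, Spectronaut, PEAKS) has produced a
protein quantification matrix, a long chain of statistical choices remains:
how strictly to filter sparse proteins, how to impute missing values, how
to normalize, how to correct batch effects, and which differential
expression test to run. `scpbench` evaluates all combinations of popular
methods for these five steps — 4 sparsity x 7 imputation x 5 normalization
x 5 batch-correction x 7 test options, 4900 workflows in total — against
ground truth, and distills the result into a ranked shortlist of
recommended workflows.

Ground truth comes from mixed-proteome designs: human material held
constant across sample groups with yeast and E. coli varied in known
ratios, so every non-human protein has a known expected log2 fold change
and every human protein is a known true negative. The package ships a
simulator for these designs (including batch location/scale effects,
technical noise, and intensity-dependent missingness) and readers for the
three search-engine report dialects with the standard q-value filters.

Each workflow is scored by:

* **ARI** — adjusted Rand index, `ARI = 2(ad − bc) / ((a+b)(b+d) + (a+c)(c+d))`
  over sample pairs, between Louvain clusters of the corrected matrix and
  the true sample groups;
* **pAUC** — area under the ROC of direction-gated `−log10` adjusted
  p-values, restricted to FPR < 10% (maximum 0.1, chance 0.005);
* **optimized F1** — F1 at the (p-value, |log2 FC|) thresholds maximizing
  recall subject to 95% precision;

aggregated as `Total Rank = Rank[Rank(ARI) + Rank(pAUC) + Rank(F1)]`. An
XGBoost learning-to-rank model with tree-SHAP attributions explains which
steps and method pairs drive the ranking, and a conservative beam search
(scoring candidates by the 5th percentile of their SHAP and SHAP-interaction
distributions, width 12) selects robust workflows and emits a Graphviz
decision tree. Differential-protein sets from competing workflows can be
compared by Fisher over-representation analysis and signed-Jaccard
clustering of their enriched-term profiles.

## Worked example

```r
library(scpbench)

d <- default_design("mixed_s1s5", seed = 42)      # 5 groups, 3 batches
d$n_proteins <- c(human = 120L, yeast = 60L, ecoli = 60L)
sim <- simulate_matrix(d)
sim$matrix
#> QuantMatrix: 240 proteins x 30 samples (28.5% missing)
#> species: ecoli=60, human=120, yeast=60

g <- grid_spec(registries = list(sparsity = "SR75",
                                 imputation = c("HalfRowMin", "KNN"),
                                 normalization = c("Sum", "Median"),
                                 batch_correction = c("NoBC", "ComBatP"),
                                 test = c("Welch", "ModT_Trend")))
metrics <- run_grid(sim$matrix, sim$annotation, sim$truth, g)
head(metrics[order(metrics$total_rank),
             c("imputation", "normalization", "batch_correction", "test",
               "ari", "pauc", "f1", "total_rank")], 5)
#>  imputation normalization batch_correction       test    ari   pauc    f1 total_rank
#>         KNN        Median          ComBatP ModT_Trend  1.000 0.0998 0.974          1
#>         KNN        Median          ComBatP      Welch  1.000 0.0965 0.974          2
#>         KNN           Sum          ComBatP ModT_Trend  1.000 0.0948 0.956          3
#>         KNN           Sum          ComBatP      Welch  1.000 0.0897 0.956          4
#>         KNN        Median             NoBC ModT_Trend -0.101 0.0988 0.964          5
```

The reading is immediate: on this simulation (batch location SD 0.5),
every ComBat-corrected workflow separates the five groups perfectly
(ARI 1.0) while the uncorrected ones cluster by batch (ARI ≈ −0.1 here),
and the differential tests recover the planted yeast/E. coli fold changes
with F1 ≈ 0.95−0.97 at optimized thresholds. pAUC close to its 0.1 maximum
means near-perfect ranking of true positives at low false-positive rates.

Continue to recommendations:

```r
model <- fit_ranker(metrics, seed = 42)
shap  <- shap_explain(model, top_fraction = 0.25)
sel   <- beam_select(shap, W = 12)
cat(export_tree(sel))    # Graphviz DOT decision tree
```

A thin command-line surface over the same functions lives in
`inst/scripts/scpbench.R` (`simulate`, `run-grid`, `recommend`, `all`),
driven by a YAML/JSON configuration with a mandatory seed; see
`?read_run_config`.

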