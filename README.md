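# sigpop — signature-positive cell population analysis

`sigpop` is an R package for finding and characterizing gene-signature-
positive cell subpopulations in single-cell RNA-seq data, and for carrying
derived signatures into bulk tumor cohorts. The motivating use case is a
transcriptional program (e.g., NF-κB or the integrated stress response)
that is active in only a fraction of cells — strong enough to matter, too
diffuse to drive clustering — in tumor cells under drug pressure. It is
aimed at computational biologists who want the full path from raw UMI
counts to enrichment calls, population signatures, and survival read-outs
as plain, tested R functions.

## The core statistic

Cells are scored against a signature $S$ on log-normalized, gene-wise
standardized expression:

$$\mathrm{score}(c) = \tfrac{1}{|S|} \textstyle\sum_{g \in S} z_{gc},
\qquad x_{gc} = \ln\!\bigl(1 + \mathrm{count}_{gc}\cdot 10^4/\mathrm{total}_c\bigr),$$

with $z_{gc}$ the per-gene z-score of $x_{gc}$ across cells. A cluster is
**enriched** for $S$ when the one-vs-rest ROC AUC (computed exactly from
the Mann–Whitney U statistic, ties counted ½) exceeds 0.7 with a two-sided
Wilcoxon rank-sum p < 0.01; a cell is **signature-positive** when its score
exceeds 0. Everything downstream — DEG-derived population signatures,
signature–signature Pearson correlation with strength banding,
cross-condition abundance shifts (χ²), and cohort-level grade (χ²) and
relapse-free survival (Kaplan–Meier + log-rank) — builds on these calls.

A negative-binomial UMI simulator with a planted signature-positive
population (`simulate_counts`) and a planted bulk cohort
(`simulate_cohort`) provide ground truth for every stage; the test suite's
acceptance checks are property-based against these known truths.

## Worked example

```r
library(sigpop)

# a 2,000-cell experiment; signature-positive cells confined to cluster 2
cfg <- sim_config(pos_fraction = 0.15, pos_placement = "concentrated",
                  pos_cluster = 2L, seed = 1)
sim <- simulate_counts(cfg)

# QC -> log-normalize -> scale -> PCA -> Louvain
pp <- preprocess(sim$matrix, seed = 1)
pp$qc$report$n_retained
#> [1] 1803
table(pp$clustering$labels)
#>   0   1   2   3   4
#> 388 367 351 349 348

sig <- gene_signature("planted",
         sim$truth$genes$gene_id[sim$truth$genes$role == "signature"])
cluster_enrichment(score_cells(pp$scaled, sig), pp$clustering)
#>   signature cluster n_cells       auc       p_value          p_bh enriched
#> 1   planted       0     388 0.4012677  2.423563e-09  4.039271e-09    FALSE
#> 2   planted       1     367 0.4048238  1.748907e-08  2.186134e-08    FALSE
#> 3   planted       2     351 0.8881766 4.187719e-113 2.093859e-112     TRUE
#> 4   planted       3     349 0.4262798  1.843930e-05  1.843930e-05    FALSE
#> 5   planted       4     348 0.3892819  1.314204e-10  3.285511e-10    FALSE
```

Only the cluster hosting the planted population passes the AUC > 0.7 &
p < 0.01 rule (clustering recovered the five simulated clusters; the 1,803
cells are those surviving QC). Deriving a signature from that cluster's
DEGs and re-scoring closes the loop:

```r
degs    <- find_degs(pp$norm, pp$clustering, 2L)
derived <- derive_signature(degs, max_genes = 50)
e2 <- cluster_enrichment(score_cells(pp$scaled, derived), pp$clustering)
e2[e2$enriched, c("signature", "cluster", "auc")]
#>                       signature cluster auc
#> 3 cluster2_population_signature       2   1
```

And a derived signature can interrogate a bulk cohort:

```r
cohort <- simulate_cohort(n_tumors = 500, n_genes = 300, signature = 30,
                          hazard_ratio = 2, grade_or = 2, seed = 1)
cc <- score_cohort(cohort$cohort, cohort$signature)
lr <- km_logrank(cc, cohort$cohort$rfs_time, cohort$cohort$rfs_event)
c(chi2 = lr$chi2, p = lr$p_value)
#>         chi2            p
#> 2.771006e+01 1.409280e-07
```

Signature-positive tumors relapse earlier (log-rank χ² = 27.7 on 1 df) —
the planted hazard ratio of 2 read back through the full scoring and
dichotomization path.

## CLI

A thin command-line interface covers the pipeline stages:

```sh
inst/cli/sigpop simulate   --config sim.json --outdir sim/ --seed 1
inst/cli/sigpop preprocess --counts sim/ --config qc.json --outdir pp/ --seed 1
inst/cli/sigpop score      --scaled pp/scaled.tsv --signatures sigs.gmt --out scores.tsv
inst/cli/sigpop enrich     --scores scores.tsv --clusters pp/clusters.tsv --out enrichment.tsv
```

Config files are JSON with keys matching `sim_config()` /
`qc_thresholds()` arguments.
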