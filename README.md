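# promotif

Gene module discovery from promoter transcription-factor binding-site
profiles.

Interpreting a list of differentially regulated genes (DRGs) usually means
enrichment against curated gene sets or co-expression clustering — both of
which miss programs that are defined by *shared regulation* rather than by
annotation or correlated expression. `promotif` clusters DRGs by the
predicted TF binding-site composition of their promoters: genes whose
promoters carry similar motif combinations are grouped into modules likely
driven by common upstream regulators, and each module's candidate drivers
are ranked statistically. It is aimed at anyone with a DRG list and an
expressed-gene list — bulk or single-cell RNA-seq contrasts, genes linked
to differentially accessible chromatin, or gene lists pulled from a web
resource.

## Method in brief

For each DRG, the promoter window `[TSS − 2000, TSS + 500]` (2,501 bp,
configurable) is scanned on both strands with the position weight matrices
of all *expressed* TFs (the expressed-gene list ∩ a reference TF list).
Scoring uses log2-odds against a Markov background estimated from the
scanned promoters; each window's p-value comes from the exact convolution
of the per-position score distribution, and hits are kept at 10% FDR
(Benjamini–Hochberg, per motif over all scored windows). Overlapping hits
(≥ 1 bp) of one TF are collapsed, giving the count matrix

&nbsp;&nbsp;&nbsp;&nbsp;C ∈ ℕ^(n_DRG × n_TF),&nbsp; C[g, t] = collapsed
occurrences of TF t in the promoter of gene g,

which is clustered with k-means (raw counts, Euclidean metric, k-means++,
best of 10 seeded restarts). For every (TF, cluster) pair a Fisher exact
test on the binarized matrix against all other clusters yields an odds
ratio and BH-adjusted p; TFs enriched (OR > 1, adj. p ≤ 0.05) in exactly
one cluster are reported as that module's candidate drivers, TFs enriched
in several clusters are set aside as ubiquitous. Marker signatures (GMT)
can be tested per cluster the same way, and a randomization control
re-runs everything on a gene-label-shuffled hit table.

## Worked example

Simulate a 60-gene fixture with three planted regulatory modules (two
driver TFs each) and run the full pipeline:

```r
library(promotif)

dir <- tempfile()
fx  <- simulateFixture(fixtureConfig(seed = 3), dir)
res <- runAll(fx$paths$genome, fx$paths$annotation, fx$paths$motifs,
              fx$paths$drgs, fx$paths$expressed, fx$paths$referenceTfs,
              outDir = file.path(dir, "out"),
              k = 3, kMax = 8, randomize = TRUE, seed = 11)
#> expressed TFs: 8 of 8 reference TFs
#> motifs for expressed TFs: 8 of 8
#> DRG promoters: 60 matched, 0 unmatched
#> raw hits passing prefilter: 498
#> hits at FDR 0.1: 324
#> recommended k: 3
#> 6 significant (TF, cluster) pairs, 6 cluster-unique

res$cluster$clusters
#> ClusterResult: k = 3 on 60 genes; inertia 73.80, mean silhouette 0.705
#> cluster
#>  0  1  2
#> 20 20 20

uniqueTFs(res$prioritize)[, c("tf_name", "cluster", "odds_ratio", "adj_p")]
#>    tf_name cluster odds_ratio    adj_p
#> 1     Tf01       0        Inf 1.02e-09
#> 2     Tf02       0        Inf 6.61e-13
#> 11    Tf03       1        Inf 2.97e-09
#> 12    Tf04       1        Inf 1.20e-13
#> 21    Tf05       2        741 1.53e-12
#> 22    Tf06       2        361 1.18e-11

truth <- setNames(fx$truth$module, fx$truth$gene)
adjustedRandIndex(clusterLabels(res$cluster$clusters), truth)
#> [1] 1
adjustedRandIndex(clusterLabels(res$randomize$clusters), truth)
#> [1] 0.04691018
```

The three planted modules are recovered exactly (adjusted Rand index 1
against the ground truth), the silhouette profile peaks at k = 3, and each
module's two planted driver TFs are its uniquely enriched regulators —
while the gene-label-shuffled control retains no structure (ARI ≈ 0).

On real data, replace the fixture paths with a genome FASTA, a GTF/GFF3 or
BED6 annotation, a MEME motif file, and plain-text gene lists; the same
stages are available as subcommands of the bundled CLI
(`inst/scripts/promotif scan|cluster|prioritize|enrich|randomize|simulate|all`),
and `--precomputed-matrix` runs clustering and prioritization from an
existing gene-by-TF matrix without any scanning.

## Documentation

The methods vignette (`vignettes/promoter-module-discovery.Rmd`) describes
the model, every tunable parameter, the numerical choices (exact p-value
discretization, FDR scope, tie handling), what the simulator does and does
not emulate, and known limitations.
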