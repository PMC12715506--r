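---
title: "Discovering gene modules from promoter TF binding-site profiles"
author: "promotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering gene modules from promoter TF binding-site profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Genes whose promoters carry similar combinations of transcription factor
(TF) binding sites are plausibly under shared regulatory control even when
their expression levels are not strongly correlated. `promotif` therefore
clusters a condition-relevant set of differentially regulated genes (DRGs)
not on expression but on a *regulatory profile*: the vector of predicted
binding-site counts for every expressed TF in each gene's promoter.

The pipeline has five stages.

1. **Expressed-TF derivation.** The expressed-gene list is intersected
   (case-insensitively, so mouse `Tox` matches a human-style reference
   entry `TOX`) with a reference TF list; only motifs of expressed TFs are
   scanned. Outputs keep the user's spelling and are sorted for
   determinism.
2. **Promoter extraction.** The promoter is the window from `upstream`
   bases 5′ of the TSS to `downstream` bases 3′ of it, TSS included —
   2,501 bp at the −2000..+500 default. Coordinates are 0-based half-open
   internally; windows are clipped at contig edges (the gene is kept with
   a shorter promoter rather than dropped), and minus-strand sequences are
   reverse-complemented so position 0 is always the most upstream base in
   gene orientation. For multi-transcript genes the 5′-most transcript
   start on the gene's strand defines the TSS.
3. **Motif scanning.** Each motif's position weight matrix is converted to
   a log2-odds matrix against the order-0 marginal of a Markov background
   estimated from the scanned promoter sequences themselves (strand-pooled
   k-mer counts, pseudocount 0.1). Every window on both strands is scored;
   p-values come from the *exact* distribution of the total score of a
   random background word, computed by position-wise convolution on a
   discretized score grid. Hits are controlled at a 10% false discovery
   rate (Benjamini–Hochberg).
4. **Count matrix.** Hits of one TF in one promoter (pooled across that
   TF's motifs) that overlap by at least 1 bp are collapsed into single
   occurrences; touching-but-not-overlapping intervals stay separate. The
   gene-by-TF matrix of collapsed counts — zero rows kept so the full DRG
   list is honored — is the clustering input.
5. **Modules and drivers.** k-means (Lloyd, k-means++ initialization,
   best of 10 seeded restarts) partitions the *raw* count matrix under the
   Euclidean metric; no transformation is applied, since variance-driven
   transformations tend to emphasize TF-family composition over the
   condition of interest. Cluster-driving TFs are ranked by Fisher exact
   tests of the *binarized* matrix against the background of all other
   clusters, BH-adjusted; TFs significant in two or more clusters are
   considered ubiquitous and excluded from the cluster-specific driver
   set. Marker gene signatures (GMT) are tested per cluster the same way.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `upstream`, `downstream` | 2000, 500 bp | promoter window around the TSS (window = upstream + downstream + 1 bp) |
| `bgOrder` | 0 | Markov order of the background; p-values always use the order-0 marginal, mirroring common scanner behavior |
| pseudocount | 0.1 | smoothing mass in the log-odds conversion, distributed proportionally to the background |
| `binWidth` | 1e-3 | score discretization; p-values are exact up to a score shift of width × binWidth |
| `pPrefilter` | 1e-4 | only windows at or below this p enter the hit table (bounds memory; the FDR step still uses the full window count) |
| `fdrAlpha` | 0.10 | BH level for motif hits, applied per motif across all scored windows of that motif |
| `k` | user-chosen | cluster count; `recommendK()` is advisory only |
| `alpha` | 0.05 | adjusted-p threshold for TF and signature enrichment |

## Numerical and design choices

**Exact p-values.** Per-position log-odds scores are rounded half-up to a
grid of `binWidth`; the null distribution of the total score is the exact
convolution over positions of the order-0 background. The quantization
can shift the effective threshold by at most width × binWidth on the
score axis — the tests assert exactly this bracketing against full
4^width word enumeration. A cap of 1e7 bins guards against degenerate
`binWidth` choices. Ambiguous bases (N and other IUPAC codes) score 0,
the background expectation.

**FDR scope.** BH is applied per motif with the family size equal to all
scored windows of that motif over all promoters (not merely the
prefiltered hits; because the prefilter keeps exactly the smallest
p-values, their global ranks are known and the adjusted values are
exact). This mirrors the per-motif q-value semantics of standard
scanners; a `global` scope pooling all motifs is available. BH rather
than Storey q-values keeps the computation deterministic. One consequence
worth knowing: an isolated perfect site of a rarely-occurring motif (p ~
1e-6 among ~3×10^5 windows) cannot pass a 10% FDR on its own, while a
motif with dozens of sites passes easily because the sites share ranks in
the BH step-up. Sparse single-site signals are therefore conservative
casualties of the hit-level FDR.

**Empty clusters and ties.** During Lloyd iterations an emptied centroid
is re-seeded at the point farthest from its assigned centroid; nearest-
centroid ties break toward the lower index. Both rules are deterministic
given the seed, and reruns are byte-identical.

**Choosing k.** `evaluateKRange()` reports inertia and mean silhouette
per k; `recommendK()` returns the largest k whose silhouette is within
10% of the range maximum — an operationalization of "the highest k before
a pronounced silhouette decline". It is advisory: the pipelines accept an
explicit k, and values of 3–5 are typical for condition-level contrasts.

**2-D embedding.** The diagnostic embedding is a principal-coordinates
(classical MDS) projection of the pairwise Canberra distances between
gene count profiles. Canberra weights presence/absence differences of
rare TFs strongly, which suits sparse count profiles; classical MDS keeps
the view fully deterministic. The embedding never feeds clustering.
Overlap in the 2-D view does not imply the clusters are unreal — regulatory
coherence does not always survive projection to two dimensions.

**Fisher tests.** The odds ratio is the sample odds ratio ad/bc (Inf and
NaN representable); the two-sided p-value sums hypergeometric
probabilities of tables no more probable than the observed one (relative
slack 1e-7, the convention of the standard implementations, verified to
1e-10 against them). Significance additionally requires enrichment
(OR > 1): depletions are reported but never flagged as drivers. The BH
family is all (TF, cluster) tests jointly; a per-cluster family is
available by flag.

## What the simulator emulates — and what it does not

`simulateFixture()` builds a fully self-contained input bundle: one
contig per gene, BED6 TSS annotation, MEME motifs, DRG/expressed/
reference-TF lists, and ground truth. Promoters are i.i.d. background
sequence at a configurable GC content; each gene of module *m* receives
`sitesPerPromoter` sites *sampled from* each of the module's driver PWMs
(not consensus copies, so the p-value machinery sees realistic score
spread) at non-overlapping random offsets and random strands, plus
off-module noise sites at `noiseRate` per promoter. The default
configuration — 60 genes, 3 modules, 2 drivers per module, 3 sites per
driver, 1.8 bits of per-position information, 20% noise — is the study
condition used throughout the tests and the acceptance script; the
k-selection diagnostics for these fixtures are evaluated over k = 2..8.

Real promoters are not i.i.d. sequence: they have CpG islands, repeats,
co-occurring motif grammars, and TSS annotation error, and real motif
databases contain highly similar motifs for related TFs. Passing the
recovery tests therefore shows the machinery is correct and the
statistics behave as designed — not that modules of comparable clarity
exist in any particular real dataset.

## The randomization control and its limits

`runRandomize()` shuffles the gene-symbol column of the post-FDR hit
table, re-runs collapse → count → k-means at the same k, and re-runs the
TF enrichment. On planted fixtures this reliably destroys the module
structure (adjusted Rand index vs truth ≈ 0). One caveat is intrinsic and
worth stating plainly: clustering a shuffled matrix and then testing *the
same matrix* for cluster-wise TF enrichment is circular — k-means groups
genes with concentrated counts in some TF column, and the Fisher test
then confirms that column. A few nominally "unique" TFs in a randomized
run are therefore expected and carry no biological meaning; the
randomized control is informative about module recovery (the ARI), not
about the enrichment machinery, whose calibration is instead checked by
label permutations that are independent of the clustering.

## A minimal session

```{r example, eval = FALSE}
library(promotif)

dir <- tempfile()
fx <- simulateFixture(fixtureConfig(seed = 3), dir)

res <- runAll(fx$paths$genome, fx$paths$annotation, fx$paths$motifs,
              fx$paths$drgs, fx$paths$expressed, fx$paths$referenceTfs,
              outDir = file.path(dir, "out"),
              k = 3, kMax = 8, randomize = TRUE, seed = 11)

res$cluster$clusters                 # ClusterResult: labels + metrics
uniqueTFs(res$prioritize)            # cluster-specific driver TFs
adjustedRandIndex(clusterLabels(res$cluster$clusters),
                  setNames(fx$truth$module, fx$truth$gene))
```

The same stages are available individually (`runScan`, `runCluster`,
`runPrioritize`, `runEnrich`, `runRandomize`) and as subcommands of the
`inst/scripts/promotif` command-line script; `--precomputed-matrix`
skips scanning and subsets a previously computed matrix to the DRG and
expressed-TF lists.

## Known limitations

* Promoter-only features: distal enhancers and post-transcriptional
  regulation are invisible to the method.
* Motif quality bounds everything downstream; motif availability varies
  across species and TF families, and similar motifs for related TFs are
  pooled only when they share a TF symbol.
* The hit-level FDR is conservative for sparse single-site signals (see
  above).
* Exact p-values are computed under the order-0 background marginal even
  when a higher-order background is configured for estimation.
* Up- and down-regulated genes are clustered together by design;
  stratify clusters by direction downstream if required.
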