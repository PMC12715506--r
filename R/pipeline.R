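# pipeline orchestration: each run*() function is one subcommand of the
# promotif command-line script (inst/scripts/promotif) and writes TSV
# outputs with a provenance comment header

.provHeader <- function(step, seed, params) {
  ser <- paste(deparse(params[order(names(params))]), collapse = "")
  tmp <- tempfile()
  writeLines(ser, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  c(paste0("promotif ", as.character(utils::packageVersion("promotif"))),
    paste0("step: ", step),
    paste0("seed: ", seed),
    paste0("config: ", hash))
}

#' Read a plain key = value run configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Values are returned as strings; callers coerce as needed.
#'
#' @param path config file path.
#' @return named list of strings.
#' @export
readRunConfig <- function(path) {
  lines <- .readSymbolList(path)
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  out <- lapply(kv, function(x) trimws(x[3]))
  names(out) <- vapply(kv, function(x) trimws(x[2]), character(1))
  out
}

#' Scan promoters and build the gene-by-TF matrix
#'
#' The full scanning stage: derive expressed TFs, read motifs for them,
#' extract DRG promoter sequences, estimate the Markov background from
#' those sequences, scan both strands with exact p-values, control the
#' FDR, collapse overlapping hits per TF and tally the count matrix.
#' Writes `promoters.bed`, `hits.tsv`, `collapsed.tsv` and `matrix.tsv`
#' into `outDir` and logs counts at every filtering step.
#'
#' In precomputed-matrix mode (`precomputedMatrix` set) scanning is
#' skipped and the given matrix is subset to the DRG list and the
#' expressed TFs.
#'
#' @param genome genome FASTA path.
#' @param annotation annotation path (GTF/GFF3/BED6).
#' @param motifs MEME motif file path.
#' @param drgFile,expressedFile,tfFile plain-text symbol lists (DRGs,
#'   expressed genes, reference TFs).
#' @param outDir output directory.
#' @param annotationFormat see [readAnnotation()].
#' @param upstream,downstream promoter window (defaults 2000/500).
#' @param bgOrder Markov background order (default 0).
#' @param pPrefilter,fdrAlpha,fdrScope see [scanConfig()] / [applyFdr()].
#' @param seed integer seed recorded in provenance (scanning itself is
#'   deterministic).
#' @param precomputedMatrix optional TSV path of a precomputed matrix.
#' @return invisibly, a list with the matrix, hit tables, promoters and
#'   the per-motif test counts.
#' @export
runScan <- function(genome, annotation, motifs, drgFile, expressedFile,
                    tfFile, outDir, annotationFormat = "auto",
                    upstream = 2000L, downstream = 500L, bgOrder = 0L,
                    pPrefilter = 1e-4, fdrAlpha = 0.10,
                    fdrScope = "per_motif", seed = 0L,
                    precomputedMatrix = NULL) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  params <- list(upstream = upstream, downstream = downstream,
                 bgOrder = bgOrder, pPrefilter = pPrefilter,
                 fdrAlpha = fdrAlpha, fdrScope = fdrScope)
  hdr <- .provHeader("scan", seed, params)
  drgs <- .readSymbolList(drgFile)
  expressed <- .readSymbolList(expressedFile)
  refTfs <- .readSymbolList(tfFile)
  expTfs <- filterExpressedTFs(expressed, refTfs)
  message("expressed TFs: ", length(expTfs), " of ", length(refTfs),
          " reference TFs")
  if (!is.null(precomputedMatrix)) {
    m <- subsetTFBSMatrix(readTFBSMatrix(precomputedMatrix),
                          genes = drgs, tfs = expTfs)
    message("precomputed-matrix mode: ", nrow(tfbsCounts(m)), " genes x ",
            ncol(tfbsCounts(m)), " TFs")
    writeTFBSMatrix(m, file.path(outDir, "matrix.tsv"), hdr)
    return(invisible(list(matrix = m)))
  }
  if (!length(expTfs)) {
    stop("no expressed TFs: cannot scan (check the expressed-gene and ",
         "reference TF lists)")
  }
  allMotifs <- readMeme(motifs)
  keep <- !is.na(.matchCaseInsensitive(
    vapply(allMotifs, tfName, character(1)), expTfs))
  motifSet <- allMotifs[keep]
  message("motifs for expressed TFs: ", length(motifSet), " of ",
          length(allMotifs))
  if (!length(motifSet)) stop("no motif matches an expressed TF")
  ann <- readAnnotation(annotation, annotationFormat)
  genomeSeqs <- Biostrings::readDNAStringSet(genome)
  names(genomeSeqs) <- sub("\\s.*", "", names(genomeSeqs))
  regions <- definePromoters(ann, upstream, downstream,
                             stats::setNames(Biostrings::width(genomeSeqs),
                                             names(genomeSeqs)))
  proms <- extractPromoterSeqs(genomeSeqs, regions)
  proms <- subsetToDrgs(proms, drgs)
  unmatched <- attr(proms, "unmatched")
  message("DRG promoters: ", length(proms), " matched, ",
          length(unmatched), " unmatched")
  bg <- estimateBackground(promoterSeqs(proms), order = bgOrder)
  loms <- lapply(motifSet, toLogOdds, bg = bg)
  dists <- lapply(loms, scoreDistribution, bg = bg)
  cfg <- scanConfig(pPrefilter = pPrefilter, fdrAlpha = fdrAlpha,
                    fdrScope = fdrScope)
  sc <- scanPromoters(loms, dists, proms, cfg)
  message("raw hits passing prefilter: ", nrow(sc$hits))
  hits <- applyFdr(sc$hits, sc$testsPerMotif, alpha = fdrAlpha,
                   scope = fdrScope)
  message("hits at FDR ", fdrAlpha, ": ", nrow(hits))
  collapsed <- collapseHits(hits)
  sym <- S4Vectors::mcols(promoterRegions(proms))$symbol
  tfs <- sort(unique(vapply(motifSet, tfName, character(1))),
              method = "radix")
  m <- buildTFBSMatrix(collapsed, sym, tfs)
  regionsOut <- promoterRegions(proms)
  bedDf <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regionsOut)),
    start = GenomicRanges::start(regionsOut) - 1L,
    end = GenomicRanges::end(regionsOut),
    name = sym, score = 0L,
    strand = as.character(GenomicRanges::strand(regionsOut)))
  con <- file(file.path(outDir, "promoters.bed"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(bedDf, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  writeHitTable(hits, file.path(outDir, "hits.tsv"), hdr)
  .writeTsv(collapsed, file.path(outDir, "collapsed.tsv"), hdr)
  writeTFBSMatrix(m, file.path(outDir, "matrix.tsv"), hdr)
  invisible(list(matrix = m, hits = hits, collapsed = collapsed,
                 promoters = proms, testsPerMotif = sc$testsPerMotif,
                 background = bg, expressedTfs = expTfs))
}

#' Cluster the gene-by-TF matrix
#'
#' Runs the k-selection diagnostics over `kMin..kMax`, clusters at the
#' requested k (or at the recommended k when `autoK`), and writes
#' `kreport.tsv`, `clusters.tsv` and the 2-D diagnostic embedding
#' `embedding.tsv`.
#'
#' @param matrixFile matrix TSV from [runScan()] (or a [TFBSMatrix-class]).
#' @param outDir output directory.
#' @param k number of clusters; required unless `autoK`.
#' @param autoK use [recommendK()] when `k` is NULL (default FALSE).
#' @param kMin,kMax k-selection range (defaults 2/12).
#' @param seed integer seed (default 0).
#' @param nInit k-means restarts (default 10).
#' @return invisibly, a list with the [ClusterResult-class], the
#'   k-report and the chosen k.
#' @export
runCluster <- function(matrixFile, outDir, k = NULL, autoK = FALSE,
                       kMin = 2L, kMax = 12L, seed = 0L, nInit = 10L) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  m <- if (is(matrixFile, "TFBSMatrix")) matrixFile
       else readTFBSMatrix(matrixFile)
  params <- list(k = k, autoK = autoK, kMin = kMin, kMax = kMax,
                 nInit = nInit)
  hdr <- .provHeader("cluster", seed, params)
  report <- evaluateKRange(m, kMin = kMin, kMax = kMax, seed = seed,
                           nInit = nInit)
  recK <- recommendK(report)
  message("recommended k: ", recK)
  if (is.null(k)) {
    if (!autoK) stop("k is not set; pass k explicitly or enable autoK")
    k <- recK
  }
  cr <- clusterGenes(m, k, seed = seed, nInit = nInit)
  .writeTsv(report, file.path(outDir, "kreport.tsv"), hdr)
  .writeTsv(data.frame(gene = names(clusterLabels(cr)),
                       cluster = unname(clusterLabels(cr))),
            file.path(outDir, "clusters.tsv"), hdr)
  .writeTsv(embedGenes(m, cr), file.path(outDir, "embedding.tsv"), hdr)
  invisible(list(clusters = cr, report = report, k = k,
                 recommendedK = recK))
}

.readClusters <- function(clustersFile) {
  if (is(clustersFile, "ClusterResult")) return(clusterLabels(clustersFile))
  df <- .readTsv(clustersFile)
  stats::setNames(as.integer(df$cluster), df$gene)
}

#' Prioritize cluster-driving TFs
#'
#' Binarizes the matrix, tests every (TF, cluster) pair with Fisher's
#' exact test against the remaining clusters, BH-adjusts, and separates
#' cluster-unique drivers from ubiquitously enriched TFs. Writes
#' `tf_enrichment.tsv` (all tests) and `unique_tfs.tsv`.
#'
#' @param matrixFile matrix TSV path or [TFBSMatrix-class].
#' @param clustersFile clusters TSV from [runCluster()] or a
#'   [ClusterResult-class].
#' @param outDir output directory.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param seed recorded in provenance.
#' @return invisibly, the full enrichment table with `unique_to_cluster`.
#' @export
runPrioritize <- function(matrixFile, clustersFile, outDir, alpha = 0.05,
                          seed = 0L) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  m <- if (is(matrixFile, "TFBSMatrix")) matrixFile
       else readTFBSMatrix(matrixFile)
  lab <- .readClusters(clustersFile)
  hdr <- .provHeader("prioritize", seed, list(alpha = alpha))
  res <- filterUbiquitous(tfEnrichment(binarize(m), lab, alpha = alpha))
  .writeTsv(res, file.path(outDir, "tf_enrichment.tsv"), hdr)
  .writeTsv(uniqueTFs(res), file.path(outDir, "unique_tfs.tsv"), hdr)
  message(sum(res$significant), " significant (TF, cluster) pairs, ",
          sum(res$unique_to_cluster), " cluster-unique")
  invisible(res)
}

#' Gene-signature enrichment per cluster
#'
#' Tests GMT gene sets against each cluster and writes
#' `signature_enrichment.tsv`.
#'
#' @param clustersFile clusters TSV or [ClusterResult-class].
#' @param gmtFile GMT path.
#' @param outDir output directory.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param seed recorded in provenance.
#' @return invisibly, the enrichment data.frame.
#' @export
runEnrich <- function(clustersFile, gmtFile, outDir, alpha = 0.05,
                      seed = 0L) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  lab <- .readClusters(clustersFile)
  sets <- readGmt(gmtFile)
  hdr <- .provHeader("enrich", seed, list(alpha = alpha, gmt = gmtFile))
  res <- signatureEnrichment(lab, sets, alpha = alpha)
  .writeTsv(res, file.path(outDir, "signature_enrichment.tsv"), hdr)
  invisible(res)
}

#' Randomization control
#'
#' Shuffles the gene-symbol column of the summarized hit table, re-runs
#' collapse, counting and clustering at the same k, and writes the
#' randomized matrix, cluster assignments and TF enrichment. The
#' randomized matrix keeps the original shape and total hit mass but
#' carries no biological structure.
#'
#' @param hitsFile hits TSV from [runScan()] (or the hit data.frame).
#' @param matrixFile original matrix TSV or [TFBSMatrix-class]; fixes the
#'   row/column universes of the rebuilt matrix.
#' @param outDir output directory.
#' @param k cluster count (use the same k as the real run).
#' @param seed integer seed for the permutation and clustering.
#' @param alpha significance threshold for the TF enrichment (default
#'   0.05).
#' @return invisibly, a list with the shuffled matrix, the
#'   [ClusterResult-class] and the enrichment table.
#' @export
runRandomize <- function(hitsFile, matrixFile, outDir, k, seed = 0L,
                         alpha = 0.05) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  hits <- if (is.data.frame(hitsFile)) hitsFile else readHitTable(hitsFile)
  m0 <- if (is(matrixFile, "TFBSMatrix")) matrixFile
        else readTFBSMatrix(matrixFile)
  hdr <- .provHeader("randomize", seed, list(k = k, alpha = alpha))
  shuf <- shuffleGeneLabels(hits, seed)
  collapsed <- collapseHits(shuf)
  m <- buildTFBSMatrix(collapsed, geneNames(m0), tfNames(m0))
  cr <- clusterGenes(m, k, seed = seed)
  res <- filterUbiquitous(tfEnrichment(binarize(m), cr, alpha = alpha))
  writeTFBSMatrix(m, file.path(outDir, "random_matrix.tsv"), hdr)
  .writeTsv(data.frame(gene = names(clusterLabels(cr)),
                       cluster = unname(clusterLabels(cr))),
            file.path(outDir, "random_clusters.tsv"), hdr)
  .writeTsv(res, file.path(outDir, "random_tf_enrichment.tsv"), hdr)
  invisible(list(matrix = m, clusters = cr, enrichment = res))
}

#' Generate a synthetic fixture from the command line
#'
#' Thin wrapper over [simulateFixture()] for the `simulate` subcommand.
#'
#' @param outDir output directory.
#' @param seed integer seed.
#' @param ... overrides passed to [fixtureConfig()].
#' @return invisibly, the fixture bundle.
#' @export
runSimulate <- function(outDir, seed = 1L, ...) {
  simulateFixture(fixtureConfig(seed = as.integer(seed), ...), outDir)
}

#' Run the full pipeline on one input bundle
#'
#' scan -> cluster -> prioritize, plus signature enrichment when a GMT is
#' given and the randomization control when requested. All randomness
#' flows from the single `seed`.
#'
#' @inheritParams runScan
#' @param k cluster count (NULL with `autoK` to use the recommendation).
#' @param autoK pick k by [recommendK()] when k is NULL.
#' @param kMin,kMax k-selection range.
#' @param gmtFile optional GMT of marker signatures.
#' @param randomize also run the shuffled-label control at the same k.
#' @param alpha enrichment significance threshold (default 0.05).
#' @return invisibly, a list with the stage results.
#' @export
runAll <- function(genome, annotation, motifs, drgFile, expressedFile,
                   tfFile, outDir, k = NULL, autoK = FALSE, kMin = 2L,
                   kMax = 12L, gmtFile = NULL, randomize = FALSE,
                   alpha = 0.05, seed = 0L, ...) {
  scan <- runScan(genome, annotation, motifs, drgFile, expressedFile,
                  tfFile, outDir, seed = seed, ...)
  clus <- runCluster(scan$matrix, outDir, k = k, autoK = autoK,
                     kMin = kMin, kMax = kMax, seed = seed)
  prio <- runPrioritize(scan$matrix, clus$clusters, outDir, alpha = alpha,
                        seed = seed)
  enr <- if (!is.null(gmtFile)) {
    runEnrich(clus$clusters, gmtFile, outDir, alpha = alpha, seed = seed)
  }
  rnd <- if (isTRUE(randomize)) {
    runRandomize(scan$hits, scan$matrix, outDir, k = clus$k, seed = seed,
                 alpha = alpha)
  }
  invisible(list(scan = scan, cluster = clus, prioritize = prio,
                 enrich = enr, randomize = rnd))
}
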