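#' Configuration for a synthetic planted-module fixture
#'
#' Defines the study conditions the simulator emulates: a panel of DRG
#' promoters in which disjoint gene modules carry binding sites for
#' module-specific driver TFs, on top of i.i.d. background sequence with
#' off-module noise insertions. The defaults (60 genes, 3 modules, 2
#' driver TFs per module, 3 sites per driver per promoter, 1.8 bits of
#' per-position motif information, noise rate 0.2) give a strong but not
#' trivial recovery problem.
#'
#' @param nGenes total number of DRGs (default 60).
#' @param nModules number of planted modules, >= 2 (default 3).
#' @param tfsPerModule driver TFs per module (default 2).
#' @param sitesPerPromoter sites planted per driver TF per promoter
#'   (default 3).
#' @param upstream,downstream promoter window extents (defaults 2000/500,
#'   giving the 2,501 bp default window).
#' @param gcContent background GC fraction (default 0.5).
#' @param widthRange inclusive motif width range (default 8..10).
#' @param infoBits target mean per-position information content in bits
#'   (default 1.8).
#' @param noiseRate expected number of off-module noise sites per promoter
#'   (default 0.2), drawn from TFs that do not drive the gene's module.
#' @param nDecoyTFs expressed TFs that drive no module (default 2).
#' @param nUbiquitousTFs TFs planted into every promoter regardless of
#'   module (default 0); used to exercise ubiquitous-TF filtering.
#' @param seed integer seed.
#' @return a list with class `FixtureConfig`.
#' @export
fixtureConfig <- function(nGenes = 60L, nModules = 3L, tfsPerModule = 2L,
                          sitesPerPromoter = 3L, upstream = 2000L,
                          downstream = 500L, gcContent = 0.5,
                          widthRange = c(8L, 10L), infoBits = 1.8,
                          noiseRate = 0.2, nDecoyTFs = 2L,
                          nUbiquitousTFs = 0L, seed = 1L) {
  # sitesPerPromoter = 0 gives a noise-only fixture (null experiments)
  stopifnot(nModules >= 2L, sitesPerPromoter >= 0L, nGenes >= nModules,
            gcContent > 0, gcContent < 1)
  structure(as.list(environment()), class = "FixtureConfig")
}

# information content (bits) of a column with max prob p, rest uniform
.colInfo <- function(p) {
  q <- (1 - p) / 3
  h <- -p * log2(p) - ifelse(q > 0, 3 * q * log2(q), 0)
  2 - h
}

# consensus-base probability achieving the target information content
.probForInfo <- function(infoBits) {
  target <- min(infoBits, 1.995)
  if (target <= 0) return(0.25)
  stats::uniroot(function(p) .colInfo(p) - target,
                 lower = 0.2500001, upper = 1 - 1e-9, tol = 1e-12)$root
}

#' Generate random TF motifs with controlled information content
#'
#' Each motif gets a random consensus (rejection-sampled so all consensus
#' sequences are distinct) of a width drawn from `widthRange`; every
#' position puts probability p on the consensus base and (1-p)/3 on the
#' others, with p chosen so the per-position information content matches
#' `infoBits`.
#'
#' @param n number of motifs (0 gives an empty list).
#' @param widthRange inclusive width range.
#' @param infoBits target per-position information content in bits.
#' @param seed integer seed.
#' @param tfNames optional TF symbols (defaults to Tf01, Tf02, ...).
#' @return list of [TFMotif-class].
#' @export
simulateMotifs <- function(n, widthRange = c(8L, 10L), infoBits = 1.8,
                           seed = 1L, tfNames = NULL) {
  if (n == 0L) return(list())
  if (is.null(tfNames)) tfNames <- sprintf("Tf%02d", seq_len(n))
  stopifnot(length(tfNames) == n)
  p <- .probForInfo(infoBits)
  widths <- seq.int(widthRange[1], widthRange[2])
  withr::with_seed(as.integer(seed), {
    seen <- character(0)
    motifs <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        w <- if (length(widths) == 1L) widths else sample(widths, 1L)
        cons <- sample.int(4L, w, replace = TRUE)
        key <- paste(cons, collapse = "")
        if (!(key %in% seen)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw a distinct consensus in 1000 tries")
      seen <- c(seen, key)
      probs <- matrix((1 - p) / 3, nrow = w, ncol = 4L)
      probs[cbind(seq_len(w), cons)] <- p
      motifs[[i]] <- makeTFMotif(sprintf("M_%s", tfNames[i]), tfNames[i],
                                 probs, nsites = 20)
    }
    motifs
  })
}

.randomSeq <- function(n, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

.sampleSite <- function(motif) {
  p <- motifProbs(motif)
  paste(DNA_BASES[apply(p, 1, function(r) sample.int(4L, 1L, prob = r))],
        collapse = "")
}

# place len at a random offset not overlapping occupied [start, end) spans
.placeSite <- function(occupied, len, promLen) {
  if (promLen < len) stop("promoter too short for the requested sites")
  for (try in seq_len(1000L)) {
    s <- sample.int(promLen - len + 1L, 1L) - 1L
    e <- s + len
    if (!any(occupied$start < e & s < occupied$end)) {
      return(c(s, e))
    }
  }
  stop("promoter too short to place all requested sites without overlap")
}

#' Generate a fully self-contained planted-module fixture
#'
#' Writes a toy genome (one contig per gene), a BED6 TSS annotation, MEME
#' motifs, DRG / expressed-gene / reference-TF lists and the ground truth,
#' all in the standard formats the pipeline reads. Each gene's promoter is
#' i.i.d. background sequence at `gcContent` into which sites sampled from
#' the gene's module driver PWMs (not consensus-only, so the p-value
#' machinery sees realistic score spread) are inserted at non-overlapping
#' random offsets and random strands; noise sites come from non-driver
#' TFs at rate `noiseRate` per promoter. The reference TF list is written
#' upper-cased to exercise case-insensitive symbol matching.
#'
#' @param config a [fixtureConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file paths, the truth data.frame
#'   (`gene`, `module`), the module -> driver-TF map, the planted site
#'   table and the motif list.
#' @export
simulateFixture <- function(config = fixtureConfig(), dir) {
  stopifnot(inherits(config, "FixtureConfig"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- config
  promLen <- cfg$upstream + cfg$downstream + 1L
  nDrivers <- cfg$nModules * cfg$tfsPerModule
  nTFs <- nDrivers + cfg$nDecoyTFs + cfg$nUbiquitousTFs
  tfNames <- sprintf("Tf%02d", seq_len(nTFs))
  motifs <- simulateMotifs(nTFs, cfg$widthRange, cfg$infoBits,
                           seed = cfg$seed + 1000L, tfNames = tfNames)
  driverIdx <- split(seq_len(nDrivers),
                     rep(seq_len(cfg$nModules), each = cfg$tfsPerModule))
  decoyIdx <- if (cfg$nDecoyTFs) nDrivers + seq_len(cfg$nDecoyTFs)
              else integer(0)
  ubiqIdx <- if (cfg$nUbiquitousTFs) {
    nDrivers + cfg$nDecoyTFs + seq_len(cfg$nUbiquitousTFs)
  } else integer(0)
  genes <- sprintf("Gene%03d", seq_len(cfg$nGenes))
  module <- sort(rep_len(seq_len(cfg$nModules), cfg$nGenes))
  flank <- 100L
  contigs <- character(cfg$nGenes)
  contigNames <- paste0("chr_", genes)
  bed <- vector("list", cfg$nGenes)
  siteRows <- list()
  withr::with_seed(as.integer(cfg$seed), {
    geneStrand <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)
    for (g in seq_len(cfg$nGenes)) {
      prom <- .randomSeq(promLen, cfg$gcContent)
      occupied <- data.frame(start = integer(), end = integer())
      plant <- function(motifIdx, kind) {
        m <- motifs[[motifIdx]]
        w <- motifWidth(m)
        site <- .sampleSite(m)
        st <- sample(c("+", "-"), 1L)
        ins <- if (st == "+") site else reverseComplement2(site)
        pos <- .placeSite(occupied, w, promLen)
        occupied <<- rbind(occupied,
                           data.frame(start = pos[1], end = pos[2]))
        substr(prom, pos[1] + 1L, pos[2]) <<- ins
        siteRows[[length(siteRows) + 1L]] <<- data.frame(
          gene = genes[g], tf = tfName(m), start = pos[1], end = pos[2],
          strand = st, kind = kind, stringsAsFactors = FALSE)
      }
      for (mi in driverIdx[[module[g]]]) {
        for (s in seq_len(cfg$sitesPerPromoter)) plant(mi, "driver")
      }
      for (mi in ubiqIdx) {
        for (s in seq_len(cfg$sitesPerPromoter)) plant(mi, "ubiquitous")
      }
      nNoise <- stats::rpois(1L, cfg$noiseRate)
      noisePool <- setdiff(c(unlist(driverIdx), decoyIdx),
                           driverIdx[[module[g]]])
      for (s in seq_len(nNoise)) {
        if (!length(noisePool)) break
        plant(if (length(noisePool) == 1L) noisePool
              else sample(noisePool, 1L), "noise")
      }
      if (geneStrand[g] == "+") {
        contigs[g] <- paste0(.randomSeq(flank, cfg$gcContent), prom,
                             .randomSeq(flank, cfg$gcContent))
        tss <- flank + cfg$upstream
      } else {
        contigs[g] <- paste0(.randomSeq(flank, cfg$gcContent),
                             reverseComplement2(prom),
                             .randomSeq(flank, cfg$gcContent))
        tss <- flank + promLen - 1L - cfg$upstream
      }
      bed[[g]] <- sprintf("%s\t%d\t%d\t%s\t0\t%s", contigNames[g],
                          tss, tss + 1L, genes[g], geneStrand[g])
    }
  })
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "tss.bed"),
    motifs = file.path(dir, "motifs.meme"),
    drgs = file.path(dir, "drgs.txt"),
    expressed = file.path(dir, "expressed.txt"),
    referenceTfs = file.path(dir, "reference_tfs.txt"),
    truth = file.path(dir, "truth.tsv"),
    sites = file.path(dir, "sites.tsv"))
  fa <- Biostrings::DNAStringSet(contigs)
  names(fa) <- contigNames
  Biostrings::writeXStringSet(fa, paths$genome, width = 80L)
  writeLines(unlist(bed), paths$annotation)
  writeMeme(motifs, paths$motifs)
  .writeSymbolList(genes, paths$drgs)
  .writeSymbolList(c(genes, tfNames), paths$expressed)
  .writeSymbolList(toupper(tfNames), paths$referenceTfs)
  truth <- data.frame(gene = genes, module = module,
                      stringsAsFactors = FALSE)
  .writeTsv(truth, paths$truth)
  sites <- if (length(siteRows)) do.call(rbind, siteRows) else
    data.frame(gene = character(), tf = character(), start = integer(),
               end = integer(), strand = character(), kind = character())
  .writeTsv(sites, paths$sites)
  drivers <- lapply(driverIdx, function(ii) tfNames[ii])
  names(drivers) <- paste0("module", seq_len(cfg$nModules))
  invisible(list(paths = paths, truth = truth, drivers = drivers,
                 decoys = tfNames[decoyIdx], ubiquitous = tfNames[ubiqIdx],
                 sites = sites, motifs = motifs, config = cfg))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement between two labelings of the
#' same genes; 1 for identical partitions, around 0 for independent ones.
#' Label names are irrelevant, only the induced partition matters.
#'
#' @param labelsA,labelsB named vectors over the same gene universe.
#' @return numeric in [-1, 1].
#' @export
adjustedRandIndex <- function(labelsA, labelsB) {
  if (is.null(names(labelsA)) || is.null(names(labelsB)) ||
      !setequal(names(labelsA), names(labelsB))) {
    stop("labelings must be named over the same gene universe")
  }
  labelsB <- labelsB[names(labelsA)]
  tab <- table(labelsA, labelsB)
  n <- sum(tab)
  sumIj <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(0)
  (sumIj - expected) / (maxIdx - expected)
}
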