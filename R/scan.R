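#' Scan configuration
#'
#' @param pPrefilter report only windows with p-value at or below this
#'   prefilter (default 1e-4); bounds the size of the raw hit table before
#'   FDR control.
#' @param fdrAlpha Benjamini-Hochberg false discovery rate applied to the
#'   retained hits (default 0.10).
#' @param bothStrands scan the reverse complement as well (default TRUE).
#' @param fdrScope "per_motif" (default) controls the FDR within each
#'   motif's scored windows; "global" pools all motifs into one family.
#' @return a list with class `ScanConfig`.
#' @export
scanConfig <- function(pPrefilter = 1e-4, fdrAlpha = 0.10,
                       bothStrands = TRUE,
                       fdrScope = c("per_motif", "global")) {
  stopifnot(pPrefilter > 0, pPrefilter <= 1, fdrAlpha > 0, fdrAlpha <= 1)
  structure(list(pPrefilter = pPrefilter, fdrAlpha = fdrAlpha,
                 bothStrands = bothStrands,
                 fdrScope = match.arg(fdrScope)),
            class = "ScanConfig")
}

# total log-odds per window start for one strand;
# M is width x 4; enc is the encoded sequence (0 = ambiguous, contributes 0)
.windowScores <- function(M, enc, w) {
  n <- length(enc) - w + 1L
  if (n <= 0L) return(numeric(0))
  tot <- numeric(n)
  for (j in seq_len(w)) {
    row <- c(0, M[j, ])
    tot <- tot + row[enc[j:(j + n - 1L)] + 1L]
  }
  tot
}

.emptyHits <- function() {
  data.frame(motif_id = character(), tf_name = character(),
             gene_symbol = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(), p_value = numeric(),
             q_value = numeric(), matched = character(),
             stringsAsFactors = FALSE)
}

#' Scan one promoter sequence with one motif
#'
#' Scores every window of the sequence (and of its reverse complement when
#' both strands are scanned) with the log-odds matrix, assigns each window
#' its exact background p-value, and reports windows passing the p-value
#' prefilter. Minus-strand matches are reported on the forward promoter
#' axis; `matched` is the sequence that matches the motif (the reverse
#' complement of the forward segment for `-` hits). A sequence shorter
#' than the motif yields an empty table.
#'
#' @param lom a [LogOddsMatrix-class].
#' @param dist the matching [ScoreDistribution-class].
#' @param seq character(1) promoter sequence.
#' @param config a [scanConfig()].
#' @param geneSymbol gene symbol recorded in the hit table.
#' @return data.frame of hits with 0-based half-open `start`/`end`
#'   coordinates on the promoter axis; attribute `n_tests` carries the
#'   number of scored windows.
#' @export
scanSequence <- function(lom, dist, seq, config = scanConfig(),
                         geneSymbol = "") {
  stopifnot(is(lom, "LogOddsMatrix"), is(dist, "ScoreDistribution"))
  w <- nrow(lom@scores)
  enc <- encodeDNA(seq)
  L <- length(enc)
  if (L < w) {
    out <- .emptyHits()
    attr(out, "n_tests") <- 0L
    return(out)
  }
  q <- .quantize(lom@scores, dist@binWidth)
  strands <- if (isTRUE(config$bothStrands)) c("+", "-") else "+"
  res <- list()
  nTests <- 0L
  for (st in strands) {
    e <- if (st == "+") enc else rev(ifelse(enc == 0L, 0L, 5L - enc))
    sc <- .windowScores(lom@scores, e, w)
    qb <- as.integer(round(.windowScores(q, e, w)))
    nTests <- nTests + length(sc)
    p <- .pvalueFromBins(dist, qb)
    hit <- which(p <= config$pPrefilter)
    if (!length(hit)) next
    if (st == "+") {
      start0 <- hit - 1L
    } else {
      start0 <- L - (hit - 1L) - w
    }
    matched <- vapply(hit, function(i)
      decodeDNA(e[i:(i + w - 1L)]), character(1))
    res[[st]] <- data.frame(
      motif_id = lom@motifId, tf_name = lom@tfName,
      gene_symbol = geneSymbol,
      start = as.integer(start0), end = as.integer(start0 + w),
      strand = st, score = sc[hit], p_value = p[hit],
      q_value = NA_real_, matched = matched, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else .emptyHits()
  rownames(out) <- NULL
  attr(out, "n_tests") <- nTests
  out
}

#' Scan all promoters with all motifs
#'
#' Concatenates [scanSequence()] hits over every (motif, promoter) pair in
#' deterministic order (motif_id, gene_symbol, start) and records the total
#' number of scored windows per motif, which is the family size used for
#' FDR control.
#'
#' @param loms list of [LogOddsMatrix-class] objects (already restricted to
#'   expressed TFs).
#' @param dists parallel list of [ScoreDistribution-class] objects.
#' @param promoters a [PromoterSet-class].
#' @param config a [scanConfig()].
#' @return list with `hits` (data.frame) and `testsPerMotif` (named integer
#'   vector of scored-window counts).
#' @export
scanPromoters <- function(loms, dists, promoters, config = scanConfig()) {
  if (!length(loms)) stop("empty motif list: no expressed TFs to scan")
  stopifnot(length(loms) == length(dists))
  seqs <- as.character(promoterSeqs(promoters))
  syms <- S4Vectors::mcols(promoterRegions(promoters))$symbol
  tabs <- list()
  tests <- integer(length(loms))
  names(tests) <- vapply(loms, function(x) x@motifId, character(1))
  for (m in seq_along(loms)) {
    nt <- 0L
    for (g in seq_along(seqs)) {
      h <- scanSequence(loms[[m]], dists[[m]], seqs[g], config, syms[g])
      nt <- nt + attr(h, "n_tests")
      if (nrow(h)) tabs[[length(tabs) + 1L]] <- h
    }
    tests[m] <- nt
  }
  hits <- if (length(tabs)) do.call(rbind, tabs) else .emptyHits()
  ord <- order(hits$motif_id, hits$gene_symbol, hits$start, hits$strand,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, testsPerMotif = tests)
}

#' Benjamini-Hochberg FDR control of motif hits
#'
#' Adjusts hit p-values by the BH step-up procedure using the full number
#' of scored windows per motif as the family size m (not merely the count
#' of prefiltered hits): because the prefilter retains exactly the smallest
#' p-values, their ranks among all m tests are known and the adjusted
#' values are exact. Hits with q at or below `alpha` are retained with
#' `q_value` populated. With scope "global" a single family pooling all
#' motifs is used.
#'
#' @param hits hit data.frame from [scanPromoters()].
#' @param testsPerMotif named vector of scored-window counts per motif.
#' @param alpha FDR level (default 0.10).
#' @param scope "per_motif" (default) or "global".
#' @return the retained hits with `q_value` filled in.
#' @export
applyFdr <- function(hits, testsPerMotif, alpha = 0.10,
                     scope = c("per_motif", "global")) {
  scope <- match.arg(scope)
  if (!nrow(hits)) return(hits)
  unknown <- setdiff(unique(hits$motif_id), names(testsPerMotif))
  if (length(unknown)) {
    stop("hits reference motif(s) with unknown test counts: ",
         paste(unknown, collapse = ", "))
  }
  bhQ <- function(p, m) {
    o <- order(p)
    ranked <- p[o] * m / seq_along(o)
    q <- rev(cummin(rev(ranked)))
    q <- pmin(q, 1)
    out <- numeric(length(p))
    out[o] <- q
    out
  }
  if (scope == "global") {
    hits$q_value <- bhQ(hits$p_value, sum(testsPerMotif))
  } else {
    for (mid in unique(hits$motif_id)) {
      sel <- hits$motif_id == mid
      hits$q_value[sel] <- bhQ(hits$p_value[sel], testsPerMotif[[mid]])
    }
  }
  out <- hits[hits$q_value <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a hit table as TSV
#'
#' @param hits hit data.frame.
#' @param path TSV path.
#' @param header optional character vector of provenance comment lines.
#' @return `readHitTable`: the hit data.frame.
#' @export
writeHitTable <- function(hits, path, header = NULL) {
  .writeTsv(hits, path, header)
  invisible(path)
}

#' @rdname writeHitTable
#' @export
readHitTable <- function(path) {
  .readTsv(path, colClasses = c(
    motif_id = "character", tf_name = "character",
    gene_symbol = "character", start = "integer", end = "integer",
    strand = "character", score = "numeric", p_value = "numeric",
    q_value = "numeric", matched = "character"))
}
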