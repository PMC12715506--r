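#' Read motifs from a MEME minimal format file
#'
#' Parses the MEME minimal motif format (version line, optional ALPHABET /
#' strands / background sections, MOTIF blocks each followed by a
#' `letter-probability matrix:` section). One [TFMotif-class] is returned
#' per MOTIF block, in file order. The TF gene symbol is taken from the
#' motif's alternate name when present, otherwise from the motif
#' identifier.
#'
#' @param path path to a MEME motif file.
#' @return list of [TFMotif-class] objects.
#' @examples
#' meme <- tempfile(fileext = ".meme")
#' writeMeme(list(makeTFMotif("m1", "TFA",
#'   matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 2, 4, byrow = TRUE))), meme)
#' readMeme(meme)
#' @export
readMeme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    stop("empty MEME file: ", path)
  }
  motifs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, "MOTIF")) {
      toks <- strsplit(ln, "[ \t]+")[[1]]
      if (length(toks) < 2L) stop("MOTIF line without identifier at line ", i)
      id <- toks[2]
      alt <- if (length(toks) >= 3L) toks[3] else id
      # advance to the letter-probability header
      j <- i + 1L
      while (j <= n && !grepl("^letter-probability matrix", trimws(lines[[j]]))) {
        if (startsWith(trimws(lines[[j]]), "MOTIF")) {
          stop("MOTIF block without letter-probability matrix before line ", j)
        }
        j <- j + 1L
      }
      if (j > n) stop("MOTIF ", id, " has no letter-probability matrix")
      hdr <- trimws(lines[[j]])
      wAttr <- regmatches(hdr, regexec("w=\\s*([0-9]+)", hdr))[[1]]
      nsAttr <- regmatches(hdr, regexec("nsites=\\s*([0-9.]+)", hdr))[[1]]
      nsites <- if (length(nsAttr) == 2L) as.numeric(nsAttr[2]) else NA_real_
      rows <- list()
      j <- j + 1L
      while (j <= n) {
        rl <- trimws(lines[[j]])
        if (!nzchar(rl)) { j <- j + 1L; next_block <- TRUE; break }
        if (startsWith(rl, "MOTIF") || grepl("^URL", rl)) break
        vals <- suppressWarnings(as.numeric(strsplit(rl, "[ \t]+")[[1]]))
        if (anyNA(vals)) break
        if (length(vals) != 4L) {
          stop("malformed probability row (", length(vals),
               " fields, expected 4) at line ", j)
        }
        if (sum(vals) < 0.99 || sum(vals) > 1.01) {
          stop("probability row sum ", format(sum(vals)),
               " outside [0.99, 1.01] at line ", j)
        }
        rows[[length(rows) + 1L]] <- vals
        j <- j + 1L
      }
      if (!length(rows)) stop("MOTIF ", id, " has an empty probability matrix")
      probs <- do.call(rbind, rows)
      if (length(wAttr) == 2L && as.integer(wAttr[2]) != nrow(probs)) {
        stop("MOTIF ", id, ": declared width ", wAttr[2],
             " does not match ", nrow(probs), " matrix rows")
      }
      # renormalize rounding slack so validity holds exactly
      probs <- probs / rowSums(probs)
      motifs[[length(motifs) + 1L]] <-
        makeTFMotif(id, alt, probs, nsites = nsites)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(motifs)) stop("no MOTIF blocks found in ", path)
  motifs
}

#' Construct a TFMotif
#'
#' @param motifId character(1) motif identifier.
#' @param tfName character(1) TF gene symbol; defaults to `motifId`.
#' @param probs width x 4 probability matrix (columns A,C,G,T).
#' @param nsites optional site count the matrix was estimated from.
#' @return a [TFMotif-class].
#' @export
makeTFMotif <- function(motifId, tfName = motifId, probs, nsites = NA_real_) {
  probs <- as.matrix(probs)
  dimnames(probs) <- list(NULL, DNA_BASES)
  new("TFMotif", motifId = motifId, tfName = tfName, probs = probs,
      nsites = as.numeric(nsites))
}

#' Write motifs in MEME minimal format
#'
#' Produces a file readable by [readMeme()] (and by standard motif
#' scanners): version line, ALPHABET, strands, a uniform background record
#' and one MOTIF block per input motif.
#'
#' @param motifs non-empty list of [TFMotif-class] objects.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeMeme <- function(motifs, path) {
  if (!length(motifs)) stop("cannot write an empty motif list")
  stopifnot(all(vapply(motifs, is, logical(1), "TFMotif")))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25000 C 0.25000 G 0.25000 T 0.25000", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m@motifId, m@tfName), con)
    ns <- if (is.na(m@nsites)) 20 else m@nsites
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %g E= 0",
      nrow(m@probs), ns), con)
    writeLines(apply(m@probs, 1, function(r)
      paste(sprintf("%.6f", r), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Intersect expressed genes with a reference TF list
#'
#' Restricts the motif query to TFs that are expressed in the dataset.
#' Matching is case-insensitive (mouse `Tox` matches human-style `TOX`);
#' the returned symbols keep the spelling of the expressed-gene input and
#' are sorted lexicographically for determinism.
#'
#' @param expressedGenes character vector of expressed gene symbols.
#' @param referenceTfs character vector of known TF symbols.
#' @return sorted character vector of expressed TFs (possibly empty, with a
#'   warning).
#' @export
filterExpressedTFs <- function(expressedGenes, referenceTfs) {
  if (!length(expressedGenes) || !length(referenceTfs)) {
    stop("both the expressed-gene and the reference TF list must be non-empty")
  }
  expressedGenes <- unique(expressedGenes)
  hit <- !is.na(.matchCaseInsensitive(expressedGenes, referenceTfs))
  out <- sort(expressedGenes[hit], method = "radix")
  if (!length(out)) {
    warning("no expressed gene matches the reference TF list; ",
            "downstream scanning will have zero motifs")
  }
  out
}

#' Estimate a Markov background model from sequences
#'
#' Counts k-mers of length `order + 1` pooled over both strands (each
#' sequence plus its reverse complement), so the order-0 marginal is
#' strand-symmetric (A = T, C = G) by construction. Counts are smoothed
#' with a pseudocount per cell and renormalized; k-mers containing
#' ambiguous bases are skipped.
#'
#' @param sequences character vector (or [Biostrings::DNAStringSet]) of DNA
#'   sequences, typically the scanned promoters.
#' @param order Markov order, 0 (default), 1 or 2.
#' @param pseudocount smoothing added to each count cell (default 0.1).
#' @return a [MarkovBackground-class].
#' @examples
#' estimateBackground(c("ACGTACGT"), order = 0)
#' @export
estimateBackground <- function(sequences, order = 0L, pseudocount = 0.1) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  order <- as.integer(order)
  if (!(order %in% 0:2)) stop("order must be 0, 1 or 2")
  if (!length(sequences) || sum(nchar(sequences)) == 0) {
    stop("total sequence length must be > 0")
  }
  k <- order + 1L
  nCtx <- 4L^order
  counts <- matrix(0, nrow = nCtx, ncol = 4L)
  margCounts <- numeric(4L)
  for (s in sequences) {
    for (e in list(encodeDNA(s),
                   { enc <- encodeDNA(s); rev(ifelse(enc == 0L, 0L, 5L - enc)) })) {
      if (!length(e)) next
      ok <- e > 0L
      margCounts <- margCounts + tabulate(e[ok], 4L)
      if (length(e) < k) next
      if (order == 0L) {
        counts[1L, ] <- counts[1L, ] + tabulate(e[ok], 4L)
      } else {
        win <- stats::embed(e, k)[, k:1, drop = FALSE]  # rows = k-mers
        keep <- rowSums(win == 0L) == 0L
        if (!any(keep)) next
        win <- win[keep, , drop = FALSE]
        ctx <- as.vector((win[, seq_len(order), drop = FALSE] - 1L) %*%
                           4L^((order - 1L):0)) + 1L
        nxt <- win[, k]
        for (ii in seq_along(ctx)) {
          counts[ctx[ii], nxt[ii]] <- counts[ctx[ii], nxt[ii]] + 1
        }
      }
    }
  }
  if (sum(margCounts) == 0) stop("no informative bases in input sequences")
  counts <- counts + pseudocount
  freqs <- counts / rowSums(counts)
  marginal <- (margCounts + pseudocount) / (sum(margCounts) + 4 * pseudocount)
  ctxNames <- if (order == 0L) "" else {
    apply(do.call(expand.grid,
                  rep(list(DNA_BASES), order))[, order:1, drop = FALSE],
          1, paste, collapse = "")
  }
  dimnames(freqs) <- list(ctxNames, DNA_BASES)
  new("MarkovBackground", order = order, freqs = freqs,
      marginal = as.numeric(marginal),
      source = sprintf("%d sequences, %.0f bases (strand-pooled)",
                       length(sequences), sum(nchar(sequences))))
}

#' Convert a motif to a log2-odds scoring matrix
#'
#' Each entry is
#' `log2((p(i,b) + pseudocount * bg(b)) / (1 + pseudocount) / bg(b))`,
#' where `bg` is the order-0 marginal of the background: the background
#' distributed pseudocount keeps all entries finite, and a motif column
#' equal to the background scores exactly 0.
#'
#' @param motif a [TFMotif-class].
#' @param bg a [MarkovBackground-class].
#' @param pseudocount smoothing mass, distributed proportionally to the
#'   background (default 0.1).
#' @return a [LogOddsMatrix-class].
#' @export
toLogOdds <- function(motif, bg, pseudocount = 0.1) {
  stopifnot(is(motif, "TFMotif"), is(bg, "MarkovBackground"))
  bg0 <- bgMarginal(bg)
  if (any(bg0 <= 0)) stop("background marginal must be strictly positive")
  p <- motif@probs
  sm <- sweep(p, 2, pseudocount * bg0, "+") / (1 + pseudocount)
  scores <- log2(sweep(sm, 2, bg0, "/"))
  if (pseudocount == 0 && any(!is.finite(scores))) {
    scores[!is.finite(scores)] <- -100  # large negative floor for hard zeros
  }
  dimnames(scores) <- list(NULL, DNA_BASES)
  new("LogOddsMatrix", motifId = motif@motifId, tfName = motif@tfName,
      scores = scores, pseudocount = pseudocount)
}

#' Exact null score distribution of a motif
#'
#' Computes the exact distribution of the total log-odds score of a random
#' width-w word drawn i.i.d. from the order-0 background marginal.
#' Per-position scores are discretized to a grid of `binWidth` (rounding
#' half-up) and convolved position by position; the stored survival
#' function yields the p-value P(score >= s) for any observed score.
#'
#' @param lom a [LogOddsMatrix-class].
#' @param bg a [MarkovBackground-class].
#' @param binWidth score discretization step (default 1e-3); p-values are
#'   exact to within `width * binWidth`.
#' @param maxBins cap on the number of score bins (default 1e7); exceeded
#'   caps raise an error suggesting a larger `binWidth`.
#' @return a [ScoreDistribution-class].
#' @export
scoreDistribution <- function(lom, bg, binWidth = 1e-3, maxBins = 1e7) {
  stopifnot(is(lom, "LogOddsMatrix"), is(bg, "MarkovBackground"))
  if (binWidth <= 0) stop("binWidth must be > 0")
  bg0 <- bgMarginal(bg)
  span <- sum(apply(lom@scores, 1, function(r) max(r) - min(r))) /
    binWidth + nrow(lom@scores)
  if (span > maxBins) {
    stop("score distribution needs ~", format(span, digits = 3),
         " bins (cap ", maxBins, "); increase binWidth")
  }
  q <- .quantize(lom@scores, binWidth)
  pmf <- 1
  off <- 0L
  for (i in seq_len(nrow(q))) {
    qi <- q[i, ]
    lo <- min(qi)
    newLen <- length(pmf) + max(qi) - lo
    np <- numeric(newLen)
    for (b in 1:4) {
      sh <- qi[b] - lo
      idx <- seq_along(pmf) + sh
      np[idx] <- np[idx] + pmf * bg0[b]
    }
    pmf <- np
    off <- off + lo
  }
  surv <- rev(cumsum(rev(pmf)))
  surv <- pmin(surv, 1)
  # enforce exact monotonicity against fp noise
  surv <- rev(cummax(rev(surv)))
  new("ScoreDistribution", motifId = lom@motifId, binWidth = binWidth,
      pmf = pmf, offset = off, survival = surv)
}

# p-value lookup from integer bin indices (sum of quantized entries)
.pvalueFromBins <- function(dist, bins) {
  idx <- bins - dist@offset + 1L
  idx[idx < 1L] <- 1L
  n <- length(dist@survival)
  idx[idx > n] <- n
  dist@survival[idx]
}

#' p-value of an observed motif score
#'
#' Survival probability P(score >= s) under the exact background score
#' distribution, with `s` quantized to the distribution's grid.
#'
#' @param dist a [ScoreDistribution-class].
#' @param score numeric vector of observed total log-odds scores.
#' @return numeric vector of p-values in (0, 1].
#' @export
scorePValue <- function(dist, score) {
  stopifnot(is(dist, "ScoreDistribution"))
  .pvalueFromBins(dist, .quantize(score, dist@binWidth))
}
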