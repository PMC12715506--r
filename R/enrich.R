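#' Fisher's exact test for a 2x2 table
#'
#' Direct hypergeometric enumeration for the table
#' \preformatted{          with motif   without
#'   cluster       a           b
#'   background    c           d }
#' The odds ratio is the sample odds ratio `(a*d)/(b*c)` (0/0 gives NaN,
#' x/0 gives Inf). The two-sided p-value sums the probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed one (relative slack 1e-7, the convention of standard
#' implementations); the one-sided enrichment p-value `pGreater` is also
#' returned.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list with `oddsRatio`, `p` (two-sided) and `pGreater`.
#' @examples
#' fisherExactTest(8, 2, 10, 80)$oddsRatio  # 32
#' @export
fisherExactTest <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if (sum(cells) == 0) stop("empty contingency table")
  oddsRatio <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  mWhite <- a + c   # genes with the motif
  nBlack <- b + d
  kDraw <- a + b    # cluster size
  lo <- max(0L, kDraw - nBlack)
  hi <- min(kDraw, mWhite)
  xs <- lo:hi
  probs <- stats::dhyper(xs, mWhite, nBlack, kDraw)
  pObs <- stats::dhyper(a, mWhite, nBlack, kDraw)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  pGreater <- sum(probs[xs >= a])
  list(oddsRatio = oddsRatio, p = min(p, 1), pGreater = min(pGreater, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement,
#' order-preserving with the input vector.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-cluster TF motif enrichment
#'
#' For every (TF, cluster) pair a Fisher exact test compares motif
#' presence in the cluster's genes against the background of all genes
#' from the remaining clusters. BH adjustment is applied across all
#' (TF, cluster) tests jointly by default. A pair is flagged significant
#' when its adjusted two-sided p-value is at or below `alpha` AND the
#' association is an enrichment (odds ratio > 1); depleted TFs are
#' reported but never flagged.
#'
#' @param bin a binarized [TFBSMatrix-class] (entries 0/1).
#' @param labels a [ClusterResult-class] or named integer vector of
#'   cluster labels over the matrix's genes.
#' @param alpha significance level on adjusted p (default 0.05).
#' @param adjustBy "global" (default, one BH family over all tests) or
#'   "per_cluster".
#' @return data.frame with one row per (TF, cluster): `tf_name`,
#'   `cluster`, `a`..`d` cell counts, `odds_ratio`, `p_value`,
#'   `p_greater`, `adj_p`, `significant`.
#' @export
tfEnrichment <- function(bin, labels, alpha = 0.05,
                         adjustBy = c("global", "per_cluster")) {
  adjustBy <- match.arg(adjustBy)
  stopifnot(is(bin, "TFBSMatrix"))
  B <- tfbsCounts(bin)
  if (any(B > 1L)) stop("matrix must be binarized (entries 0/1)")
  lab <- if (is(labels, "ClusterResult")) clusterLabels(labels) else labels
  lab <- lab[rownames(B)]
  if (anyNA(lab)) stop("labels missing for some matrix genes")
  clusters <- sort(unique(lab))
  if (length(clusters) < 2L) {
    stop("at least two clusters are required (no background otherwise)")
  }
  rows <- list()
  for (cl in clusters) {
    inCl <- lab == cl
    nIn <- sum(inCl)
    nOut <- sum(!inCl)
    withIn <- colSums(B[inCl, , drop = FALSE])
    withOut <- colSums(B[!inCl, , drop = FALSE])
    for (t in seq_len(ncol(B))) {
      ft <- fisherExactTest(withIn[t], nIn - withIn[t],
                            withOut[t], nOut - withOut[t])
      rows[[length(rows) + 1L]] <- data.frame(
        tf_name = colnames(B)[t], cluster = cl,
        a = withIn[[t]], b = nIn - withIn[[t]],
        c = withOut[[t]], d = nOut - withOut[[t]],
        odds_ratio = ft$oddsRatio, p_value = ft$p,
        p_greater = ft$pGreater, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (adjustBy == "global") {
    res$adj_p <- bhAdjust(res$p_value)
  } else {
    res$adj_p <- NA_real_
    for (cl in clusters) {
      sel <- res$cluster == cl
      res$adj_p[sel] <- bhAdjust(res$p_value[sel])
    }
  }
  res$significant <- res$adj_p <= alpha &
    !is.nan(res$odds_ratio) & res$odds_ratio > 1
  res
}

#' Flag cluster-unique TFs and drop ubiquitous ones
#'
#' A TF significantly enriched in two or more clusters is "ubiquitous" and
#' removed from the cluster-specific driver set; significant TFs confined
#' to a single cluster are flagged `unique_to_cluster`. The full result
#' table is returned with the flag added — only the unique set changes.
#'
#' @param results data.frame from [tfEnrichment()].
#' @return the input with a logical `unique_to_cluster` column.
#' @export
filterUbiquitous <- function(results) {
  nSig <- tapply(results$significant, results$tf_name, sum)
  results$unique_to_cluster <- results$significant &
    nSig[results$tf_name] == 1L
  results
}

#' Extract the unique driver-TF table
#'
#' @param results output of [filterUbiquitous()].
#' @return the rows flagged `unique_to_cluster`.
#' @export
uniqueTFs <- function(results) {
  results[results$unique_to_cluster, , drop = FALSE]
}

#' Gene-signature enrichment per cluster
#'
#' Fisher exact test of each gene set against each cluster over a gene
#' universe (default: all clustered genes). Matching is case-insensitive.
#' Sets without any overlap with the universe are reported with p = 1 and
#' flagged `no_overlap`. BH adjustment is applied across all (set,
#' cluster) pairs; significance at adjusted p <= `alpha`.
#'
#' @param labels a [ClusterResult-class] or named label vector.
#' @param sets named list of gene-symbol vectors (see [readGmt()]).
#' @param universe optional character vector of universe symbols; defaults
#'   to the clustered genes.
#' @param alpha significance level (default 0.05).
#' @return data.frame with `set`, `cluster`, cell counts, `odds_ratio`,
#'   `p_value`, `adj_p`, `significant`, `no_overlap`.
#' @export
signatureEnrichment <- function(labels, sets, universe = NULL,
                                alpha = 0.05) {
  lab <- if (is(labels, "ClusterResult")) clusterLabels(labels) else labels
  if (is.null(universe)) universe <- names(lab)
  universe <- unique(universe)
  lab <- lab[names(lab) %in% universe]
  clusters <- sort(unique(lab))
  rows <- list()
  for (sn in names(sets)) {
    inSet <- !is.na(.matchCaseInsensitive(names(lab), sets[[sn]]))
    noOv <- !any(inSet)
    for (cl in clusters) {
      inCl <- lab == cl
      a <- sum(inCl & inSet); b <- sum(inCl & !inSet)
      cc <- sum(!inCl & inSet); d <- sum(!inCl & !inSet)
      ft <- if (noOv) list(oddsRatio = NaN, p = 1) else
        fisherExactTest(a, b, cc, d)
      rows[[length(rows) + 1L]] <- data.frame(
        set = sn, cluster = cl, a = a, b = b, c = cc, d = d,
        odds_ratio = ft$oddsRatio, p_value = ft$p,
        no_overlap = noOv, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$adj_p <- bhAdjust(res$p_value)
  res$significant <- res$adj_p <= alpha &
    !is.nan(res$odds_ratio) & res$odds_ratio > 1
  res
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then one or more gene
#' symbols. Duplicate genes within a line are deduplicated; a line without
#' any gene raises an error naming the line.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 3L) {
      stop("malformed GMT line ", i, ": need name, description and >= 1 gene")
    }
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}
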