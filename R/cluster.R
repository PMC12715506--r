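# squared Euclidean distances of rows of X to rows of C (k x p)
.sqDistToCenters <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  d2 <- outer(xx, cc, "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

.kmeansPP <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- .sqDistToCenters(X, centers[1L, , drop = FALSE])[, 1]
  if (k > 1L) for (j in 2:k) {
    i <- if (sum(d2) <= 0) sample.int(n, 1L)
         else sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, .sqDistToCenters(X, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

.lloyd <- function(X, centers, maxIter) {
  k <- nrow(centers)
  lab <- rep(-1L, nrow(X))
  for (it in seq_len(maxIter)) {
    d2 <- .sqDistToCenters(X, centers)
    newLab <- max.col(-d2, ties.method = "first")
    # empty clusters: reseed at the point farthest from its own centroid
    for (cl in which(tabulate(newLab, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(nrow(X)), newLab)])
      centers[cl, ] <- X[far, ]
      d2 <- .sqDistToCenters(X, centers)
      newLab <- max.col(-d2, ties.method = "first")
    }
    if (identical(newLab, lab)) break
    lab <- newLab
    for (cl in seq_len(k)) {
      centers[cl, ] <- colMeans(X[lab == cl, , drop = FALSE])
    }
  }
  d2 <- .sqDistToCenters(X, centers)
  inertia <- sum(d2[cbind(seq_len(nrow(X)), lab)])
  list(labels = lab, centers = centers, inertia = inertia)
}

#' k-means clustering of the gene-by-TF count matrix
#'
#' Lloyd's algorithm with k-means++ initialization, run `nInit` times from
#' a seeded random stream and keeping the restart with the lowest total
#' within-cluster sum of squares (inertia). Clustering operates on the raw
#' integer counts treated as reals, with the Euclidean metric; no
#' transformation is applied. The mean silhouette width is computed on the
#' same matrix and metric. Fully deterministic given `seed`; empty
#' clusters arising during iteration are re-seeded at the point farthest
#' from its assigned centroid.
#'
#' @param m a [TFBSMatrix-class].
#' @param k number of clusters, 2 <= k <= number of distinct rows.
#' @param seed integer seed (default 0).
#' @param nInit number of restarts (default 10).
#' @param maxIter Lloyd iteration cap per restart (default 300).
#' @return a [ClusterResult-class] with 0-based labels.
#' @export
clusterGenes <- function(m, k, seed = 0L, nInit = 10L, maxIter = 300L) {
  stopifnot(is(m, "TFBSMatrix"))
  X <- tfbsCounts(m) + 0.0
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  nDistinct <- nrow(unique(X))
  if (k > nDistinct) {
    stop("k = ", k, " exceeds the number of distinct gene profiles (",
         nDistinct, ")")
  }
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nInit)) {
      fit <- .lloyd(X, .kmeansPP(X, k), maxIter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  sil <- .meanSilhouette(X, best$labels)
  labels <- as.integer(best$labels - 1L)
  names(labels) <- rownames(X)
  if (length(unique(labels)) < k) {
    warning("only ", length(unique(labels)), " of ", k, " clusters are used")
  }
  new("ClusterResult", labels = labels, k = k, centroids = best$centers,
      inertia = best$inertia, silhouette = sil, seed = as.integer(seed))
}

# mean silhouette width; Euclidean, via cluster::silhouette
.meanSilhouette <- function(X, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(labels, stats::dist(X))
  # all-singleton partitions (k = n) have no defined silhouette
  if (!is.matrix(sil)) return(NA_real_)
  mean(sil[, "sil_width"])
}

#' Evaluate a range of k values
#'
#' Runs [clusterGenes()] for each k in `kMin..kMax` under a shared seed
#' policy and reports inertia and mean silhouette per k (the elbow /
#' silhouette diagnostics used to choose the cluster count). A `kMax` at
#' or above the number of distinct gene profiles is truncated with a
#' warning.
#'
#' @inheritParams clusterGenes
#' @param kMin,kMax inclusive k range (defaults 2 and 12).
#' @return data.frame with columns `k`, `inertia`, `silhouette`.
#' @export
evaluateKRange <- function(m, kMin = 2L, kMax = 12L, seed = 0L, nInit = 10L) {
  X <- tfbsCounts(m)
  nDistinct <- nrow(unique(X))
  if (kMax > nDistinct) {
    warning("kMax truncated from ", kMax, " to ", nDistinct,
            " (number of distinct gene profiles)")
    kMax <- nDistinct
  }
  stopifnot(kMin >= 2L, kMax >= kMin)
  rows <- lapply(kMin:kMax, function(k) {
    cr <- clusterGenes(m, k, seed = seed, nInit = nInit)
    data.frame(k = k, inertia = clusterInertia(cr),
               silhouette = clusterSilhouette(cr))
  })
  do.call(rbind, rows)
}

#' Recommend a cluster count from the k-selection report
#'
#' Operationalizes "the highest k before a pronounced decline in
#' silhouette scores": returns the largest k whose silhouette is within
#' `dropFraction` of the maximum over the evaluated range. Advisory only;
#' pipelines accept an explicit k.
#'
#' @param report data.frame from [evaluateKRange()].
#' @param dropFraction relative silhouette decline treated as "pronounced"
#'   (default 0.10).
#' @return integer recommended k.
#' @export
recommendK <- function(report, dropFraction = 0.10) {
  if (!nrow(report)) stop("empty k-selection report")
  bound <- (1 - dropFraction) * max(report$silhouette, na.rm = TRUE)
  max(report$k[!is.na(report$silhouette) & report$silhouette >= bound])
}

#' Two-dimensional diagnostic embedding of the gene-by-TF matrix
#'
#' Principal-coordinates (classical MDS) embedding of the pairwise
#' Canberra distances between gene count profiles, for visual inspection
#' of cluster structure. Purely diagnostic: the embedding never feeds
#' clustering, which always operates on the full count matrix. The
#' computation is deterministic.
#'
#' @param m a [TFBSMatrix-class].
#' @param labels optional [ClusterResult-class] (or named vector) whose
#'   labels are attached to the coordinates.
#' @return data.frame with columns `gene`, `x`, `y` and, when labels are
#'   given, `cluster`.
#' @export
embedGenes <- function(m, labels = NULL) {
  X <- tfbsCounts(m) + 0.0
  d <- stats::dist(X, method = "canberra")
  d[!is.finite(d)] <- 0  # identical all-zero profiles
  xy <- stats::cmdscale(d, k = 2)
  out <- data.frame(gene = rownames(X), x = xy[, 1], y = xy[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    lab <- if (is(labels, "ClusterResult")) clusterLabels(labels) else labels
    out$cluster <- unname(lab[out$gene])
  }
  rownames(out) <- NULL
  out
}
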