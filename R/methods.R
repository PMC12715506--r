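#' @rdname TFMotif-class
#' @export
setMethod("motifId", "TFMotif", function(x) x@motifId)

#' @rdname TFMotif-class
#' @export
setMethod("tfName", "TFMotif", function(x) x@tfName)

#' @rdname TFMotif-class
#' @export
setMethod("motifWidth", "TFMotif", function(x) nrow(x@probs))

#' @rdname TFMotif-class
#' @export
setMethod("motifProbs", "TFMotif", function(x) x@probs)

#' @rdname TFMotif-class
#' @export
setMethod("tfName", "LogOddsMatrix", function(x) x@tfName)

#' @rdname TFMotif-class
#' @export
setMethod("motifId", "LogOddsMatrix", function(x) x@motifId)

#' @rdname TFMotif-class
#' @export
setMethod("motifWidth", "LogOddsMatrix", function(x) nrow(x@scores))

#' @rdname TFMotif-class
#' @export
setMethod("motifId", "ScoreDistribution", function(x) x@motifId)

setMethod("show", "TFMotif", function(object) {
  cat("TFMotif", object@motifId, sprintf("(%s)", object@tfName),
      "width", nrow(object@probs), "\n")
  cat("consensus:", consensusString(object), "\n")
})

#' Consensus sequence of a motif
#'
#' The most probable base at each position (ties broken toward A<C<G<T).
#'
#' @param x a [TFMotif-class].
#' @return character(1) consensus sequence.
#' @export
consensusString <- function(x) {
  stopifnot(is(x, "TFMotif"))
  paste(DNA_BASES[max.col(x@probs, ties.method = "first")], collapse = "")
}

#' @rdname MarkovBackground-class
#' @export
setMethod("bgOrder", "MarkovBackground", function(x) x@order)

#' @rdname MarkovBackground-class
#' @export
setMethod("bgFreqs", "MarkovBackground", function(x) x@freqs)

#' @rdname MarkovBackground-class
#' @export
setMethod("bgMarginal", "MarkovBackground", function(x) x@marginal)

setMethod("show", "MarkovBackground", function(object) {
  cat("MarkovBackground order", object@order, "from", object@source, "\n")
  cat("marginal:", paste(sprintf("%s=%.4f", DNA_BASES, object@marginal),
                         collapse = " "), "\n")
})

setMethod("show", "LogOddsMatrix", function(object) {
  cat("LogOddsMatrix", object@motifId, sprintf("(%s)", object@tfName),
      "width", nrow(object@scores),
      sprintf("score range [%.3f, %.3f]\n",
              sum(apply(object@scores, 1, min)),
              sum(apply(object@scores, 1, max))))
})

setMethod("show", "ScoreDistribution", function(object) {
  cat("ScoreDistribution", object@motifId,
      sprintf("bins=%d binWidth=%g\n", length(object@pmf), object@binWidth))
})

#' @rdname PromoterSet-class
#' @export
setMethod("promoterRegions", "PromoterSet", function(x) x@regions)

#' @rdname PromoterSet-class
#' @export
setMethod("promoterSeqs", "PromoterSet", function(x) x@seqs)

#' @rdname PromoterSet-class
#' @export
setMethod("length", "PromoterSet", function(x) length(x@regions))

#' @rdname PromoterSet-class
#' @param i index (numeric, logical or gene-symbol character).
#' @export
setMethod("[", "PromoterSet", function(x, i) {
  if (is.character(i)) {
    i <- match(i, S4Vectors::mcols(x@regions)$symbol)
    if (anyNA(i)) stop("unknown gene symbol(s) in promoter subset")
  }
  new("PromoterSet", regions = x@regions[i], seqs = x@seqs[i])
})

setMethod("show", "PromoterSet", function(object) {
  cat("PromoterSet with", length(object), "promoters\n")
  if (length(object)) {
    w <- GenomicRanges::width(object@regions)
    cat("widths:", min(w), "-", max(w), "bp\n")
  }
})

#' @rdname TFBSMatrix-class
#' @export
setMethod("tfbsCounts", "TFBSMatrix", function(x) x@counts)

#' @rdname TFBSMatrix-class
#' @export
setMethod("geneNames", "TFBSMatrix", function(x) rownames(x@counts))

#' @rdname TFBSMatrix-class
#' @export
setMethod("tfNames", "TFBSMatrix", function(x) colnames(x@counts))

#' @rdname TFBSMatrix-class
#' @export
setMethod("dim", "TFBSMatrix", function(x) dim(x@counts))

#' @rdname binarize
#' @export
setMethod("binarize", "TFBSMatrix", function(x) {
  new("TFBSMatrix", counts = pmin(x@counts, 1L))
})

setMethod("show", "TFBSMatrix", function(object) {
  d <- dim(object@counts)
  cat("TFBSMatrix:", d[1], "genes x", d[2], "TFs;",
      sum(object@counts), "collapsed occurrences\n")
})

#' @rdname ClusterResult-class
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname ClusterResult-class
#' @export
setMethod("clusterCentroids", "ClusterResult", function(x) x@centroids)

#' @rdname ClusterResult-class
#' @export
setMethod("clusterInertia", "ClusterResult", function(x) x@inertia)

#' @rdname ClusterResult-class
#' @export
setMethod("clusterSilhouette", "ClusterResult", function(x) x@silhouette)

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k =", object@k, "on", length(object@labels), "genes;",
      sprintf("inertia %.2f, mean silhouette %.3f\n",
              object@inertia, object@silhouette))
  print(table(cluster = object@labels))
})
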