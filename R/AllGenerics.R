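#' @rdname TFMotif-class
#' @param x,object an object.
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))

#' @rdname TFMotif-class
#' @export
setGeneric("tfName", function(x) standardGeneric("tfName"))

#' @rdname TFMotif-class
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @rdname TFMotif-class
#' @export
setGeneric("motifProbs", function(x) standardGeneric("motifProbs"))

#' @rdname MarkovBackground-class
#' @export
setGeneric("bgOrder", function(x) standardGeneric("bgOrder"))

#' @rdname MarkovBackground-class
#' @export
setGeneric("bgFreqs", function(x) standardGeneric("bgFreqs"))

#' @rdname MarkovBackground-class
#' @export
setGeneric("bgMarginal", function(x) standardGeneric("bgMarginal"))

#' @rdname PromoterSet-class
#' @export
setGeneric("promoterRegions", function(x) standardGeneric("promoterRegions"))

#' @rdname PromoterSet-class
#' @export
setGeneric("promoterSeqs", function(x) standardGeneric("promoterSeqs"))

#' @rdname TFBSMatrix-class
#' @export
setGeneric("tfbsCounts", function(x) standardGeneric("tfbsCounts"))

#' @rdname TFBSMatrix-class
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname TFBSMatrix-class
#' @export
setGeneric("tfNames", function(x) standardGeneric("tfNames"))

#' Binarize a gene-by-TF count matrix
#'
#' Reduces motif occurrence counts to presence/absence: an entry becomes 1
#' iff at least one collapsed occurrence was counted. Idempotent.
#'
#' @param x a [TFBSMatrix-class].
#' @return a [TFBSMatrix-class] with entries in \{0, 1\}.
#' @export
setGeneric("binarize", function(x) standardGeneric("binarize"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterInertia", function(x) standardGeneric("clusterInertia"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterSilhouette", function(x) standardGeneric("clusterSilhouette"))
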