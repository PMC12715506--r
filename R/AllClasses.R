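#' @import methods
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' TFMotif: a position weight matrix for one transcription factor
#'
#' Per-position base probabilities describing the binding preference of one
#' TF, in fixed alphabet order A, C, G, T. The motif identifier is the name
#' used in the motif database; `tfName` is the gene symbol of the TF (case
#' preserved), taken from the motif's alternate name when one exists.
#'
#' @slot motifId character(1) motif identifier.
#' @slot tfName character(1) TF gene symbol.
#' @slot probs numeric matrix, width x 4, rows summing to 1; columns A,C,G,T.
#' @slot nsites numeric(1) number of sites the matrix was built from (NA if
#'   unknown).
#'
#' @exportClass TFMotif
setClass("TFMotif",
  slots = c(
    motifId = "character",
    tfName  = "character",
    probs   = "matrix",
    nsites  = "numeric"
  )
)

setValidity("TFMotif", function(object) {
  p <- object@probs
  if (!is.numeric(p) || ncol(p) != 4L) {
    return("probs must be a numeric matrix with 4 columns (A,C,G,T)")
  }
  if (nrow(p) < 1L) return("motif width must be >= 1")
  if (any(p < 0)) return("probabilities must be non-negative")
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    return("every probs row must sum to 1 (tolerance 1e-6)")
  }
  if (length(object@motifId) != 1L || !nzchar(object@motifId)) {
    return("motifId must be a non-empty string")
  }
  TRUE
})

#' MarkovBackground: a Markov nucleotide background model
#'
#' Conditional base frequencies of the scanned sequence set, estimated by
#' strand-symmetric k-mer counting (sequences pooled with their reverse
#' complements) and pseudocount smoothing. Row names are the length-`order`
#' contexts ("" for order 0). The order-0 marginal is stored alongside and
#' is the null used for log-odds scoring and exact p-values.
#'
#' @slot order integer(1), Markov order in 0..2.
#' @slot freqs numeric matrix, 4^order x 4; each row sums to 1, all
#'   entries > 0.
#' @slot marginal numeric(4), order-0 base frequencies (A,C,G,T).
#' @slot source character(1) description of the estimation input.
#'
#' @exportClass MarkovBackground
setClass("MarkovBackground",
  slots = c(
    order    = "integer",
    freqs    = "matrix",
    marginal = "numeric",
    source   = "character"
  )
)

setValidity("MarkovBackground", function(object) {
  if (!(object@order %in% 0:2)) return("order must be 0, 1 or 2")
  f <- object@freqs
  if (nrow(f) != 4L^object@order || ncol(f) != 4L) {
    return("freqs must be a 4^order x 4 matrix")
  }
  if (any(f <= 0)) return("all conditional probabilities must be > 0")
  if (any(abs(rowSums(f) - 1) > 1e-6)) {
    return("each conditional row must sum to 1 (tolerance 1e-6)")
  }
  if (length(object@marginal) != 4L || any(object@marginal <= 0) ||
      abs(sum(object@marginal) - 1) > 1e-6) {
    return("marginal must be 4 positive frequencies summing to 1")
  }
  TRUE
})

#' LogOddsMatrix: position-wise log2-odds scores for one motif
#'
#' log2 of the pseudocount-smoothed motif probability over the background
#' marginal, per position and base. The total score of a sequence window is
#' the sum of its per-position entries; a column identical to the background
#' scores 0.
#'
#' @slot motifId,tfName character(1) identifiers carried from the motif.
#' @slot scores numeric matrix, width x 4 of finite log2-odds values.
#' @slot pseudocount numeric(1) smoothing used in the conversion.
#'
#' @exportClass LogOddsMatrix
setClass("LogOddsMatrix",
  slots = c(
    motifId = "character",
    tfName  = "character",
    scores  = "matrix",
    pseudocount = "numeric"
  )
)

setValidity("LogOddsMatrix", function(object) {
  s <- object@scores
  if (!is.numeric(s) || ncol(s) != 4L || nrow(s) < 1L) {
    return("scores must be a width x 4 numeric matrix")
  }
  if (any(!is.finite(s))) return("all log-odds entries must be finite")
  TRUE
})

#' ScoreDistribution: exact null distribution of a motif's total score
#'
#' Probability mass of the total log-odds score of a random word drawn
#' i.i.d. from the order-0 background marginal, on a discretized score grid
#' of width `binWidth`. Computed by position-wise convolution; the survival
#' function gives p-values P(score >= s).
#'
#' @slot motifId character(1).
#' @slot binWidth numeric(1) score discretization step.
#' @slot pmf numeric vector of bin probabilities (sums to 1).
#' @slot offset integer(1), integer bin index of `pmf[1]` (bin b covers
#'   scores near b * binWidth).
#' @slot survival numeric vector, survival[i] = P(binned score >= bin i).
#'
#' @exportClass ScoreDistribution
setClass("ScoreDistribution",
  slots = c(
    motifId  = "character",
    binWidth = "numeric",
    pmf      = "numeric",
    offset   = "integer",
    survival = "numeric"
  )
)

setValidity("ScoreDistribution", function(object) {
  if (object@binWidth <= 0) return("binWidth must be > 0")
  if (abs(sum(object@pmf) - 1) > 1e-9) return("pmf must sum to 1 (1e-9)")
  if (length(object@survival) != length(object@pmf)) {
    return("survival and pmf must have equal length")
  }
  if (any(diff(object@survival) > 1e-12)) {
    return("survival function must be non-increasing")
  }
  TRUE
})

#' PromoterSet: promoter intervals and their strand-corrected sequences
#'
#' Genomic promoter windows around each gene's TSS together with the
#' extracted sequence, oriented 5'->3' relative to the gene (minus-strand
#' sequences are reverse-complemented so that position 0 is the most
#' upstream promoter base).
#'
#' @slot regions a [GenomicRanges::GRanges] with metadata columns
#'   `gene_id`, `symbol` and `tss` (0-based TSS coordinate).
#' @slot seqs a [Biostrings::DNAStringSet], one sequence per region, named
#'   by gene symbol.
#'
#' @exportClass PromoterSet
setClass("PromoterSet",
  slots = c(
    regions = "GRanges",
    seqs    = "DNAStringSet"
  )
)

setValidity("PromoterSet", function(object) {
  if (length(object@regions) != length(object@seqs)) {
    return("regions and seqs must be parallel")
  }
  need <- c("gene_id", "symbol", "tss")
  if (!all(need %in% colnames(S4Vectors::mcols(object@regions)))) {
    return("regions must carry gene_id, symbol and tss metadata columns")
  }
  if (length(object@regions) &&
      !all(GenomicRanges::width(object@regions) ==
           Biostrings::width(object@seqs))) {
    return("sequence lengths must equal region widths")
  }
  TRUE
})

#' TFBSMatrix: gene-by-TF motif occurrence counts
#'
#' Non-negative integer counts of collapsed motif occurrences, rows =
#' differentially regulated genes, columns = expressed TFs. The raw count
#' matrix is the clustering input; [binarize()] reduces it to
#' presence/absence for enrichment testing.
#'
#' @slot counts integer matrix with unique row (gene) and column (TF) names.
#'
#' @exportClass TFBSMatrix
setClass("TFBSMatrix", slots = c(counts = "matrix"))

setValidity("TFBSMatrix", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    return("counts must have gene row names and TF column names")
  }
  if (anyDuplicated(rownames(m))) return("duplicate gene (row) labels")
  if (anyDuplicated(colnames(m))) return("duplicate TF (column) labels")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(m != round(m))) return("counts must be integers")
  TRUE
})

#' ClusterResult: a k-means partition of the gene-by-TF matrix
#'
#' Gene module labels (0-based, as in the cluster assignment files) with the
#' quality metrics of the selected restart: total within-cluster sum of
#' squares (inertia) and the mean silhouette width under the Euclidean
#' metric used for clustering.
#'
#' @slot labels named integer vector, gene -> cluster in 0..(k-1).
#' @slot k integer(1) number of clusters.
#' @slot centroids numeric matrix k x n_TF.
#' @slot inertia numeric(1) total within-cluster sum of squares.
#' @slot silhouette numeric(1) mean silhouette width in [-1, 1].
#' @slot seed integer(1) seed the restarts were drawn from.
#'
#' @exportClass ClusterResult
setClass("ClusterResult",
  slots = c(
    labels     = "integer",
    k          = "integer",
    centroids  = "matrix",
    inertia    = "numeric",
    silhouette = "numeric",
    seed       = "integer"
  )
)

setValidity("ClusterResult", function(object) {
  if (is.null(names(object@labels))) return("labels must be named by gene")
  if (any(object@labels < 0L | object@labels >= object@k)) {
    return("labels must lie in 0..(k-1)")
  }
  if (object@inertia < 0) return("inertia must be non-negative")
  TRUE
})
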