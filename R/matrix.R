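#' Collapse overlapping motif hits per gene and TF
#'
#' Within each (gene, TF) group — hits from multiple motifs of the same TF
#' are pooled first — intervals on the promoter axis are merged into
#' connected components under the relation "overlap of at least 1 bp".
#' Merging is strand-agnostic; touching half-open intervals (e.g.
#' `[10,20)` and `[20,30)`) share no base and are never merged. One record
#' per component is returned with its span and member count.
#'
#' @param hits hit data.frame with `gene_symbol`, `tf_name`, `start`,
#'   `end` (0-based half-open).
#' @return data.frame with columns `gene_symbol`, `tf_name`, `start`,
#'   `end`, `n_hits`.
#' @export
collapseHits <- function(hits) {
  if (!nrow(hits)) {
    return(data.frame(gene_symbol = character(), tf_name = character(),
                      start = integer(), end = integer(),
                      n_hits = integer(), stringsAsFactors = FALSE))
  }
  if (any(hits$end < hits$start)) stop("negative-length hit interval")
  key <- paste(hits$gene_symbol, hits$tf_name, sep = "\r")
  groups <- split(seq_len(nrow(hits)), key)
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    ir <- IRanges::IRanges(start = hits$start[idx] + 1L,
                           end = hits$end[idx])
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    out[[i]] <- data.frame(
      gene_symbol = hits$gene_symbol[idx[1]],
      tf_name = hits$tf_name[idx[1]],
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      n_hits = lengths(S4Vectors::mcols(red)$revmap),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_symbol, res$tf_name, res$start,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the gene-by-TF count matrix
#'
#' `counts[g, t]` is the number of collapsed occurrence components for TF t
#' in the promoter of gene g. Genes without any hit are kept as all-zero
#' rows so the matrix honors the full DRG list; TFs represented by several
#' motifs occupy a single column because hits were pooled by TF name
#' before collapsing.
#'
#' @param collapsed data.frame from [collapseHits()].
#' @param genes ordered, deduplicated gene symbols (matrix rows).
#' @param tfs ordered, deduplicated TF symbols (matrix columns).
#' @return a [TFBSMatrix-class].
#' @export
buildTFBSMatrix <- function(collapsed, genes, tfs) {
  if (anyDuplicated(genes)) stop("duplicate gene symbols in row list")
  if (anyDuplicated(tfs)) stop("duplicate TF symbols in column list")
  m <- matrix(0L, nrow = length(genes), ncol = length(tfs),
              dimnames = list(genes, tfs))
  if (nrow(collapsed)) {
    gi <- match(collapsed$gene_symbol, genes)
    ti <- match(collapsed$tf_name, tfs)
    if (anyNA(gi)) {
      stop("collapsed table references gene(s) outside the DRG list: ",
           paste(unique(collapsed$gene_symbol[is.na(gi)]), collapse = ", "))
    }
    if (anyNA(ti)) {
      stop("collapsed table references TF(s) outside the TF list: ",
           paste(unique(collapsed$tf_name[is.na(ti)]), collapse = ", "))
    }
    for (i in seq_along(gi)) m[gi[i], ti[i]] <- m[gi[i], ti[i]] + 1L
  }
  nz <- sum(rowSums(m) == 0)
  if (nz) message(nz, " gene(s) have zero motif hits (all-zero rows kept)")
  new("TFBSMatrix", counts = m)
}

#' Shuffle the gene-symbol column of a hit table
#'
#' The randomization control: the gene labels of the summarized hit table
#' are permuted uniformly at random (Fisher-Yates via `sample()`, seeded),
#' all other columns untouched. Re-running collapse and counting on the
#' shuffled table yields a matrix of the original shape and approximate
#' value range but without biological structure.
#'
#' @param hits hit data.frame.
#' @param seed integer seed; the same seed reproduces the permutation.
#' @return the hit table with permuted `gene_symbol`.
#' @export
shuffleGeneLabels <- function(hits, seed) {
  if (!nrow(hits)) return(hits)
  perm <- withr::with_seed(as.integer(seed), sample.int(nrow(hits)))
  hits$gene_symbol <- hits$gene_symbol[perm]
  hits
}

#' Write / read a gene-by-TF matrix as TSV
#'
#' Header row of TF names, first column `gene` of gene symbols; round-trip
#' exact. Reading validates label uniqueness and that all cells are
#' non-negative integers.
#'
#' @param m a [TFBSMatrix-class].
#' @param path TSV path.
#' @param header optional provenance comment lines.
#' @export
writeTFBSMatrix <- function(m, path, header = NULL) {
  df <- data.frame(gene = geneNames(m), tfbsCounts(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(df, path, header)
  invisible(path)
}

#' @rdname writeTFBSMatrix
#' @return `readTFBSMatrix`: a [TFBSMatrix-class].
#' @export
readTFBSMatrix <- function(path) {
  df <- .readTsv(path)
  if (colnames(df)[1] != "gene") stop("first column must be 'gene'")
  if (anyDuplicated(df$gene)) stop("duplicate gene labels in ", path)
  if (anyDuplicated(colnames(df)[-1])) {
    stop("duplicate TF labels in ", path)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(vals != round(vals)) || any(vals < 0)) {
    stop("matrix cells must be non-negative integers")
  }
  storage.mode(vals) <- "integer"
  rownames(vals) <- df$gene
  new("TFBSMatrix", counts = vals)
}

#' Subset a gene-by-TF matrix (precomputed-matrix mode)
#'
#' Case-insensitive subsetting of rows to a DRG list and/or columns to an
#' expressed-TF list, preserving the matrix's own row and column order.
#'
#' @param m a [TFBSMatrix-class].
#' @param genes optional DRG symbols to retain.
#' @param tfs optional TF symbols to retain.
#' @return a [TFBSMatrix-class] submatrix.
#' @export
subsetTFBSMatrix <- function(m, genes = NULL, tfs = NULL) {
  cnt <- tfbsCounts(m)
  ri <- seq_len(nrow(cnt))
  ci <- seq_len(ncol(cnt))
  if (!is.null(genes)) {
    ri <- which(toupper(rownames(cnt)) %in% toupper(genes))
    if (!length(ri)) stop("no matrix row matches the DRG list")
  }
  if (!is.null(tfs)) {
    ci <- which(toupper(colnames(cnt)) %in% toupper(tfs))
    if (!length(ci)) stop("no matrix column matches the TF list")
  }
  new("TFBSMatrix", counts = cnt[ri, ci, drop = FALSE])
}
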