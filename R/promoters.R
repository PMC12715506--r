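#' Read gene annotation and derive TSS records
#'
#' Supports GTF, GFF3 and BED6 input. For GTF/GFF3, one record per gene is
#' produced using the 5'-most transcript start on the gene's strand (the
#' most upstream start in gene orientation); genes without transcript
#' features fall back to the gene-level start with a warning. BED6 lines
#' are taken as TSS point features (tss = start for `+`, tss = end - 1 for
#' `-`, in 0-based coordinates). Records without a usable strand are
#' skipped with a warning.
#'
#' All coordinates are handled 0-based half-open internally; 1-based GTF/
#' GFF3 coordinates are converted on read.
#'
#' @param path annotation file path.
#' @param format one of "gtf", "gff3", "bed6" (default guessed from the
#'   file extension).
#' @return data.frame with columns `gene_id`, `symbol`, `contig`, `strand`,
#'   `tss` (0-based coordinate of the first transcribed base).
#' @export
readAnnotation <- function(path, format = c("auto", "gtf", "gff3", "bed6")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, gtf = "gtf", gff = "gff3", gff3 = "gff3",
                     bed = "bed6",
                     stop("cannot guess annotation format from '", ext, "'"))
  }
  if (format == "bed6") {
    gr <- rtracklayer::import(path, format = "BED")
    strand <- as.character(GenomicRanges::strand(gr))
    drop <- !(strand %in% c("+", "-"))
    if (any(drop)) {
      warning(sum(drop), " BED record(s) without strand skipped")
      gr <- gr[!drop]
      strand <- strand[!drop]
    }
    if (!length(gr)) stop("no usable TSS records in ", path)
    tss <- ifelse(strand == "+",
                  GenomicRanges::start(gr) - 1L,  # back to 0-based
                  GenomicRanges::end(gr) - 1L)
    nm <- gr$name
    if (is.null(nm)) nm <- paste0("feature", seq_along(gr))
    return(data.frame(gene_id = nm, symbol = nm,
                      contig = as.character(GenomicRanges::seqnames(gr)),
                      strand = strand, tss = as.integer(tss),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = ifelse(format == "gtf",
                                                  "gtf", "gff3"))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  geneId <- if ("gene_id" %in% colnames(md)) as.character(md$gene_id)
            else as.character(md$ID)
  symbol <- if ("gene_name" %in% colnames(md)) as.character(md$gene_name)
            else if ("Name" %in% colnames(md)) as.character(md$Name)
            else geneId
  strand <- as.character(GenomicRanges::strand(gr))
  isTx <- type %in% c("transcript", "mRNA")
  isGene <- type == "gene"
  out <- list()
  for (g in unique(geneId[isGene | isTx])) {
    sel <- which(geneId == g & isTx & strand %in% c("+", "-"))
    fromGene <- FALSE
    if (!length(sel)) {
      sel <- which(geneId == g & isGene & strand %in% c("+", "-"))
      fromGene <- TRUE
      if (!length(sel)) {
        warning("gene ", g, " has no stranded feature; skipped")
        next
      }
      if (any(geneId == g & isGene)) {
        warning("gene ", g, " has no transcript features; gene-level start used")
      }
    }
    st <- strand[sel[1]]
    tss1 <- if (st == "+") min(GenomicRanges::start(gr[sel]))
            else max(GenomicRanges::end(gr[sel]))
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g,
      symbol = symbol[sel[1]],
      contig = as.character(GenomicRanges::seqnames(gr[sel[1]])),
      strand = st,
      tss = as.integer(tss1 - 1L),
      stringsAsFactors = FALSE)
    if (fromGene) invisible(NULL)
  }
  if (!length(out)) stop("no usable gene records in ", path)
  do.call(rbind, out)
}

#' Define promoter windows around TSSs
#'
#' The promoter spans `upstream` bases 5' of the TSS through `downstream`
#' bases 3' of it, with the TSS itself included, so the unclipped window is
#' `upstream + downstream + 1` bp (2,501 bp at the -2000..+500 default).
#' In 0-based half-open coordinates: `[tss - upstream, tss + downstream + 1)`
#' on `+`, `[tss - downstream, tss + upstream + 1)` on `-`. Windows are
#' clipped at contig edges; genes whose window becomes empty are dropped
#' with a warning.
#'
#' @param annotation data.frame as returned by [readAnnotation()].
#' @param upstream,downstream non-negative window extents (defaults 2000
#'   and 500).
#' @param contigLengths named integer vector of contig lengths.
#' @return a [GenomicRanges::GRanges] with metadata `gene_id`, `symbol`,
#'   `tss`.
#' @export
definePromoters <- function(annotation, upstream = 2000L, downstream = 500L,
                            contigLengths) {
  stopifnot(upstream >= 0, downstream >= 0)
  miss <- setdiff(unique(annotation$contig), names(contigLengths))
  if (length(miss)) {
    stop("contig(s) missing from the genome: ", paste(miss, collapse = ", "))
  }
  len <- contigLengths[annotation$contig]
  plus <- annotation$strand == "+"
  start0 <- ifelse(plus, annotation$tss - upstream,
                   annotation$tss - downstream)
  end0 <- ifelse(plus, annotation$tss + downstream + 1L,
                 annotation$tss + upstream + 1L)
  start0 <- pmax(start0, 0L)
  end0 <- pmin(end0, as.integer(len))
  keep <- end0 > start0
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) dropped: promoter window empty after ",
            "clipping at contig edges")
  }
  ann <- annotation[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(start = start0[keep] + 1L, end = end0[keep]),
    strand = ann$strand,
    gene_id = ann$gene_id, symbol = ann$symbol, tss = ann$tss)
  GenomeInfoDb::seqlengths(gr) <-
    contigLengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Extract strand-corrected promoter sequences from a genome FASTA
#'
#' Sequences are upper-cased; minus-strand promoters are
#' reverse-complemented so that position 0 of every sequence is the most
#' upstream promoter base in gene orientation.
#'
#' @param genome path to a genome FASTA file, or a named
#'   [Biostrings::DNAStringSet].
#' @param regions promoter [GenomicRanges::GRanges] from
#'   [definePromoters()].
#' @return a [PromoterSet-class].
#' @export
extractPromoterSeqs <- function(genome, regions) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  }
  contigs <- as.character(GenomicRanges::seqnames(regions))
  miss <- setdiff(unique(contigs), names(genome))
  if (length(miss)) {
    stop("contig(s) absent from the FASTA: ", paste(miss, collapse = ", "))
  }
  seqs <- character(length(regions))
  for (i in seq_along(regions)) {
    s <- toupper(as.character(Biostrings::subseq(
      genome[[contigs[i]]],
      start = GenomicRanges::start(regions)[i],
      end = GenomicRanges::end(regions)[i])))
    if (as.character(GenomicRanges::strand(regions))[i] == "-") {
      s <- reverseComplement2(s)
    }
    seqs[i] <- s
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- S4Vectors::mcols(regions)$symbol
  new("PromoterSet", regions = regions, seqs = dss)
}

#' Subset promoters to a list of differentially regulated genes
#'
#' Case-insensitive symbol matching; duplicate input symbols are
#' deduplicated (with a message) and unmatched symbols are reported in the
#' `unmatched` attribute of the result.
#'
#' @param promoters a [PromoterSet-class].
#' @param drgs character vector of DRG symbols.
#' @return a [PromoterSet-class] restricted to matched DRGs, with attribute
#'   `unmatched` listing symbols absent from the annotation.
#' @export
subsetToDrgs <- function(promoters, drgs) {
  ndup <- sum(duplicated(toupper(drgs)))
  if (ndup) message(ndup, " duplicate DRG symbol(s) deduplicated")
  drgs <- drgs[!duplicated(toupper(drgs))]
  sym <- S4Vectors::mcols(promoterRegions(promoters))$symbol
  idx <- .matchCaseInsensitive(drgs, sym)
  unmatched <- drgs[is.na(idx)]
  if (all(is.na(idx))) {
    stop("no DRG symbol matches the annotation; check that gene lists and ",
         "annotation use the same symbol space")
  }
  out <- promoters[idx[!is.na(idx)]]
  attr(out, "unmatched") <- unmatched
  out
}
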