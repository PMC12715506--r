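writeToyGenome <- function(contigs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(contigs), function(n)
    c(paste0(">", n), contigs[[n]]))), fa)
  fa
}

test_that("BED6 TSS records use the point-feature convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t5000\t5001\tGeneA\t0\t-",
               "chr1\t100\t101\tGeneB\t0\t+",
               "chr1\t7\t8\tGeneC\t0\t."), bed)
  expect_warning(ann <- readAnnotation(bed), "without strand")
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$tss[ann$symbol == "GeneA"], 5000L)
  expect_equal(ann$tss[ann$symbol == "GeneB"], 100L)
})

test_that("GTF genes use the 5'-most transcript start per strand", {
  gtf <- tempfile(fileext = ".gtf")
  attrs <- function(g) sprintf('gene_id "%s"; gene_name "%s";', g, g)
  writeLines(c(
    paste("chr1", "src", "gene", 1000, 2000, ".", "+", ".", attrs("g1"),
          sep = "\t"),
    paste("chr1", "src", "transcript", 1000, 1500, ".", "+", ".",
          attrs("g1"), sep = "\t"),
    paste("chr1", "src", "transcript", 1200, 2000, ".", "+", ".",
          attrs("g1"), sep = "\t"),
    paste("chr1", "src", "gene", 3000, 4000, ".", "-", ".", attrs("g2"),
          sep = "\t"),
    paste("chr1", "src", "transcript", 3000, 3500, ".", "-", ".",
          attrs("g2"), sep = "\t"),
    paste("chr1", "src", "transcript", 3200, 4000, ".", "-", ".",
          attrs("g2"), sep = "\t"),
    paste("chr1", "src", "gene", 9000, 9100, ".", "+", ".", attrs("g3"),
          sep = "\t")), gtf)
  expect_warning(ann <- readAnnotation(gtf), "gene-level start")
  # + strand: earliest start (1-based 1000 -> 0-based 999)
  expect_equal(ann$tss[ann$gene_id == "g1"], 999L)
  # - strand: largest end (1-based 4000 -> 0-based 3999)
  expect_equal(ann$tss[ann$gene_id == "g2"], 3999L)
  # gene without transcripts falls back to the gene record
  expect_equal(ann$tss[ann$gene_id == "g3"], 8999L)
})

test_that("promoter windows are upstream+downstream+1 bp and clip at edges", {
  ann <- data.frame(gene_id = c("a", "b", "c"), symbol = c("a", "b", "c"),
                    contig = "chr1", strand = c("+", "-", "+"),
                    tss = c(10000L, 10000L, 100L))
  gr <- suppressWarnings(
    definePromoters(ann, 2000L, 500L, c(chr1 = 20000L)))
  # + strand: [8000, 10501)
  expect_equal(GenomicRanges::start(gr)[1] - 1L, 8000L)
  expect_equal(GenomicRanges::end(gr)[1], 10501L)
  expect_equal(GenomicRanges::width(gr)[1], 2501L)
  # - strand: [9500, 12001)
  expect_equal(GenomicRanges::start(gr)[2] - 1L, 9500L)
  expect_equal(GenomicRanges::end(gr)[2], 12001L)
  expect_equal(GenomicRanges::width(gr)[2], 2501L)
  # clipped at the contig start: [0, 601)
  expect_equal(GenomicRanges::start(gr)[3] - 1L, 0L)
  expect_equal(GenomicRanges::width(gr)[3], 601L)
  expect_error(definePromoters(ann, 2000L, 500L, c(chrX = 1000L)),
               "missing from the genome")
})

test_that("sequence extraction is strand-corrected and upper-cased", {
  fa <- writeToyGenome(list(chr1 = "acgtacgt"))
  mkAnn <- function(strand) data.frame(gene_id = "g", symbol = "g",
                                       contig = "chr1", strand = strand,
                                       tss = 3L)
  # + strand, tss 3, upstream 1, downstream 2 -> [2, 6) = GTAC
  grP <- definePromoters(mkAnn("+"), 1L, 2L, c(chr1 = 8L))
  ps <- extractPromoterSeqs(fa, grP)
  expect_equal(as.character(promoterSeqs(ps)[[1]]), "GTAC")
  # - strand, tss 3, upstream 2, downstream 1 -> [2, 6) reverse-complemented
  grM <- definePromoters(mkAnn("-"), 2L, 1L, c(chr1 = 8L))
  psM <- extractPromoterSeqs(fa, grM)
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GTAC")))
  expect_equal(as.character(promoterSeqs(psM)[[1]]), oracle)
  expect_error(
    extractPromoterSeqs(fa, definePromoters(
      data.frame(gene_id = "g", symbol = "g", contig = "chr9",
                 strand = "+", tss = 3L), 1L, 1L, c(chr9 = 8L))),
    "absent from the FASTA")
})

test_that("reverse complement agrees with Biostrings on random sequences", {
  withr::with_seed(3, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:40, 1), TRUE),
                 collapse = "")
      expect_equal(reverseComplement2(s),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(s))))
    }
  })
})

test_that("minus-strand extraction equals revcomp of the mirrored window", {
  withr::with_seed(9, {
    for (i in 1:5) {
      contig <- paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                      collapse = "")
      fa <- writeToyGenome(list(c1 = contig))
      tss <- sample(60:140, 1)
      annP <- data.frame(gene_id = "g", symbol = "g", contig = "c1",
                         strand = "+", tss = tss)
      annM <- annP; annM$strand <- "-"
      # same genomic interval: swap upstream/downstream for the - gene
      grP <- definePromoters(annP, 30L, 10L, c(c1 = 200L))
      grM <- definePromoters(annM, 10L, 30L, c(c1 = 200L))
      sP <- as.character(promoterSeqs(extractPromoterSeqs(fa, grP))[[1]])
      sM <- as.character(promoterSeqs(extractPromoterSeqs(fa, grM))[[1]])
      expect_equal(sM, naiveRevComp(sP))
    }
  })
})

test_that("DRG subsetting matches case-insensitively and reports misses", {
  fa <- writeToyGenome(list(chr1 = strrep("ACGT", 30)))
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    symbol = c("Tox", "Gapdh", "Foxp1"),
                    contig = "chr1", strand = "+", tss = c(30L, 60L, 90L))
  ps <- extractPromoterSeqs(fa, definePromoters(ann, 5L, 5L,
                                                c(chr1 = 120L)))
  expect_message(sub <- subsetToDrgs(ps, c("TOX", "FAKE1", "tox")),
                 "deduplicated")
  expect_equal(length(sub), 1L)
  expect_equal(attr(sub, "unmatched"), "FAKE1")
  expect_error(subsetToDrgs(ps, c("NOPE")), "symbol space")
})
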