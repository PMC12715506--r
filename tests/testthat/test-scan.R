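strongMotif <- function(consensus, p = 0.97) {
  base <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  idx <- base[strsplit(consensus, "")[[1]]]
  probs <- matrix((1 - p) / 3, length(idx), 4)
  probs[cbind(seq_along(idx), idx)] <- p
  makeTFMotif(paste0("M_", consensus), paste0("Tf_", consensus), probs)
}

scanSetup <- function(consensus, p = 0.97) {
  bg <- uniformBackground()
  lo <- toLogOdds(strongMotif(consensus, p), bg)
  list(lo = lo, dist = scoreDistribution(lo, bg), bg = bg)
}

test_that("a planted consensus site is found at the right offset", {
  s <- scanSetup("ACGG")
  cfg <- scanConfig(pPrefilter = 0.005)
  hits <- scanSequence(s$lo, s$dist, "TTACGGTT", cfg, "g1")
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 2L)
  expect_equal(plus$end, 6L)
  expect_equal(plus$matched, "ACGG")
  # reverse-complement planting: CCGT on the forward strand
  hitsM <- scanSequence(s$lo, s$dist, "TTCCGTTT", cfg, "g1")
  minus <- hitsM[hitsM$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$start, 2L)
  expect_equal(minus$matched, "ACGG")
})

test_that("degenerate inputs behave as specified", {
  s <- scanSetup("ACGG")
  # zero-information motif: all windows score 0, p = 1, nothing passes
  bg <- uniformBackground()
  flat <- toLogOdds(makeTFMotif("f", "f", matrix(0.25, 4, 4)), bg)
  dFlat <- scoreDistribution(flat, bg)
  expect_equal(nrow(scanSequence(flat, dFlat, "ACGTACGTAC",
                                 scanConfig(pPrefilter = 0.9))), 0L)
  # sequence shorter than the motif: empty, not an error
  short <- scanSequence(s$lo, s$dist, "AC", scanConfig())
  expect_equal(nrow(short), 0L)
  expect_equal(attr(short, "n_tests"), 0L)
})

test_that("scan agrees with a naive quadratic scanner on random sequences", {
  withr::with_seed(21, {
    for (rep in 1:6) {
      w <- sample(2:6, 1)
      motif <- randomMotif(w, seed = rep * 31L)
      seqs <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
      bg <- estimateBackground(seqs)
      lo <- toLogOdds(motif, bg)
      d <- scoreDistribution(lo, bg)
      cfg <- scanConfig(pPrefilter = 1)  # keep every window
      hits <- scanSequence(lo, d, seqs, cfg, "g")
      oracle <- naiveScan(lo@scores, seqs)
      expect_equal(nrow(hits), nrow(oracle))
      key <- function(df) paste(df$start, df$strand)
      hits <- hits[order(key(hits)), ]
      oracle <- oracle[order(key(oracle)), ]
      expect_equal(hits$start, oracle$start)
      expect_equal(hits$score, oracle$score, tolerance = 1e-9)
      # p-values against full enumeration, bracketing the score
      # quantization (at most w * binWidth of threshold shift)
      tol <- w * d@binWidth
      for (i in seq_len(nrow(hits))) {
        expect_lte(hits$p_value[i],
                   enumeratePValue(lo@scores, bgMarginal(bg),
                                   oracle$score[i] - tol) + 1e-12)
        expect_gte(hits$p_value[i],
                   enumeratePValue(lo@scores, bgMarginal(bg),
                                   oracle$score[i] + tol) - 1e-12)
      }
    }
  })
})

test_that("scanPromoters is deterministic and validates inputs", {
  fx <- simulateFixture(fixtureConfig(nGenes = 4L, nModules = 2L,
                                      upstream = 150L, downstream = 50L,
                                      seed = 5L), tempfile())
  bg <- uniformBackground()
  loms <- lapply(fx$motifs[1:2], toLogOdds, bg = bg)
  dists <- lapply(loms, scoreDistribution, bg = bg)
  ann <- readAnnotation(fx$paths$annotation)
  genome <- Biostrings::readDNAStringSet(fx$paths$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  proms <- extractPromoterSeqs(
    genome, definePromoters(ann, 150L, 50L,
                            setNames(Biostrings::width(genome),
                                     names(genome))))
  r1 <- scanPromoters(loms, dists, proms, scanConfig(pPrefilter = 0.01))
  r2 <- scanPromoters(loms, dists, proms, scanConfig(pPrefilter = 0.01))
  expect_identical(r1, r2)
  # deterministic ordering contract
  ord <- order(r1$hits$motif_id, r1$hits$gene_symbol, r1$hits$start,
               method = "radix")
  expect_equal(ord, seq_len(nrow(r1$hits)))
  # test counts: windows on both strands for every promoter
  w1 <- motifWidth(loms[[1]])
  expect_equal(unname(r1$testsPerMotif[1]), 4L * 2L * (201L - w1 + 1L))
  expect_error(scanPromoters(list(), list(), proms), "empty motif list")
})

test_that("BH over all scored windows matches the step-up arithmetic", {
  mkHit <- function(p, motif = "m1") {
    data.frame(motif_id = motif, tf_name = motif, gene_symbol = "g",
               start = 0L, end = 4L, strand = "+", score = 1,
               p_value = p, q_value = NA_real_, matched = "ACGT")
  }
  # single hit, p = 0.001, m = 50 -> q = 0.05, retained at alpha 0.10
  out <- applyFdr(mkHit(0.001), c(m1 = 50L), alpha = 0.10)
  expect_equal(out$q_value, 0.05, tolerance = 1e-12)
  # p = 0.01, m = 1000 -> q capped at 1, removed
  expect_equal(nrow(applyFdr(mkHit(0.01), c(m1 = 1000L), alpha = 0.10)), 0L)
  # alpha = 1 retains everything
  hits <- rbind(mkHit(0.2), mkHit(0.9))
  expect_equal(nrow(applyFdr(hits, c(m1 = 10L), alpha = 1)), 2L)
  # monotone non-decreasing retention in alpha
  hits2 <- do.call(rbind, lapply(c(1e-5, 1e-4, 1e-3, 0.01), mkHit))
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.5, 1),
                  function(a) nrow(applyFdr(hits2, c(m1 = 100L), a)),
                  integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(applyFdr(mkHit(0.5, "unknown"), c(m1 = 10L)),
               "unknown test counts")
})

test_that("per-motif q-values match a reference BH on the full family", {
  withr::with_seed(4, {
    m <- 500L
    pAll <- sort(runif(m))
    keep <- pAll <= 0.02
    hits <- data.frame(motif_id = "m1", tf_name = "m1", gene_symbol = "g",
                       start = seq_len(sum(keep)), end = 2L, strand = "+",
                       score = 1, p_value = pAll[keep],
                       q_value = NA_real_, matched = "AC")
    out <- applyFdr(hits, c(m1 = m), alpha = 1)
    ref <- p.adjust(pAll, "BH")[keep]
    expect_equal(out$q_value[order(out$p_value)], ref, tolerance = 1e-12)
  })
})

test_that("no-signal scans rarely yield retained hits at 10% FDR", {
  # on iid background with no planted sites, the fraction of motifs with
  # any retained hit should not exceed alpha by much
  withr::with_seed(77, {
    seqs <- vapply(1:200, function(i)
      paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""),
      character(1))
    bg <- estimateBackground(seqs[1:20])
    motifs <- simulateMotifs(10L, widthRange = c(6L, 8L), infoBits = 1.5,
                             seed = 99L)
    flagged <- 0L
    for (mo in motifs) {
      lo <- toLogOdds(mo, bg)
      d <- scoreDistribution(lo, bg)
      tabs <- list(); nt <- 0L
      for (g in seq_along(seqs)) {
        h <- scanSequence(lo, d, seqs[g], scanConfig(), as.character(g))
        nt <- nt + attr(h, "n_tests")
        if (nrow(h)) tabs[[length(tabs) + 1L]] <- h
      }
      hits <- if (length(tabs)) do.call(rbind, tabs) else NULL
      if (!is.null(hits) && nrow(applyFdr(hits, setNames(nt, motifId(mo)),
                                          alpha = 0.10))) {
        flagged <- flagged + 1L
      }
    }
    expect_lte(flagged / length(motifs), 0.2)
  })
})
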