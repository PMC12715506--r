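test_that("MEME parsing handles the minimal format and preserves order", {
  meme <- tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "MOTIF m1 TFA",
    "letter-probability matrix: alength= 4 w= 3 nsites= 10 E= 0",
    "1 0 0 0", "0 1 0 0", "0 0 1 0", "",
    "MOTIF m2",
    "letter-probability matrix: alength= 4 w= 2 nsites= 5 E= 0",
    "0.25 0.25 0.25 0.25", "0.97 0.01 0.01 0.01"), meme)
  pwms <- readMeme(meme)
  expect_length(pwms, 2L)
  expect_equal(motifId(pwms[[1]]), "m1")
  expect_equal(tfName(pwms[[1]]), "TFA")
  expect_equal(motifWidth(pwms[[1]]), 3L)
  expect_equal(consensusString(pwms[[1]]), "ACG")
  # alternate name absent -> tf name falls back to the id
  expect_equal(tfName(pwms[[2]]), "m2")
  expect_equal(pwms[[2]]@nsites, 5)
})

test_that("MEME parse errors name the offending line", {
  bad <- tempfile()
  writeLines(c(
    "MEME version 4", "",
    "MOTIF m1",
    "letter-probability matrix: alength= 4 w= 2",
    "0.5 0.5 0", "0.25 0.25 0.25 0.25"), bad)
  expect_error(readMeme(bad), "line 5")
  writeLines(c(
    "MEME version 4", "",
    "MOTIF m1",
    "letter-probability matrix: alength= 4 w= 1",
    "0.70 0.10 0.10 0.05"), bad)
  expect_error(readMeme(bad), "0.99")
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(readMeme(empty), "empty")
  expect_error(writeMeme(list(), tempfile()), "empty")
})

test_that("read/write MEME round-trips motifs", {
  pwms <- simulateMotifs(5L, widthRange = c(1L, 9L), infoBits = 1.3,
                         seed = 7L)
  path <- tempfile(fileext = ".meme")
  writeMeme(pwms, path)
  back <- readMeme(path)
  expect_length(back, length(pwms))
  for (i in seq_along(pwms)) {
    expect_equal(motifId(back[[i]]), motifId(pwms[[i]]))
    expect_equal(motifWidth(back[[i]]), motifWidth(pwms[[i]]))
    expect_equal(back[[i]]@nsites, pwms[[i]]@nsites)
    expect_lt(max(abs(motifProbs(back[[i]]) - motifProbs(pwms[[i]]))), 1e-6)
  }
})

test_that("expressed-TF filtering is case-insensitive and deterministic", {
  expect_identical(
    filterExpressedTFs(c("Tox", "Gapdh", "Foxp1"),
                       c("TOX", "FOXP1", "KLF13")),
    c("Foxp1", "Tox"))
  expect_warning(out <- filterExpressedTFs(c("Aa", "Bb"), c("Cc")),
                 "no expressed gene")
  expect_length(out, 0L)
  # expressed superset of reference -> whole reference, sorted,
  # under the expressed spelling
  expect_identical(filterExpressedTFs(c("b1", "a1", "c1"), c("A1", "B1")),
                   c("a1", "b1"))
})

test_that("background estimation pools strands and smooths counts", {
  bg <- estimateBackground("ACGT", order = 0L)
  expect_equal(bgMarginal(bg), rep(0.25, 4), tolerance = 1e-12)
  # strand pooling: AAAA + its reverse complement gives A=4, T=4;
  # +0.1 per cell then /8.4
  bg2 <- estimateBackground("AAAA", order = 0L)
  expect_equal(bgMarginal(bg2), c(4.1, 0.1, 0.1, 4.1) / 8.4,
               tolerance = 1e-12)
  expect_error(estimateBackground("NNNN"), "no informative")
  # order-1 rows all sum to 1 even on a 2-bp input
  bg3 <- estimateBackground("AC", order = 1L)
  expect_equal(unname(rowSums(bgFreqs(bg3))), rep(1, 4), tolerance = 1e-9)
})

test_that("background marginal is strand-symmetric on arbitrary input", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      seqs <- vapply(1:3, function(i)
        paste(sample(c("A", "C", "G", "T"), 50, TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)), collapse = ""),
        character(1))
      m <- bgMarginal(estimateBackground(seqs, order = 0L))
      expect_equal(m[1], m[4], tolerance = 1e-12)
      expect_equal(m[2], m[3], tolerance = 1e-12)
    }
  })
})

test_that("log-odds conversion matches the smoothing arithmetic", {
  bg <- uniformBackground()
  # column equal to the background scores 0
  flat <- makeTFMotif("flat", "flat", matrix(0.25, 2, 4))
  expect_equal(max(abs(toLogOdds(flat, bg)@scores)), 0, tolerance = 1e-12)
  # (1 + 0.1*0.25) / 1.1 / 0.25 = 3.7272..
  m <- makeTFMotif("m", "m", matrix(c(1, 0, 0, 0), 1, 4))
  lo <- toLogOdds(m, bg, pseudocount = 0.1)
  expect_equal(unname(lo@scores[1, 1]), log2(1.025 / 1.1 / 0.25),
               tolerance = 1e-12)
  # pseudocount 0: perfect base scores log2(1/0.25) = 2, zeros are floored
  lo0 <- toLogOdds(m, bg, pseudocount = 0)
  expect_equal(unname(lo0@scores[1, 1]), 2)
  expect_true(all(lo0@scores[1, 2:4] <= -50))
  # monotonicity in the motif probability
  m2 <- makeTFMotif("m2", "m2", matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4))
  expect_lt(toLogOdds(m2, bg)@scores[1, 1], lo@scores[1, 1])
})

test_that("score distribution matches hand enumeration for width 1", {
  bg <- uniformBackground()
  m <- makeTFMotif("m", "m", matrix(c(1, 0, 0, 0), 1, 4))
  lo <- new("LogOddsMatrix", motifId = "m", tfName = "m",
            scores = matrix(c(2, 0, 0, 0), 1, 4), pseudocount = 0)
  d <- scoreDistribution(lo, bg)
  expect_equal(scorePValue(d, 2), 0.25, tolerance = 1e-9)
  expect_equal(scorePValue(d, 0), 1.0, tolerance = 1e-9)
  expect_equal(sum(d@pmf), 1, tolerance = 1e-9)
})

test_that("score distribution p-values equal full word enumeration", {
  withr::with_seed(5, {
    for (w in c(2L, 4L, 6L)) {
      motif <- randomMotif(w, seed = w * 13L)
      bg <- estimateBackground(
        paste(sample(c("A","C","G","T"), 200, TRUE,
                     prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""))
      lo <- toLogOdds(motif, bg)
      d <- scoreDistribution(lo, bg)
      # p at a handful of observed scores vs enumeration over all 4^w words
      # probe at word scores (the max) and at off-grid intermediate scores
      probes <- quantile(as.vector(lo@scores %*% c(1, 1, 1, 1)),
                         c(0, 0.5, 1)) * w / 4 + 0.0123
      probes <- c(probes, sum(apply(lo@scores, 1, max)))
      # the discretized p must lie between enumerations at s -/+ the
      # worst-case quantization shift of w * binWidth
      tol <- w * d@binWidth
      for (s in probes) {
        p <- scorePValue(d, s)
        expect_lte(p, enumeratePValue(lo@scores, bgMarginal(bg), s - tol) +
                     1e-12)
        expect_gte(p, enumeratePValue(lo@scores, bgMarginal(bg), s + tol) -
                     1e-12)
      }
    }
  })
})

test_that("score distribution respects the bin cap", {
  bg <- uniformBackground()
  motif <- randomMotif(8L, seed = 2L, info = 1.9)
  lo <- toLogOdds(motif, bg)
  expect_error(scoreDistribution(lo, bg, binWidth = 1e-9, maxBins = 1e5),
               "increase binWidth")
})
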