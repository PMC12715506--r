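# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, full enumeration, and
# reference implementations from other packages.

# exact p-value of `score` by enumerating all 4^w words weighted by bg0
enumeratePValue <- function(scores, bg0, score, slack = 1e-9) {
  w <- nrow(scores)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  tot <- numeric(nrow(words))
  prob <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    tot <- tot + scores[j, words[, j]]
    prob <- prob * bg0[words[, j]]
  }
  sum(prob[tot >= score - slack])
}

# quadratic scan of one strand with explicit loops
naiveScanStrand <- function(scores, seq) {
  base <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  chars <- strsplit(seq, "")[[1]]
  w <- nrow(scores)
  n <- length(chars) - w + 1L
  if (n <= 0) return(numeric(0))
  out <- numeric(n)
  for (s in seq_len(n)) {
    tot <- 0
    for (j in seq_len(w)) {
      b <- base[chars[s + j - 1L]]
      if (!is.na(b)) tot <- tot + scores[j, b]
    }
    out[s] <- tot
  }
  out
}

naiveRevComp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- rev(strsplit(seq, "")[[1]])
  paste(ifelse(chars %in% names(map), map[chars], "N"), collapse = "")
}

# naive scanner over both strands: data.frame(start0, strand, score)
naiveScan <- function(scores, seq) {
  w <- nrow(scores)
  L <- nchar(seq)
  plus <- naiveScanStrand(scores, seq)
  rc <- naiveScanStrand(scores, naiveRevComp(seq))
  rows <- list()
  for (s in seq_along(plus)) {
    rows[[length(rows) + 1L]] <- data.frame(start = s - 1L, strand = "+",
                                            score = plus[s])
  }
  for (s in seq_along(rc)) {
    rows[[length(rows) + 1L]] <- data.frame(start = L - (s - 1L) - w,
                                            strand = "-", score = rc[s])
  }
  do.call(rbind, rows)
}

# number of connected components of intervals under ">= 1 bp overlap",
# via union-find
unionFindComponents <- function(starts, ends) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && starts[i] < ends[j] && starts[j] < ends[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# reference BH step-up written as an explicit loop
bhNaive <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- numeric(n)
  mn <- Inf
  for (i in seq_len(n)) {
    idx <- o[i]
    rank <- n - i + 1L
    mn <- min(mn, p[idx] * n / rank)
    adj[i] <- min(mn, 1)
  }
  adj[ro]
}

# naive mean silhouette width, explicit double loops over a distance matrix
naiveSilhouette <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small deterministic count matrix with planted blocks: genes of block b
# have counts only in the TF columns of block b
blockMatrix <- function(nPerBlock = 8L, nBlocks = 3L, tfsPerBlock = 2L,
                        lambda = 4, seed = 42L) {
  withr::with_seed(seed, {
    n <- nPerBlock * nBlocks
    p <- nBlocks * tfsPerBlock
    m <- matrix(0L, n, p,
                dimnames = list(sprintf("g%02d", 1:n), sprintf("t%02d", 1:p)))
    for (b in seq_len(nBlocks)) {
      rows <- (b - 1L) * nPerBlock + seq_len(nPerBlock)
      cols <- (b - 1L) * tfsPerBlock + seq_len(tfsPerBlock)
      m[rows, cols] <- 1L + stats::rpois(length(rows) * length(cols), lambda)
    }
    list(matrix = new("TFBSMatrix", counts = m),
         truth = stats::setNames(rep(seq_len(nBlocks), each = nPerBlock),
                                 rownames(m)))
  })
}

uniformBackground <- function() {
  new("MarkovBackground", order = 0L,
      freqs = matrix(0.25, 1, 4, dimnames = list("", c("A","C","G","T"))),
      marginal = rep(0.25, 4), source = "uniform")
}

randomMotif <- function(w, seed, info = 1.2) {
  simulateMotifs(1L, widthRange = c(w, w), infoBits = info, seed = seed)[[1]]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
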