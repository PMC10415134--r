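# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written along different computational routes than the
# package functions they check.

tinyTreeText <- "((A:1,B:1):1,C:2);"

tinyTree <- function() ape::read.tree(text = tinyTreeText)

# independent whitening oracle for GLS: Cholesky-transform then ordinary lm
whitenedOlsFit <- function(y, x, V) {
  L <- chol(V)
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, cbind(1, x), transpose = TRUE)
  s <- summary(stats::lm(wy ~ wX - 1))
  list(slope = s$coefficients[2, 1], slope_se = s$coefficients[2, 2],
       p = s$coefficients[2, 4])
}

# independent permutation enumeration for the Spearman null (recursive
# permutation generation + plain cor(), unlike the package's rank-matrix
# route)
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

spearmanEnumOracle <- function(x, y) {
  rhoObs <- stats::cor(x, y, method = "spearman")
  rhos <- vapply(allPerms(length(y)),
                 function(p) stats::cor(x, y[p], method = "spearman"),
                 numeric(1))
  mean(abs(rhos) >= abs(rhoObs) - 1e-12)
}

# brute-force null tail probabilities of a motif score over all 4^w windows
motifEnumOracle <- function(motif, scores) {
  lo <- motifLogOdds(motif)
  bg <- motifBackground(motif)
  w <- ncol(lo)
  wins <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- rowSums(vapply(seq_len(w), function(j) lo[wins[, j], j],
                       numeric(nrow(wins))))
  pr <- apply(wins, 1, function(r) prod(bg[r]))
  vapply(scores, function(s) sum(pr[sc >= s - 1e-9]), numeric(1))
}

# naive per-window scanner (no DP, no vectorization)
naiveScan <- function(seq, motif, pThreshold) {
  lo <- motifLogOdds(motif)
  w <- ncol(lo)
  chars <- strsplit(seq, "")[[1L]]
  rcmap <- c(A = "T", C = "G", G = "C", T = "A")
  dist <- exactScoreDistribution(motif)
  rows <- list()
  for (i in seq_len(length(chars) - w + 1L)) {
    win <- chars[i:(i + w - 1L)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    for (strand in c("+", "-")) {
      ws <- if (strand == "+") win else rev(rcmap[win])
      sc <- sum(vapply(seq_len(w),
                       function(j) lo[match(ws[j], c("A", "C", "G", "T")), j],
                       numeric(1)))
      p <- scoreTailProb(dist, sc)
      if (p < pThreshold)
        rows[[length(rows) + 1L]] <- data.frame(offset = i - 1L,
                                                strand = strand,
                                                score = sc, p = p)
    }
  }
  if (!length(rows))
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$offset, out$strand), , drop = FALSE]
}

randomSignedSet <- function(universe, n) {
  SignedGeneSet(sample(universe, n), sample(c(1L, -1L), n, replace = TRUE))
}
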