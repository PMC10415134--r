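# PWM scanning: exact null distribution, hit reporting, per-set statistics
# and the co-evolution trend test.

test_that("width-1 null distribution reproduces single-base probabilities", {
  m <- MotifModel("w1", matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 0)
  d <- exactScoreDistribution(m)
  expect_equal(scoreTailProb(d, 2), 0.25)   # only A scores log2(4) = 2
  expect_equal(scoreTailProb(d, -100), 0.25)  # C,G,T score -Inf
  mf <- MotifModel("w1f", matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 0.5)
  expect_equal(scoreTailProb(exactScoreDistribution(mf), -100), 1)
  expect_equal(scoreTailProb(d, 3), 0)
  # tail is non-increasing in the score
  expect_true(all(diff(d$tail) <= 1e-12))
})

test_that("null tail probabilities equal brute-force enumeration for
           small widths", {
  set.seed(61)
  for (w in c(2, 3, 4, 6)) {
    m <- simulateMotif(paste0("m", w), w, seed = w)
    d <- exactScoreDistribution(m)
    qs <- sort(unique(round(d$scores, 9)))
    expect_equal(scoreTailProb(d, qs), motifEnumOracle(m, qs),
                 tolerance = 1e-9)
  }
  # non-uniform background
  m <- MotifModel("gc", matrix(c(1, 5, 5, 1, 8, 1, 1, 2), 4, 2),
                  background = c(0.2, 0.3, 0.3, 0.2))
  d <- exactScoreDistribution(m)
  qs <- sort(unique(round(d$scores, 9)))
  expect_equal(scoreTailProb(d, qs), motifEnumOracle(m, qs),
               tolerance = 1e-9)
})

test_that("finer discretization leaves reported p-values unchanged", {
  m <- simulateMotif("m6", 6, seed = 2)
  d1 <- exactScoreDistribution(m, granularity = 100)
  d2 <- exactScoreDistribution(m, granularity = 200)
  qs <- seq(min(d1$scores), max(d1$scores), length.out = 50)
  expect_lt(max(abs(scoreTailProb(d1, qs) - scoreTailProb(d2, qs))), 1e-6)
  # wide motifs fall back to the integer grid and stay close to the
  # exact-value path
  mw <- simulateMotif("m12", 12, seed = 3)
  dg <- exactScoreDistribution(mw, granularity = 4000)
  de <- exactScoreDistribution(mw, exactMaxWidth = 12)
  qs <- stats::quantile(de$scores, c(0.5, 0.9, 0.99))
  expect_equal(scoreTailProb(dg, qs), scoreTailProb(de, qs),
               tolerance = 1e-3)
  expect_error(exactScoreDistribution(m, granularity = 10), ">= 100")
})

test_that("threshold semantics of the scanner match the null
           distribution", {
  m <- MotifModel("w1", matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 0)
  # best achievable p is 0.25, so nothing passes the 1e-4 default
  expect_equal(nrow(scanPromoter("AAAA", m, pThreshold = 1e-4)), 0)
  h <- scanPromoter("AAAA", m, pThreshold = 0.5)
  h <- h[h$strand == "+", ]
  expect_equal(h$offset, 0:3)
  expect_equal(h$p, rep(0.25, 4))
  # sequence shorter than the motif: empty, not an error
  m4 <- simulateMotif("m4", 4, seed = 1)
  expect_equal(nrow(scanPromoter("AC", m4)), 0)
  # windows containing N are skipped
  expect_equal(nrow(scanPromoter("NN", simulateMotif("m2", 2, seed = 1),
                                 pThreshold = 1)), 0)
})

test_that("scanner agrees with a naive per-window scanner on random 1 kb
           sequences", {
  set.seed(62)
  m <- simulateMotif("m7", 7, seed = 7)
  for (r in 1:3) {
    seq <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    mine <- scanPromoter(seq, m, pThreshold = 1e-3)
    ref <- naiveScan(seq, m, pThreshold = 1e-3)
    expect_equal(nrow(mine), nrow(ref))
    expect_equal(mine$offset, ref$offset)
    expect_equal(mine$strand, ref$strand)
    expect_equal(mine$score, ref$score, tolerance = 1e-12)
    expect_equal(mine$p, ref$p, tolerance = 1e-12)
  }
})

test_that("hits are invariant under reverse complementation", {
  set.seed(63)
  m <- simulateMotif("m8", 8, seed = 8)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  # plant one consensus to guarantee a hit
  substr(seq, 101, 108) <- motifConsensus(m)
  h <- scanPromoter(seq, m, pThreshold = 1e-3)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h2 <- scanPromoter(rc, m, pThreshold = 1e-3)
  expect_equal(nrow(h), nrow(h2))
  expect_setequal(600 - 8 - h$offset, h2$offset)
  expect_equal(sort(h$score), sort(h2$score))
})

test_that("set scanning equals per-sequence scanning", {
  set.seed(64)
  m <- simulateMotif("m6b", 6, seed = 9)
  seqs <- setNames(
    replicate(8, paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                       collapse = "")),
    paste0("g", 1:8, "|sp1"))
  d <- exactScoreDistribution(m)
  all <- scanPromoterSet(seqs, m, pThreshold = 5e-3, dist = d)
  for (nm in names(seqs)) {
    one <- scanPromoter(seqs[[nm]], m, pThreshold = 5e-3, dist = d)
    sub <- all[all$seqname == nm, ]
    expect_equal(sub$offset, one$offset)
    expect_equal(sub$score, one$score)
  }
})

test_that("per-set statistics count presence and mean hits", {
  hits <- data.frame(gene = c("g1", "g1"))
  st <- motifGeneStats(hits, c("g1", "g2"))
  expect_equal(st$presence_ratio, 0.5)
  expect_equal(st$mean_count, 1.0)
  none <- motifGeneStats(hits[0, , drop = FALSE], c("g1", "g2"))
  expect_equal(none$presence_ratio, 0)
  expect_equal(none$mean_count, 0)
  allHit <- motifGeneStats(data.frame(gene = c("g1", "g2")), c("g1", "g2"))
  expect_equal(allHit$presence_ratio, 1)
  expect_error(motifGeneStats(hits, character(0)), "empty")
  # genes without a promoter leave the denominator
  suppressMessages(
    st2 <- motifGeneStats(hits, c("g1", "g2", "g3"),
                          available = c("g1", "g2")))
  expect_equal(st2$n_genes, 2)
})

test_that("trend test requires both metrics significant in the same
           direction", {
  mls <- setNames(exp(seq(log(3), log(80), length.out = 12)),
                  sprintf("sp%02d", 1:12))
  grad <- seq(0.1, 0.9, length.out = 12)
  base <- data.frame(species = names(mls),
                     presence_bg = 0.3, count_bg = 0.5)
  # motif A: both metrics trend up with MLS
  stA <- cbind(motif = "A", base, presence_set = grad,
               count_set = grad * 2)
  # motif B: only the count metric trends
  stB <- cbind(motif = "B", base, presence_set = 0.3,
               count_set = grad * 2)
  out <- coevolutionTrend(rbind(stA, stB), mls, fdr = 0.05)
  expect_true(all(out$called[out$motif == "A"]))
  expect_false(any(out$called[out$motif == "B"]))
  # identical stats in set and background: constant ORs, untestable
  stC <- cbind(motif = "C", base, presence_set = 0.3, count_set = 0.5)
  outC <- coevolutionTrend(stC, mls, fdr = 0.05)
  expect_false(any(outC$called))
})
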