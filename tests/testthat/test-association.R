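# Spearman, PGLS, ensemble aggregation, BKY FDR, and set calling.

test_that("the species-coverage filter is inclusive at the threshold", {
  m <- matrix(rnorm(36), 3, 12,
              dimnames = list(c("g9", "g10", "gfull"), sprintf("s%02d", 1:12)))
  m[1, 1:3] <- NA   # 9 species observed -> removed
  m[2, 1:2] <- NA   # 10 species observed -> retained
  suppressMessages(kept <- filterMinSpecies(m, 10))
  expect_identical(rownames(kept), c("g10", "gfull"))
  expect_identical(filterMinSpecies(m, 3), m)
  expect_error(filterMinSpecies(m, 13), "no gene")
})

test_that("Spearman exact p matches permutation enumeration", {
  # perfectly monotone n=5: only 2 of the 120 permutations reach |rho| = 1
  f <- spearmanAssociation(1:5, c(0.1, 0.5, 0.9, 1.8, 2))
  expect_equal(f$rho, 1)
  expect_equal(f$p, 2 / 120)
  # antisymmetry
  f2 <- spearmanAssociation(1:5, c(2, 1.8, 0.9, 0.5, 0.1))
  expect_equal(f2$rho, -1)
  expect_equal(f2$p, f$p)
  # randomized battery incl. ties, against the independent enumeration oracle
  set.seed(41)
  for (n in 4:7) {
    for (r in 1:3) {
      x <- rnorm(n)
      y <- sample(c(rnorm(n - 1), x[1]))  # occasional tie material
      fit <- spearmanAssociation(x, y)
      expect_equal(fit$p, spearmanEnumOracle(x, y), tolerance = 1e-12)
    }
  }
})

test_that("Spearman large-n p agrees with the t approximation and errors on
           constant input", {
  set.seed(7)
  x <- rnorm(15); y <- rnorm(15)
  fit <- spearmanAssociation(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(fit$rho, unname(ref$estimate))
  expect_error(spearmanAssociation(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearmanAssociation(rnorm(2), rnorm(2)), "at least 3")
})

test_that("PGLS equals OLS on star trees and the whitening oracle on
           random trees", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(3:10, 1)
    # star tree: identity-proportional covariance reduces GLS to OLS
    x <- rnorm(n); y <- rnorm(n)
    fit <- pglsFit(y, x, diag(runif(1, 0.5, 2), n))
    ols <- summary(stats::lm(y ~ x))$coefficients
    expect_equal(fit$slope, ols[2, 1], tolerance = 1e-8)
    expect_equal(fit$slope_se, ols[2, 2], tolerance = 1e-8)
    expect_equal(fit$p, ols[2, 4], tolerance = 1e-8)
    # random phylogeny: match Cholesky-whitened OLS
    tr <- simulateTree(n, seed = r)
    V <- phyloCovariance(tr)
    yv <- rnorm(n); xv <- rnorm(n)
    fit2 <- pglsFit(yv, xv, V)
    orc <- whitenedOlsFit(yv, xv, V)
    expect_equal(fit2$slope, orc$slope, tolerance = 1e-8)
    expect_equal(fit2$slope_se, orc$slope_se, tolerance = 1e-8)
    expect_equal(fit2$p, orc$p, tolerance = 1e-8)
  }
})

test_that("PGLS agrees with nlme gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  tr <- simulateTree(12, seed = 5)
  V <- phyloCovariance(tr)
  set.seed(6)
  x <- rnorm(12); y <- 0.4 * x + as.numeric(t(chol(V)) %*% rnorm(12))
  fit <- pglsFit(y, x, V)
  df <- data.frame(y = y, x = x, sp = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corBrownian(1, tr, form = ~sp))
  refsum <- summary(ref)$tTable
  expect_equal(fit$slope, refsum["x", "Value"], tolerance = 1e-6)
  expect_equal(fit$slope_se, refsum["x", "Std.Error"], tolerance = 1e-6)
})

test_that("PGLS fits a perfect line with zero generalized residual", {
  tr <- simulateTree(6, seed = 9)
  V <- phyloCovariance(tr)
  x <- rnorm(6)
  fit <- pglsFit(2 + 3 * x, x, V)
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_error(pglsFit(rnorm(6), rep(1, 6), V), "singular")
})

test_that("ensemble aggregation takes the max p and flags sign conflicts", {
  tr <- simulateTree(8, seed = 3)
  V <- phyloCovariance(tr)
  set.seed(4)
  x <- setNames(rnorm(8), tr$tip.label)
  y <- setNames(0.3 * x + rnorm(8, sd = 0.5), tr$tip.label)
  single <- pglsFit(y, x[names(y)], V[names(y), names(y)])
  # identical trees: max p equals the single-tree p
  ens <- pglsEnsemble(y, x, list(tr, tr, tr))
  expect_equal(ens$p_max, single$p)
  expect_equal(ens$slope_ref, single$slope)
  # two different covariances: max of the two oracle p-values
  tr2 <- simulateTree(8, seed = 99); tr2$tip.label <- tr$tip.label
  V2 <- phyloCovariance(tr2)
  o1 <- whitenedOlsFit(y, x[names(y)], V[names(y), names(y)])
  o2 <- whitenedOlsFit(y, x[names(y)], V2[names(y), names(y)])
  ens2 <- pglsEnsemble(y, x, list(tr, tr2))
  expect_equal(ens2$p_max, max(o1$p, o2$p), tolerance = 1e-10)
  # p_max is monotone non-decreasing as trees are added
  ens3 <- pglsEnsemble(y, x, list(tr, tr2, simulateTree(8, seed = 123)))
  expect_gte(ens3$p_max, ens2$p_max)
  expect_error(pglsEnsemble(y, x, list()), "empty")
})

test_that("BKY two-stage FDR reproduces the hand-worked example", {
  # q' = 0.1/1.1; stage 1 rejects 2 of 4; stage 2 level 0.1818 rejects the
  # same two
  r <- bkyFdr(c(0.01, 0.02, 0.5, 0.6), q = 0.1)
  expect_identical(r$rejected, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(r$rejected, r$q_values <= 0.1)
  expect_identical(bkyFdr(rep(1, 10), 0.1)$rejected, rep(FALSE, 10))
  expect_error(bkyFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # q-values are monotone in p
  set.seed(8)
  p <- runif(50)
  qv <- bkyFdr(p)$q_values
  expect_true(all(diff(qv[order(p)]) >= -1e-12))
})

test_that("BKY rejects at least as much as BH on strong mixed signal", {
  set.seed(12)
  for (r in 1:20) {
    p <- c(rbeta(300, 0.05, 1), runif(700))
    bky <- bkyFdr(p, 0.1)$rejected
    bh <- stats::p.adjust(p, "BH") <= 0.1
    expect_true(all(bky[bh]))
  }
})

test_that("signed-set calling applies the strict FDR inequality", {
  tab <- AssociationTable(data.frame(
    gene = c("g1", "g2", "g3"), method = "spearman",
    statistic = c(0.9, -0.8, 0.7), p_value = c(0.001, 0.002, 0.5),
    q_value = c(0.05, 0.10, 0.60), n_species = 20,
    sign = c(1L, -1L, 1L)), fdrLevel = 0.10)
  s <- callSignedSet(tab)
  # boundary q exactly at the level is excluded (strict "<")
  expect_identical(geneIds(s), "g1")
  expect_length(callSignedSet(AssociationTable(
    data.frame(gene = character(0), method = character(0),
               statistic = numeric(0), p_value = numeric(0),
               q_value = numeric(0), n_species = integer(0),
               sign = integer(0)))), 0)
})

test_that("method-call merging unions sets and drops sign conflicts", {
  a <- SignedGeneSet(c("g1", "g2", "g3"), c(1L, -1L, 1L))
  b <- SignedGeneSet(c("g4", "g5"), c(1L, 1L))
  expect_length(mergeMethodCalls(a, b), 5)
  # same gene, same sign: appears once
  b2 <- SignedGeneSet(c("g1", "g4"), c(1L, -1L))
  m <- mergeMethodCalls(a, b2)
  expect_length(m, 4)
  expect_equal(unname(geneSigns(m)["g1"]), 1L)
  # same gene, opposite signs: excluded with a warning
  b3 <- SignedGeneSet("g1", -1L)
  expect_warning(m3 <- mergeMethodCalls(a, b3), "opposite signs")
  expect_false("g1" %in% geneIds(m3))
})

test_that("the association driver recovers a strong planted signal", {
  tr <- simulateTree(20, seed = 21)
  trait <- simulateTraitBm(tr, 1, log2(25), seed = 22)
  cfg <- simulationConfig(n_species = 20, n_genes = 120, n_planted = 20,
                          missing_rate = 0.1, seed = 23)
  sim <- simulateExpression(cfg, tr, trait)
  mls <- setNames(sim$species$mls_years, sim$species$species_id)
  trees <- list(tr, simulateTree(20, seed = 31))
  suppressMessages(tab <- associateMLS(sim$expr, mls, trees = trees))
  recs <- associationRecords(tab)
  expect_setequal(unique(recs$method), c("spearman", "pgls"))
  expect_true(all(recs$n_species >= 10))
  sp <- callSignedSet(tab, method = "spearman")
  truth <- geneSigns(sim$planted)
  hits <- intersect(geneIds(sp), names(truth))
  expect_gte(length(hits), 0.7 * length(truth))
  # recovered signs match the planted slope signs
  expect_identical(geneSigns(sp)[hits], truth[hits])
})
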