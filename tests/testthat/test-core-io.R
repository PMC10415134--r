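# Readers/writers, tree pruning and the Brownian covariance.

test_that("expression TSV round-trips with missing entries preserved", {
  m <- matrix(c(1.5, NA, -2.25, 0.125, 3, 7), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("spA", "spB")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTsv(m, f)
  back <- readExpressionTsv(f)
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(back, m)
  expect_true(is.na(back["g2", "spA"]))
})

test_that("expression reader rejects duplicates and non-numeric cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(readExpressionTsv(f), "duplicate gene")
  writeLines(c("gene\ts1\ts2", "g1\t1\tx"), f)
  expect_error(readExpressionTsv(f), "non-numeric")
  writeLines(c("gene\ts1\ts2", "g1\t1\tNA", "g2\t\t2"), f)
  m <- readExpressionTsv(f)
  expect_equal(sum(is.na(m)), 2L)
})

test_that("newick ensembles parse, validate leaf sets, and round-trip", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(rep(tinyTreeText, 5), f)
  ens <- readNewickEnsemble(f)
  expect_length(ens, 5)
  expect_setequal(ens[[1]]$tip.label, c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(ens[[1]])[1:3]
  expect_equal(depths, c(2, 2, 2))
  writeLines(c(tinyTreeText, "((A:1,X:1):1,C:2);"), f)
  expect_error(readNewickEnsemble(f), "different leaf set")
  writeLines(c(tinyTreeText, "((A:1,B:1:2;"), f)
  expect_error(readNewickEnsemble(f), "unparsable")
  writeNewickEnsemble(ens, f)
  expect_length(readNewickEnsemble(f), 5)
})

test_that("phylo covariance matches hand-computed shared path lengths", {
  V <- phyloCovariance(tinyTree(), c("A", "B", "C"))
  expect_equal(unname(V), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  # star tree: no shared branches
  star <- ape::read.tree(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  expect_equal(unname(phyloCovariance(star)), diag(1.5, 4))
  expect_error(phyloCovariance(tinyTree(), c("A", "Z")), "not in tree")
})

test_that("phylo covariance is symmetric PSD on random trees", {
  for (s in 1:5) {
    tr <- simulateTree(10, seed = s)
    V <- phyloCovariance(tr)
    expect_equal(V, t(V))
    expect_no_error(chol(V + diag(1e-10, nrow(V))))
    # ultrametric: constant diagonal
    expect_equal(max(diag(V)) - min(diag(V)), 0, tolerance = 1e-8)
  }
})

test_that("pruning preserves root-to-tip and shared path lengths", {
  expect_equal(ape::write.tree(pruneTree(tinyTree(), c("A", "B", "C"))),
               ape::write.tree(tinyTree()))
  tr <- simulateTree(8, seed = 2)
  keep <- c("sp001", "sp004", "sp007")
  pruned <- pruneTree(tr, keep)
  Vfull <- phyloCovariance(tr, keep)
  Vpruned <- phyloCovariance(pruned, keep)
  expect_equal(Vpruned, Vfull, tolerance = 1e-12)
  expect_error(pruneTree(tr, c("sp001", "nope", "sp002")), "not in tree")
  expect_error(pruneTree(tr, c("sp001", "sp002")), "at least 3")
})

test_that("JASPAR PFM parsing converts counts to probabilities and bits", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M0001 TF1", "A [ 10 ]", "C [ 0 ]", "G [ 0 ]", "T [ 0 ]",
               ">M0002 TF2",
               "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]", "T [ 1 2 ]"), f)
  ms <- readJasparPfm(f, pseudocount = 0)
  expect_named(ms, c("M0001", "M0002"))
  expect_equal(ms$M0001@frequencies[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unname(motifLogOdds(ms$M0001)["A", 1]), 2)  # log2(1 / 0.25) bits
  ms1 <- readJasparPfm(f, pseudocount = 1)
  expect_equal(unname(ms1$M0001@frequencies["A", 1]), 11 / 14)
  writeLines(c(">bad x", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]",
               "T [ 1 2 ]"), f)
  expect_error(readJasparPfm(f), "unequal width")
  writeLines(c(">bad x", "A [ -1 ]", "C [ 1 ]", "G [ 1 ]", "T [ 1 ]"), f)
  expect_error(readJasparPfm(f), "negative")
})

test_that("promoter FASTA reading uppercases and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1|sp1", "acgtn", ">g2|sp1", "TTTT"), f)
  seqs <- readFastaPromoters(f)
  expect_length(seqs, 2)
  expect_equal(as.character(seqs[["g1|sp1"]]), "ACGTN")
  writeLines(c(">g1|sp1", "ACGT", ">g1|sp1", "TTTT"), f)
  expect_error(readFastaPromoters(f), "duplicate")
  nm <- splitPromoterNames(c("g1|sp1", "g2|sp9"))
  expect_equal(nm$gene, c("g1", "g2"))
  expect_equal(nm$species, c("sp1", "sp9"))
})

test_that("signed gene set IO applies the conflicting-sign drop rule", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsign", "g1\t+", "g2\t-1"), f)
  s <- readSignedGeneSet(f)
  expect_length(s, 2)
  expect_equal(unname(geneSigns(s)[c("g1", "g2")]), c(1L, -1L))
  # a gene listed with both signs is contradictory and dropped
  writeLines(c("gene_id\tsign", "g1\t+", "g1\t-"), f)
  expect_warning(s2 <- readSignedGeneSet(f), "both signs")
  expect_length(s2, 0)
  writeLines(c("gene_id\tsign", "g1\tup"), f)
  expect_error(readSignedGeneSet(f), "unknown sign")
  # round trip
  writeSignedGeneSet(s, f)
  expect_equal(geneSigns(readSignedGeneSet(f))[geneIds(s)], geneSigns(s))
})

test_that("GMT libraries round-trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  lib <- list(t1 = c("a", "b", "c"), t2 = c("b", "d"))
  writeGmt(lib, f)
  expect_equal(readGmt(f), lib)
  writeLines("t1\tdesc", f)
  expect_error(readGmt(f), "fewer than 3")
})

test_that("SignedGeneSet and MotifModel validity is enforced", {
  expect_error(SignedGeneSet(c("a", "a"), c(1L, 1L)), "duplicate")
  expect_error(SignedGeneSet("a", 2L), "signs")
  expect_error(MotifModel("m", matrix(-1, 4, 2)), "negative")
  m <- MotifModel("m", matrix(c(8, 4, 2, 2), 4, 1), pseudocount = 0)
  expect_equal(sum(m@frequencies[, 1]), 1)
  expect_equal(motifWidth(m), 1L)
  expect_equal(motifConsensus(m), "A")
})

test_that("LifespanExperiment couples expression with species traits", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), sprintf("s%02d", 1:10)))
  sp <- data.frame(species_id = colnames(m),
                   mls_years = seq(2, 90, length.out = 10))
  le <- LifespanExperiment(m, sp)
  expect_s4_class(le, "LifespanExperiment")
  expect_equal(exprValues(le), m)
  expect_equal(unname(mlsYears(le)), sp$mls_years)
  expect_equal(speciesInfo(le)$species_id, sp$species_id)
  # the association driver accepts the container directly
  suppressMessages(tab <- associateMLS(le, methods = "spearman",
                                       minSpecies = 5))
  expect_equal(nrow(associationRecords(tab)), 4)
  # invalid traits are rejected
  sp$mls_years[1] <- -3
  expect_error(LifespanExperiment(m, sp), "positive")
  expect_error(LifespanExperiment(m, sp[-1, ]), "absent")
})
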