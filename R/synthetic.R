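# Synthetic-data generators with the statistical structure the analysis
# assumes: a phylogeny, a Brownian trait (log2 MLS), expression with planted
# linear trait dependence plus phylogenetic and independent noise, signed
# partner gene sets with a target concordance odds ratio, and promoter
# sequences with planted motif trends. All generators are deterministic
# given their seed.

#' Simulation configuration
#'
#' Validated parameter list for [simulateExpression()] and the pipeline's
#' simulate stage. Defaults describe a study of 29 species and 2000 genes
#' of which 200 carry a planted log2-expression-per-log2-MLS slope of 1,
#' with noise levels chosen so the planted genes have an expected absolute
#' Spearman correlation of about 0.8 with the trait.
#'
#' @param n_species number of species (>= 10).
#' @param n_genes total genes.
#' @param n_planted genes with a true trait effect (half positive slope,
#'   half negative).
#' @param effect_slope expression change (log2 units) per doubling of MLS.
#' @param phylo_noise_sd SD of the Brownian (tree-correlated) noise
#'   component per gene.
#' @param iid_noise_sd SD of the independent Gaussian noise per cell.
#' @param missing_rate per-cell missingness probability in \[0, 1);
#'   per-gene masks are redrawn until >= `min_obs` species remain observed.
#' @param min_obs minimum observed species per gene (default 10, matching
#'   the analysis filter).
#' @param concordance_target target concordance odds ratio for
#'   [simulateSignedPartnerSet()].
#' @param partner_size size of the simulated partner (aging) set.
#' @param trait_sigma Brownian rate SD of the log2-MLS trait per unit tree
#'   height.
#' @param trait_root root value of log2 MLS (default log2(25) years).
#' @param seed master seed.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_species = 29L, n_genes = 2000L,
                             n_planted = 200L, effect_slope = 1,
                             phylo_noise_sd = 0.12, iid_noise_sd = 0.46,
                             missing_rate = 0.1, min_obs = 10L,
                             concordance_target = 3, partner_size = 300L,
                             trait_sigma = 1, trait_root = log2(25),
                             seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_genes = as.integer(n_genes),
              n_planted = as.integer(n_planted),
              effect_slope = effect_slope,
              phylo_noise_sd = phylo_noise_sd,
              iid_noise_sd = iid_noise_sd, missing_rate = missing_rate,
              min_obs = as.integer(min_obs),
              concordance_target = concordance_target,
              partner_size = as.integer(partner_size),
              trait_sigma = trait_sigma, trait_root = trait_root,
              seed = as.integer(seed))
  if (cfg$n_species < 10L) stop("n_species must be >= 10")
  if (cfg$n_planted > cfg$n_genes) stop("n_planted must be <= n_genes")
  if (cfg$phylo_noise_sd < 0 || cfg$iid_noise_sd < 0 ||
      cfg$trait_sigma < 0) stop("noise SDs must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate an ultrametric phylogeny
#'
#' Pure-birth (Yule) tree rescaled to unit height, with tips labeled
#' `sp001..spNNN`. Deterministic given the seed.
#'
#' @param nSpecies number of tips (>= 3).
#' @param seed RNG seed.
#' @return a rooted ultrametric `phylo`.
#' @export
simulateTree <- function(nSpecies, seed = 1L) {
  if (nSpecies < 3L) stop("need at least 3 species")
  set.seed(seed)
  tr <- ape::rphylo(nSpecies, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(nSpecies))
  tr
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Tip values of a Brownian motion with rate variance `sigma^2`, so the tip
#' covariance equals `sigma^2` times the shared-branch-length matrix of
#' [phyloCovariance()]. Used for log2 MLS: the exported lifespan in years is
#' `2^trait`.
#'
#' @param tree a `phylo`.
#' @param sigma Brownian rate SD (>= 0).
#' @param rootValue trait value at the root.
#' @param seed RNG seed.
#' @return named numeric vector over the tips.
#' @export
simulateTraitBm <- function(tree, sigma, rootValue = 0, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  tips <- tree$tip.label
  if (sigma == 0)
    return(setNames(rep(rootValue, length(tips)), tips))
  V <- phyloCovariance(tree)[tips, tips]
  L <- chol(V + diag(1e-12, nrow(V)))
  set.seed(seed)
  z <- rnorm(length(tips))
  setNames(rootValue + sigma * as.numeric(crossprod(L, z)), tips)
}

#' Simulate a cross-species expression matrix with planted trait effects
#'
#' The first `n_planted` genes follow `slope * trait` (half the planted
#' genes with negated slope) plus a gene-specific Brownian noise component
#' on the tree (SD `phylo_noise_sd`) plus i.i.d. Gaussian noise
#' (`iid_noise_sd`); the remaining genes are noise only. Missingness is
#' drawn independently per cell at `missing_rate`, redrawing any gene mask
#' that would leave fewer than `min_obs` observed species.
#'
#' @param cfg a [simulationConfig()].
#' @param tree the species tree (tips must cover `trait`).
#' @param trait named vector of the log2-scale trait at the tips.
#' @return list with `expr` (genes x species matrix, NA = missing),
#'   `planted` (a [SignedGeneSet-class] recording each planted gene's slope
#'   sign), and `species` (data.frame with `species_id`, `mls_years`).
#' @export
simulateExpression <- function(cfg, tree, trait) {
  tips <- tree$tip.label
  if (!all(tips %in% names(trait))) stop("trait missing for some tips")
  trait <- trait[tips]
  nS <- length(tips); nG <- cfg$n_genes
  if (cfg$missing_rate > 0 && nS * (1 - cfg$missing_rate) < cfg$min_obs / 2)
    stop("missing_rate leaves too few species per gene")
  genes <- sprintf("g%04d", seq_len(nG))
  set.seed(cfg$seed)
  slopes <- numeric(nG)
  if (cfg$n_planted > 0) {
    sgn <- rep(c(1, -1), length.out = cfg$n_planted)
    slopes[seq_len(cfg$n_planted)] <- cfg$effect_slope * sgn
  }
  expr <- outer(slopes, trait)
  if (cfg$phylo_noise_sd > 0) {
    V <- phyloCovariance(tree)[tips, tips]
    L <- chol(V + diag(1e-12, nS))
    Z <- matrix(rnorm(nS * nG), nS, nG)
    expr <- expr + cfg$phylo_noise_sd * t(crossprod(L, Z))
  }
  if (cfg$iid_noise_sd > 0)
    expr <- expr + matrix(rnorm(nG * nS, sd = cfg$iid_noise_sd), nG, nS)
  dimnames(expr) <- list(genes, tips)
  if (cfg$missing_rate > 0) {
    for (i in seq_len(nG)) {
      for (try in seq_len(1000L)) {
        mask <- runif(nS) < cfg$missing_rate
        if (nS - sum(mask) >= cfg$min_obs) break
        if (try == 1000L)
          stop("could not draw a mask keeping >= ", cfg$min_obs,
               " species for gene ", genes[i])
      }
      expr[i, mask] <- NA_real_
    }
  }
  planted <- SignedGeneSet(genes[seq_len(cfg$n_planted)],
                           as.integer(sign(slopes[seq_len(cfg$n_planted)])),
                           provenance = c(origin = "planted"))
  list(expr = expr, planted = planted,
       species = data.frame(species_id = tips, mls_years = 2^trait))
}

#' Simulate a signed partner gene set with a target concordance odds ratio
#'
#' Draws `setSize` genes from the universe, oversampling sign-matched
#' anchor members at odds `targetOr`: an anchor gene's (gene, sign) pair
#' matching the anchor sign has sampling weight `targetOr`, every other
#' (gene, sign) pair has weight 1. With `targetOr = 1` this reduces to
#' uniform sampling with random signs; as `targetOr` grows, the partner set
#' concentrates on sign-matched anchor members. The expected concordance
#' odds ratio against the anchor (observed-vs-expected construction of
#' [concordanceOddsRatio()]) approaches `targetOr` when the set is small
#' relative to the universe.
#'
#' @param universe character vector of genes.
#' @param anchor the anchor [SignedGeneSet-class] (e.g. the MLS set).
#' @param targetOr target odds ratio (> 0; `Inf` gives a sign-matched
#'   subset of the anchor).
#' @param setSize partner set size.
#' @param seed RNG seed.
#' @return a [SignedGeneSet-class].
#' @export
simulateSignedPartnerSet <- function(universe, anchor, targetOr, setSize,
                                     seed = 1L) {
  universe <- unique(as.character(universe))
  if (setSize > length(universe)) stop("setSize exceeds universe size")
  if (targetOr <= 0) stop("targetOr must be positive")
  anchorSigns <- geneSigns(anchor)
  anchorSigns <- anchorSigns[names(anchorSigns) %in% universe]
  set.seed(seed)
  if (is.infinite(targetOr)) {
    if (setSize > length(anchorSigns))
      stop("targetOr = Inf needs setSize <= anchor size")
    picked <- sample(names(anchorSigns), setSize)
    return(SignedGeneSet(picked, anchorSigns[picked],
                         provenance = c(origin = "partner",
                                        target_or = "Inf")))
  }
  inAnchor <- universe %in% names(anchorSigns)
  w <- ifelse(inAnchor, (targetOr + 1) / 2, 1)
  picked <- sample(universe, setSize, prob = w)
  isA <- picked %in% names(anchorSigns)
  sgn <- integer(setSize)
  match <- runif(setSize) < targetOr / (1 + targetOr)
  sgn[isA] <- ifelse(match[isA], anchorSigns[picked[isA]],
                     -anchorSigns[picked[isA]])
  sgn[!isA] <- sample(c(-1L, 1L), sum(!isA), replace = TRUE)
  SignedGeneSet(picked, sgn,
                provenance = c(origin = "partner",
                               target_or = as.character(targetOr)))
}

#' Simulate promoter sequences with an optional planted motif trend
#'
#' Generates i.i.d. background sequences of the given length for every
#' (gene, species) pair. With `trend = "gain"`, exact consensus copies of
#' the motif are planted so that the species' total (and hence mean)
#' planted count per promoter grows linearly with its MLS rank, from 0 in
#' the shortest-lived species to `maxInsertions` per promoter on average in
#' the longest-lived; copies are distributed over the gene promoters at
#' random, so the fraction of promoters carrying the motif stays
#' informative (below 1) as well. `trend = "loss"` reverses the gradient;
#' `trend = "none"` plants nothing.
#'
#' @param species data.frame with `species_id` and `mls_years`.
#' @param genes character vector of gene ids.
#' @param motif a [MotifModel-class] (used for its consensus and width).
#' @param trend `"gain"`, `"loss"` or `"none"`.
#' @param length promoter length in bp (default 1000; must be >= motif
#'   width).
#' @param maxInsertions mean planted copies per promoter in the extreme
#'   species (default 3).
#' @param baseProbs background base probabilities (default uniform).
#' @param seed RNG seed.
#' @return named character vector of sequences, names `gene|species`, with
#'   attribute `planted_total`: the planted copy total per species.
#' @export
simulatePromoters <- function(species, genes, motif,
                              trend = c("none", "gain", "loss"),
                              length = 1000L, maxInsertions = 3L,
                              baseProbs = rep(0.25, 4), seed = 1L) {
  trend <- match.arg(trend)
  cons <- motifConsensus(motif)
  w <- nchar(cons)
  if (length < w) stop("promoter length shorter than motif width")
  nSp <- nrow(species)
  nG <- base::length(genes)
  rankMls <- rank(species$mls_years, ties.method = "first")
  gradient <- switch(trend,
    none = rep(0, nSp),
    gain = (rankMls - 1) / (nSp - 1),
    loss = (nSp - rankMls) / (nSp - 1))
  totals <- round(gradient * maxInsertions * nG)
  set.seed(seed)
  out <- character(nSp * nG)
  nms <- character(nSp * nG)
  k <- 0L
  for (s in seq_len(nSp)) {
    copies <- if (totals[s] > 0L)
      tabulate(sample.int(nG, totals[s], replace = TRUE), nbins = nG)
    else integer(nG)
    chars <- DNA_BASES[sample.int(4L, nG * length, replace = TRUE,
                                  prob = baseProbs)]
    for (gi in seq_len(nG)) {
      seq <- paste(chars[((gi - 1L) * length + 1L):(gi * length)],
                   collapse = "")
      nCopy <- copies[gi]
      if (nCopy > 0L) {
        # non-overlapping slots: partition the promoter into nCopy blocks
        # and place one consensus copy at a random offset within each
        block <- length %/% nCopy
        if (block < w) stop("too many insertions for the promoter length")
        for (ci in seq_len(nCopy)) {
          at <- (ci - 1L) * block + sample.int(block - w + 1L, 1L)
          substr(seq, at, at + w - 1L) <- cons
        }
      }
      k <- k + 1L
      out[k] <- seq
      nms[k] <- paste0(genes[gi], "|", species$species_id[s])
    }
  }
  structure(setNames(out, nms),
            planted_total = setNames(totals, species$species_id))
}

#' Simulate a motif model
#'
#' A synthetic position frequency matrix with a random consensus and a
#' given per-position concentration (probability mass on the consensus
#' base), emulating a curated transcription-factor motif.
#'
#' @param motifId identifier for the motif.
#' @param width motif width.
#' @param seed RNG seed.
#' @param concentration consensus-base probability per position (default
#'   0.85, the remainder split equally).
#' @param counts total pseudo-observations per column (default 100).
#' @param balanced if TRUE, draw the consensus as a random permutation of a
#'   base-balanced multiset (equal A/C/G/T content, width a multiple of 4),
#'   so that planting consensus copies leaves the sequence composition
#'   unchanged; useful for composition-neutral spike-ins.
#' @return a [MotifModel-class].
#' @export
simulateMotif <- function(motifId, width, seed = 1L, concentration = 0.85,
                          counts = 100L, balanced = FALSE) {
  set.seed(seed)
  if (balanced) {
    if (width %% 4L != 0L)
      stop("balanced consensus needs width divisible by 4")
    cons <- sample(rep(1:4, width %/% 4L))
  } else {
    cons <- sample.int(4L, width, replace = TRUE)
  }
  mat <- matrix(counts * (1 - concentration) / 3, 4L, width)
  mat[cbind(cons, seq_len(width))] <- counts * concentration
  MotifModel(motifId, mat, pseudocount = 0.01)
}
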