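# PWM promoter scanning with null p-values from the exact distribution of
# the log-odds score of a random background window, and the per-species
# motif-statistic trend test against maximum lifespan.

DNA_BASES <- c("A", "C", "G", "T")

#' Base composition of a sequence set
#' @param seqs DNAStringSet or character vector.
#' @return length-4 probability vector (A,C,G,T); non-ACGT codes ignored.
#' @export
baseComposition <- function(seqs) {
  chars <- strsplit(paste(as.character(seqs), collapse = ""), "")[[1L]]
  counts <- tabulate(match(chars, DNA_BASES), nbins = 4L)
  if (sum(counts) == 0) return(rep(0.25, 4))
  counts / sum(counts)
}

#' Exact null distribution of the motif log-odds score
#'
#' Distribution of the score of a random width-w window drawn from the
#' motif's background model, computed by dynamic programming (convolution
#' across columns). For widths up to `exactMaxWidth` the convolution is
#' carried out on the exact score values (distinct sums merged at 1e-9
#' resolution), so tail probabilities agree with exhaustive enumeration over
#' all 4^w windows. Wider motifs use a discretized integer-score grid with
#' `granularity` bins per column, the approximation commonly used by
#' large-scale scanners.
#'
#' @param motif a [MotifModel-class].
#' @param granularity integer >= 100, score bins per column for the grid
#'   path (default 1000).
#' @param exactMaxWidth widest motif handled by the exact-value path
#'   (default 10).
#' @return an object of class `motifScoreDist`: ascending `scores` with
#'   `tail\[k\] = P(S >= scores\[k\])` (non-increasing in the score).
#' @export
exactScoreDistribution <- function(motif, granularity = 1000L,
                                   exactMaxWidth = 10L) {
  if (granularity < 100L) stop("granularity must be >= 100")
  lo <- motifLogOdds(motif)
  bg <- motifBackground(motif)
  w <- ncol(lo)
  if (w <= exactMaxWidth) {
    s <- 0; p <- 1
    for (j in seq_len(w)) {
      sNew <- rep(s, each = 4L) + lo[, j]
      pNew <- rep(p, each = 4L) * bg
      key <- round(sNew * 1e9)
      o <- order(key)
      sNew <- sNew[o]; pNew <- pNew[o]; key <- key[o]
      first <- !duplicated(key)
      s <- sNew[first]
      p <- as.numeric(rowsum(pNew, cumsum(first)))
    }
    tail <- rev(cumsum(rev(p)))
    out <- list(scores = s, tail = pmin(tail, 1), exact = TRUE)
  } else {
    # integer grid: shift each column to min 0, round to a common step
    colMin <- apply(lo, 2, min)
    step <- max(apply(lo, 2, function(col) diff(range(col)))) / granularity
    if (step <= 0) step <- 1e-9
    ints <- round(sweep(lo, 2, colMin, "-") / step)
    maxInt <- sum(apply(ints, 2, max))
    dist <- c(1, numeric(maxInt))   # P(int score = 0..maxInt)
    top <- 0L
    for (j in seq_len(w)) {
      nxt <- numeric(maxInt + 1L)
      for (b in 1:4) {
        k <- ints[b, j]
        idx <- seq_len(top + 1L)
        nxt[idx + k] <- nxt[idx + k] + dist[idx] * bg[b]
      }
      dist <- nxt
      top <- top + max(ints[, j])
    }
    tail <- rev(cumsum(rev(dist)))
    out <- list(scores = (0:maxInt) * step + sum(colMin),
                tail = pmin(tail, 1), exact = FALSE, step = step,
                origin = sum(colMin))
  }
  out$width <- w
  class(out) <- "motifScoreDist"
  out
}

#' Null tail probability of a score
#'
#' P(random background window scores >= `score`), from a distribution
#' produced by [exactScoreDistribution()].
#'
#' @param dist a `motifScoreDist`.
#' @param score numeric vector of scores (bits).
#' @return numeric vector of tail probabilities.
#' @export
scoreTailProb <- function(dist, score) {
  # index of the first stored score >= score (within tolerance)
  idx <- findInterval(score - 1e-9, dist$scores) + 1L
  out <- numeric(length(score))
  inRange <- idx <= length(dist$scores)
  out[inRange] <- dist$tail[idx[inRange]]
  out[!inRange] <- 0
  out
}

# smallest score whose null tail probability is < pThreshold (Inf if none)
scoreThresholdFor <- function(dist, pThreshold) {
  hit <- which(dist$tail < pThreshold)
  if (!length(hit)) return(Inf)
  dist$scores[hit[1L]]
}

seqToCodes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1L]], DNA_BASES)
}

# reverse-complement scoring matrix: scanning the forward strand with it is
# equivalent to scanning the reverse complement with the original matrix
revcompLogOdds <- function(lo) lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]

scoreWindows <- function(codes, lo) {
  if (length(codes) - ncol(lo) + 1L < 1L) return(numeric(0))
  scoreWindowsC(as.integer(codes), lo)
}

#' Scan one sequence for motif occurrences
#'
#' Scores every width-w window on both strands with the motif's log2-odds
#' matrix and reports windows whose null p-value (from
#' [exactScoreDistribution()]) is below `pThreshold`. Windows containing a
#' non-ACGT code are skipped. Offsets are 0-based on the forward coordinate
#' system regardless of strand; the window is \[offset, offset + width).
#'
#' @param seq a single DNA string (character or DNAString).
#' @param motif a [MotifModel-class].
#' @param pThreshold report hits with null p strictly below this (default
#'   1e-4, the conventional scanner default).
#' @param dist optional precomputed `motifScoreDist` for this motif.
#' @param strands strands to scan (default both).
#' @return data.frame with columns `offset`, `strand`, `score`, `p`.
#' @export
scanPromoter <- function(seq, motif, pThreshold = 1e-4, dist = NULL,
                         strands = c("+", "-")) {
  if (is.null(dist)) dist <- exactScoreDistribution(motif)
  lo <- motifLogOdds(motif)
  codes <- seqToCodes(as.character(seq))
  sStar <- scoreThresholdFor(dist, pThreshold)
  res <- list()
  for (strand in strands) {
    mat <- if (strand == "+") lo else revcompLogOdds(lo)
    hit <- scanThresholdC(as.integer(codes), mat, sStar - 1e-9)
    if (length(hit$pos))
      res[[strand]] <- data.frame(offset = hit$pos - 1L, strand = strand,
                                  score = hit$score,
                                  p = scoreTailProb(dist, hit$score))
  }
  if (!length(res))
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters for one motif
#'
#' Equivalent to [scanPromoter()] per sequence but scored in a single
#' vectorized pass (sequences are concatenated with N spacers, which no
#' window can cross).
#'
#' @param seqs named character vector or DNAStringSet.
#' @inheritParams scanPromoter
#' @return data.frame with `seqname`, `offset`, `strand`, `score`, `p`.
#' @export
scanPromoterSet <- function(seqs, motif, pThreshold = 1e-4, dist = NULL,
                            strands = c("+", "-"), prep = NULL) {
  if (is.null(dist)) dist <- exactScoreDistribution(motif)
  lo <- motifLogOdds(motif)
  w <- ncol(lo)
  if (is.null(prep)) prep <- prepPromoterCodes(seqs, w)
  # any window crossing a sequence boundary overlaps >= 1 spacer N and is
  # skipped, so a spacer of length >= 1 is safe for every motif width
  if (prep$spacer < 1L) stop("spacer must be >= 1")
  starts <- prep$starts
  codes <- prep$codes
  seqnames <- prep$names
  sStar <- scoreThresholdFor(dist, pThreshold)
  res <- list()
  for (strand in strands) {
    mat <- if (strand == "+") lo else revcompLogOdds(lo)
    hit <- scanThresholdC(as.integer(codes), mat, sStar - 1e-9)
    if (length(hit$pos)) {
      si <- findInterval(hit$pos, starts)
      res[[strand]] <- data.frame(seqname = seqnames[si],
                                  offset = hit$pos - starts[si],
                                  strand = strand, score = hit$score,
                                  p = scoreTailProb(dist, hit$score))
    }
  }
  if (!length(res))
    return(data.frame(seqname = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0)))
  out <- do.call(rbind, res)
  out <- out[order(match(out$seqname, seqnames), out$offset,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pre-encode a promoter set for repeated scanning: sequences concatenated
# with N spacers of length `spacer` (which no window of width <= spacer + 1
# can cross), integer base codes, and 1-based start offsets.
prepPromoterCodes <- function(seqs, spacer) {
  sq <- as.character(seqs)
  names(sq) <- names(seqs)
  if (is.null(names(sq))) stop("sequences must be named")
  lens <- nchar(sq)
  list(codes = seqToCodes(paste(sq, collapse = strrep("N", spacer))),
       starts = cumsum(c(1L, lens[-length(lens)] + spacer)),
       names = names(sq), spacer = as.integer(spacer))
}

#' Per-gene-set motif statistics
#'
#' For one species and one motif: the fraction of genes with at least one
#' hit in their promoter, and the mean number of hits per promoter. Genes
#' without an available promoter are excluded from the denominator.
#'
#' @param hits data.frame with a `gene` column (one row per hit), already
#'   restricted to one species and motif.
#' @param geneSet character vector of genes to evaluate.
#' @param available optional character vector of genes with promoters; by
#'   default all of `geneSet`.
#' @return list with `presence_ratio`, `mean_count`, `n_genes`.
#' @export
motifGeneStats <- function(hits, geneSet, available = NULL) {
  geneSet <- unique(as.character(geneSet))
  if (!length(geneSet)) stop("empty gene set")
  if (!is.null(available)) {
    dropped <- setdiff(geneSet, available)
    if (length(dropped))
      message(length(dropped), " gene(s) without promoter excluded")
    geneSet <- intersect(geneSet, available)
    if (!length(geneSet)) stop("no gene in the set has a promoter")
  }
  cnt <- tabulate(match(hits$gene, geneSet), nbins = length(geneSet))
  list(presence_ratio = mean(cnt >= 1L),
       mean_count = sum(cnt) / length(geneSet),
       n_genes = length(geneSet))
}

#' Motif/MLS co-evolution trend test
#'
#' For each motif and species, forms the odds ratio of the promoter motif
#' presence ratio between a trait-associated gene set and the background
#' (odds(p1)/odds(p0)), and the ratio of mean motif counts, then tests the
#' Spearman correlation of each per-species metric with maximum lifespan.
#' FDR is controlled across all (motif, metric) tests with [bkyFdr()]; a
#' motif is called trait-associated only if BOTH metrics are significant
#' with a consistent trend direction.
#'
#' @param stats data.frame with columns `motif`, `species`,
#'   `presence_set`, `presence_bg`, `count_set`, `count_bg`.
#' @param mls named numeric vector of maximum lifespans (years) by species.
#' @param fdr FDR level for calling (default 0.05).
#' @param minSpecies minimum usable species per metric (default 5).
#' @return data.frame with one row per (motif, metric): `rho`, `p`, `q`,
#'   `n_species`, `called` (both-metric rule applied per motif).
#' @export
coevolutionTrend <- function(stats, mls, fdr = 0.05, minSpecies = 5L) {
  rows <- list()
  for (mo in unique(stats$motif)) {
    st <- stats[stats$motif == mo, , drop = FALSE]
    lifespan <- mls[st$species]
    # presence metric: true odds ratio; species where either ratio is 0 or
    # 1 have undefined odds and are dropped
    okP <- st$presence_set > 0 & st$presence_set < 1 &
      st$presence_bg > 0 & st$presence_bg < 1 & !is.na(lifespan)
    orP <- (st$presence_set / (1 - st$presence_set)) /
      (st$presence_bg / (1 - st$presence_bg))
    # mean-count metric: plain ratio of means (odds of an unbounded mean
    # are undefined); background mean of 0 drops the species
    okC <- st$count_bg > 0 & !is.na(lifespan)
    ratC <- st$count_set / st$count_bg
    for (metric in c("presence_ratio", "mean_count")) {
      ok <- if (metric == "presence_ratio") okP else okC
      v <- if (metric == "presence_ratio") orP else ratC
      if (sum(ok) < minSpecies) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = mo, metric = metric, rho = NA_real_, p = NA_real_,
          n_species = sum(ok))
        next
      }
      fit <- tryCatch(spearmanAssociation(v[ok], lifespan[ok]),
                      error = function(e) list(rho = NA_real_, p = NA_real_,
                                               n = sum(ok)))
      rows[[length(rows) + 1L]] <- data.frame(
        motif = mo, metric = metric, rho = fit$rho, p = fit$p,
        n_species = sum(ok))
    }
  }
  out <- do.call(rbind, rows)
  testable <- !is.na(out$p)
  out$q <- NA_real_
  if (any(testable))
    out$q[testable] <- bkyFdr(out$p[testable], fdr)$q_values
  out$called <- FALSE
  for (mo in unique(out$motif)) {
    idx <- out$motif == mo
    sig <- !is.na(out$q[idx]) & out$q[idx] < fdr
    sameDir <- length(unique(sign(out$rho[idx][sig]))) == 1L
    if (all(sig) && sameDir) out$called[idx] <- TRUE
  }
  rownames(out) <- NULL
  out
}

#' Full promoter motif co-evolution analysis
#'
#' Scans every species' promoters for each motif, computes the per-species
#' presence/mean-count statistics for a trait-associated gene set versus
#' the background gene set, and runs [coevolutionTrend()].
#'
#' @param promoters DNAStringSet named `gene|species`.
#' @param motifs list of [MotifModel-class] objects.
#' @param setGenes character vector: the trait-associated gene set.
#' @param backgroundGenes character vector: the investigated-gene
#'   background (genes in `setGenes` are excluded from it).
#' @param mls named numeric vector of maximum lifespans by species.
#' @param pThreshold scanner p-value threshold (default 1e-4).
#' @param fdr FDR for the trend test (default 0.05).
#' @param background `"promoters"` (zero-order model estimated from the
#'   input sequences, the default) or `"uniform"`; motif log-odds are
#'   rebuilt against this background before scanning.
#' @return list with `trend` (the [coevolutionTrend()] table), `stats`
#'   (per motif x species statistics), `called` (motif ids passing the
#'   both-metric rule).
#' @export
motifCoevolution <- function(promoters, motifs, setGenes, backgroundGenes,
                             mls, pThreshold = 1e-4, fdr = 0.05,
                             background = c("promoters", "uniform")) {
  background <- match.arg(background)
  keys <- splitPromoterNames(names(promoters))
  backgroundGenes <- setdiff(backgroundGenes, setGenes)
  if (!length(backgroundGenes)) stop("empty background gene set")
  statRows <- list()
  allSpecies <- unique(keys$species)
  preps <- lapply(allSpecies, function(sp) {
    idx <- keys$species == sp
    prep <- prepPromoterCodes(promoters[idx], 1L)
    prep$names <- keys$gene[idx]   # map hits straight to gene ids
    prep
  })
  names(preps) <- allSpecies
  bg <- if (background == "promoters") {
    counts <- Reduce(`+`, lapply(preps, function(p)
      tabulate(p$codes, nbins = 4L)))
    counts / sum(counts)
  } else rep(0.25, 4)
  bg[bg <= 0] <- 1e-6
  bg <- bg / sum(bg)
  for (motif in motifs) {
    m <- MotifModel(motif@motifId, motif@frequencies, pseudocount = 0,
                    background = bg, tfName = motif@tfName)
    dist <- exactScoreDistribution(m)
    for (sp in allSpecies) {
      idx <- keys$species == sp
      hits <- scanPromoterSet(promoters[idx], m, pThreshold, dist = dist,
                              prep = preps[[sp]])
      hitGenes <- hits$seqname
      avail <- keys$gene[idx]
      stSet <- motifGeneStats(data.frame(gene = hitGenes), setGenes,
                              available = avail)
      stBg <- motifGeneStats(data.frame(gene = hitGenes), backgroundGenes,
                             available = avail)
      statRows[[length(statRows) + 1L]] <- data.frame(
        motif = m@motifId, species = sp,
        presence_set = stSet$presence_ratio,
        presence_bg = stBg$presence_ratio,
        count_set = stSet$mean_count, count_bg = stBg$mean_count)
    }
  }
  stats <- do.call(rbind, statRows)
  trend <- coevolutionTrend(stats, mls, fdr = fdr)
  list(trend = trend, stats = stats,
       called = unique(trend$motif[trend$called]))
}
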