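# Concordance between two signed gene sets: concordant/discordant counts,
# observed-vs-expected odds ratios, exact binomial overlap tests, and the
# coefficient-profile comparisons used when contrasting species panels.

#' Count concordant and discordant genes
#'
#' Both sets are first restricted to the shared gene universe. Concordant
#' genes carry the same sign in both sets (+/+ or -/-), discordant genes
#' opposite signs. Expected counts under independence are summed over sign
#' strata: E\[concordant\] = sum_s |A_s||B_s|/N, E\[discordant\] =
#' sum_s |A_s||B_-s|/N.
#'
#' @param a,b [SignedGeneSet-class] objects; `a` is the query (e.g. the
#'   MLS-associated set) on which the odds ratios condition.
#' @param universe character vector of investigated genes.
#' @return list with `n_universe`, `n_a`, `n_b`, stratum sizes, observed
#'   and expected concordant/discordant counts.
#' @export
classifyConcordance <- function(a, b, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  sa <- geneSigns(restrictToUniverse(a, universe))
  sb <- geneSigns(restrictToUniverse(b, universe))
  N <- length(universe)
  aPos <- names(sa)[sa > 0]; aNeg <- names(sa)[sa < 0]
  bPos <- names(sb)[sb > 0]; bNeg <- names(sb)[sb < 0]
  conc <- length(intersect(aPos, bPos)) + length(intersect(aNeg, bNeg))
  disc <- length(intersect(aPos, bNeg)) + length(intersect(aNeg, bPos))
  expConc <- (length(aPos) * length(bPos) +
                length(aNeg) * length(bNeg)) / N
  expDisc <- (length(aPos) * length(bNeg) +
                length(aNeg) * length(bPos)) / N
  list(n_universe = N, n_a = length(sa), n_b = length(sb),
       n_a_pos = length(aPos), n_a_neg = length(aNeg),
       n_b_pos = length(bPos), n_b_neg = length(bNeg),
       concordant = conc, discordant = disc,
       expected_concordant = expConc, expected_discordant = expDisc)
}

#' Two-sided exact binomial overlap test
#'
#' Tests whether an observed overlap count is compatible with chance:
#' k successes in `nA` trials at null success probability `p0`. Two-sided
#' p-value by the small-p-sum convention (sum of the probabilities of all
#' outcomes no more likely than the observed one).
#'
#' @param k observed count.
#' @param nA number of trials (size of the query set).
#' @param p0 null success probability, e.g. expected count / nA.
#' @return the p-value.
#' @export
overlapBinomialTest <- function(k, nA, p0) {
  if (k < 0 || k > nA) stop("k must lie in [0, nA]")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (nA == 0L) return(1)
  if (p0 == 0) return(if (k == 0) 1 else 0)
  if (p0 == 1) return(if (k == nA) 1 else 0)
  stats::binom.test(k, nA, p = p0, alternative = "two.sided")$p.value
}

#' Concordance and discordance odds ratios
#'
#' The odds that a query-set gene is concordant (observed) relative to the
#' odds expected under independence: OR = \[O/(nA - O)\] / \[E/(nA - E)\],
#' pooled over the two sign strata; likewise for discordant genes. Undefined
#' ratios (zero denominators) are returned as NA with a flag.
#'
#' @param counts result of [classifyConcordance()].
#' @return list with `or_concordant`, `or_discordant` and logical
#'   `undefined_concordant`, `undefined_discordant`.
#' @export
concordanceOddsRatio <- function(counts) {
  orOne <- function(O, E, nA) {
    if (nA == 0 || O >= nA || E <= 0 || E >= nA)
      return(list(or = NA_real_, undef = TRUE))
    list(or = (O / (nA - O)) / (E / (nA - E)), undef = FALSE)
  }
  oc <- orOne(counts$concordant, counts$expected_concordant, counts$n_a)
  od <- orOne(counts$discordant, counts$expected_discordant, counts$n_a)
  list(or_concordant = oc$or, or_discordant = od$or,
       undefined_concordant = oc$undef, undefined_discordant = od$undef)
}

#' Full concordance comparison of two signed gene sets
#'
#' Combines [classifyConcordance()], [concordanceOddsRatio()] and
#' [overlapBinomialTest()] (trials = query-set members, null success
#' probability = expected count / nA) into one result row.
#'
#' @inheritParams classifyConcordance
#' @param label optional comparison label.
#' @return one-row data.frame with counts, expectations, odds ratios and
#'   binomial p-values for the concordant and discordant directions.
#' @export
concordanceTest <- function(a, b, universe, label = NA_character_) {
  ct <- classifyConcordance(a, b, universe)
  ors <- concordanceOddsRatio(ct)
  pConc <- if (ct$n_a > 0)
    overlapBinomialTest(ct$concordant, ct$n_a,
                        min(ct$expected_concordant / ct$n_a, 1)) else 1
  pDisc <- if (ct$n_a > 0)
    overlapBinomialTest(ct$discordant, ct$n_a,
                        min(ct$expected_discordant / ct$n_a, 1)) else 1
  data.frame(label = label, n_universe = ct$n_universe, n_a = ct$n_a,
             n_b = ct$n_b, concordant = ct$concordant,
             discordant = ct$discordant,
             expected_concordant = ct$expected_concordant,
             expected_discordant = ct$expected_discordant,
             or_concordant = ors$or_concordant,
             or_discordant = ors$or_discordant,
             p_concordant = pConc, p_discordant = pDisc)
}

#' Concordance across many comparisons with FDR control
#'
#' Runs [concordanceTest()] for each (a, b) pair and applies [bkyFdr()]
#' across all binomial p-values of each direction, mirroring per-panel
#' significance marking at a given FDR.
#'
#' @param pairs list of lists with elements `a`, `b`, `universe` and
#'   optionally `label`.
#' @param fdr FDR level for the q-value columns (default 0.05).
#' @return data.frame with one row per comparison plus `q_concordant`,
#'   `q_discordant`.
#' @export
concordanceBattery <- function(pairs, fdr = 0.05) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    concordanceTest(p$a, p$b, p$universe,
                    label = if (!is.null(p$label)) p$label else
                      paste0("comparison_", i))
  })
  out <- do.call(rbind, rows)
  out$q_concordant <- bkyFdr(out$p_concordant, fdr)$q_values
  out$q_discordant <- bkyFdr(out$p_discordant, fdr)$q_values
  out
}

#' Compare two per-gene correlation-coefficient profiles
#'
#' Welch (unequal-variance, unpaired) two-tailed t-test between two vectors
#' of per-tissue correlation coefficients for the same gene in two species
#' panels. Degenerate inputs (both groups with zero variance) are flagged:
#' identical profiles give p = 1, disjoint constant profiles are reported
#' with p = 0 and `degenerate = TRUE`.
#'
#' @param rho1,rho2 numeric vectors (length >= 2 each).
#' @return list with `t`, `p`, `degenerate`.
#' @export
compareCoefficientProfiles <- function(rho1, rho2) {
  if (length(rho1) < 2L || length(rho2) < 2L)
    stop("each coefficient vector needs length >= 2")
  if (sd(rho1) == 0 && sd(rho2) == 0) {
    if (mean(rho1) == mean(rho2))
      return(list(t = 0, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(rho1) - mean(rho2)) * Inf, p = 0,
                degenerate = TRUE))
  }
  fit <- stats::t.test(rho1, rho2, var.equal = FALSE,
                       alternative = "two.sided")
  list(t = unname(fit$statistic), p = fit$p.value, degenerate = FALSE)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided test of median = `mu0`. Values equal to `mu0` are dropped;
#' the exact null distribution is used for n <= 25 (no ties), the normal
#' approximation with continuity correction otherwise.
#'
#' @param values numeric vector.
#' @param mu0 hypothesized median (default 0).
#' @return the p-value.
#' @export
oneSampleWilcoxon <- function(values, mu0 = 0) {
  v <- values[values != mu0]
  if (!length(v)) stop("all values equal mu0: test undefined")
  if (length(v) < 5L)
    warning("fewer than 5 non-tied values; test has little power")
  n <- length(v)
  exact <- n <= 25L && !anyDuplicated(abs(v - mu0))
  suppressWarnings(
    stats::wilcox.test(v, mu = mu0, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}
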