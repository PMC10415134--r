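# Trait-expression association: Spearman rank correlation with exact small-n
# p-values, closed-form PGLS under Brownian-motion covariance, conservative
# max-p aggregation over a tree ensemble, and two-stage adaptive FDR control.

#' Drop genes observed in too few species
#'
#' Genes measured in fewer than `minSpecies` species carry too little
#' cross-species information to test; the surviving rows define the
#' "all investigated genes" background used downstream (concordance
#' universes, enrichment backgrounds).
#'
#' @param expr genes x species matrix (NA = missing) or a
#'   [LifespanExperiment-class].
#' @param minSpecies minimum number of non-missing species per gene
#'   (inclusive). Default 10.
#' @return object of the same class with under-observed genes removed, in
#'   the original order.
#' @export
filterMinSpecies <- function(expr, minSpecies = 10L) {
  m <- if (methods::is(expr, "LifespanExperiment")) exprValues(expr) else expr
  nObs <- rowSums(!is.na(m))
  keep <- nObs >= minSpecies
  if (!any(keep)) stop("no gene observed in >= ", minSpecies, " species")
  if (any(!keep))
    message(sum(!keep), " gene(s) observed in < ", minSpecies,
            " species removed; ", sum(keep), " investigated genes retained")
  expr[keep, , drop = FALSE]
}

# all permutations of 1..n as an (n! x n) matrix; n is small (<= 7 here)
permutationMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationMatrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Spearman correlation with two-sided p-value
#'
#' Rank correlation (average ranks for ties) between a gene's expression and
#' a trait. The two-sided p-value is exact — computed by enumerating all n!
#' permutations of one rank vector — for n <= `exactMax`, and uses the
#' t-distribution approximation with n-2 degrees of freedom otherwise.
#'
#' @param x,y paired numeric vectors; pairs with any NA are dropped.
#' @param exactMax largest n for which the exact permutation null is used
#'   (default 7).
#' @return list with `rho`, `p`, and `n` (pairs used).
#' @export
spearmanAssociation <- function(x, y, exactMax = 7L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("constant input: Spearman correlation undefined")
  rho <- cor(rx, ry)
  if (n <= exactMax) {
    P <- permutationMatrix(n)
    A <- matrix(ry[P], nrow(P), n)
    cross <- as.numeric(A %*% rx)
    rhoAll <- (cross - n * mean(rx) * mean(ry)) /
      ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Phylogenetic generalized least squares fit
#'
#' Regresses `y` on `x` with intercept under error covariance proportional
#' to `V` (Brownian motion on the phylogeny: V[i,j] = shared root-to-MRCA
#' branch length). Closed form: beta = (X' V^-1 X)^-1 X' V^-1 y, residual
#' variance from the generalized residual sum of squares on n-2 degrees of
#' freedom, two-sided t-test on the slope.
#'
#' @param y,x numeric vectors over the same species, no NAs.
#' @param V positive-definite covariance matrix matching `y`.
#' @return list with `slope`, `intercept`, `slope_se`, `t`, `p`, `df`.
#' @export
pglsFit <- function(y, x, V) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 species for PGLS")
  if (length(x) != n || !identical(dim(V), c(n, n)))
    stop("dimension mismatch between y, x and V")
  L <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite"))
  Vi <- chol2inv(L)
  X <- cbind(intercept = 1, slope = x)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  if (abs(det(XtViX)) < 1e-12 * max(abs(XtViX))^2)
    stop("singular design (constant x?)")
  XtViXinv <- solve(XtViX)
  beta <- as.numeric(XtViXinv %*% (XtVi %*% y))
  resid <- y - as.numeric(X %*% beta)
  rss <- as.numeric(crossprod(resid, Vi %*% resid))
  df <- n - 2L
  sigma2 <- rss / df
  se <- unname(sqrt(pmax(sigma2 * diag(XtViXinv), 0)))
  tstat <- if (se[2L] > 0) beta[2L] / se[2L] else sign(beta[2L]) * Inf
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(slope = beta[2L], intercept = beta[1L], slope_se = se[2L],
       t = tstat, p = p, df = df)
}

#' PGLS across a tree ensemble with max-p aggregation
#'
#' Fits [pglsFit()] once per candidate tree (each tree's Brownian covariance
#' restricted to the species with data) and tests the association with the
#' maximum p-value across trees — the least significant fit — a conservative
#' treatment of phylogenetic uncertainty. The reported slope is taken from
#' the fit attaining that maximum. Slope-sign disagreement across trees is
#' flagged.
#'
#' @param y named numeric vector of expression values (names = species; NAs
#'   dropped).
#' @param x named numeric vector of the trait (log2 MLS) covering `y`.
#' @param trees a `multiPhylo`/list of trees, or a precomputed list of full
#'   covariance matrices with species dimnames (as from [phyloCovariance()]).
#' @return list with `p_max`, `slope_ref`, `sign_conflict` (logical),
#'   `p_per_tree`, `slope_per_tree`, `n`.
#' @export
pglsEnsemble <- function(y, x, trees) {
  if (!length(trees)) stop("empty tree ensemble")
  ok <- !is.na(y)
  y <- y[ok]
  sp <- names(y)
  if (is.null(sp)) stop("y must be named by species")
  x <- x[sp]
  if (anyNA(x)) stop("trait missing for some species")
  covs <- lapply(trees, function(tr) {
    if (is.matrix(tr)) tr else phyloCovariance(tr)
  })
  ps <- numeric(length(covs))
  slopes <- numeric(length(covs))
  for (i in seq_along(covs)) {
    V <- covs[[i]]
    bad <- setdiff(sp, rownames(V))
    if (length(bad))
      stop("species not in tree ", i, ": ", paste(bad, collapse = ", "))
    fit <- pglsFit(y, x, V[sp, sp, drop = FALSE])
    ps[i] <- fit$p
    slopes[i] <- fit$slope
  }
  imax <- which.max(ps)
  conflict <- length(unique(sign(slopes[slopes != 0]))) > 1L
  list(p_max = ps[imax], slope_ref = slopes[imax],
       sign_conflict = conflict, p_per_tree = ps, slope_per_tree = slopes,
       n = length(y))
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR control
#'
#' Adaptive linear step-up procedure: stage 1 runs Benjamini-Hochberg at
#' q' = q/(1+q); if it rejects none (or all), stop; otherwise the number of
#' true nulls is estimated as m0 = m - r1 and stage 2 reruns BH at level
#' q' * m/m0. Adjusted q-values are defined so that `q_values <= q`
#' reproduces the stage-2 rejection set exactly.
#'
#' @param pValues numeric vector of p-values in \[0,1\].
#' @param q nominal FDR level (default 0.10).
#' @return list with logical `rejected` and numeric `q_values`, both in the
#'   input order.
#' @export
bkyFdr <- function(pValues, q = 0.10) {
  p <- as.numeric(pValues)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (!m) return(list(rejected = logical(0), q_values = numeric(0)))
  qPrime <- q / (1 + q)
  bhAdj <- stats::p.adjust(p, method = "BH")
  r1 <- sum(bhAdj <= qPrime)
  if (r1 == 0L || r1 == m) {
    qv <- pmin(bhAdj * (1 + q), 1)
  } else {
    qv <- pmin(bhAdj * (1 + q) * (m - r1) / m, 1)
  }
  list(rejected = qv <= q, q_values = qv)
}

#' Run trait association over all genes
#'
#' The main association driver: filters genes by species coverage, tests
#' each gene against log2(MLS) by the requested method(s), applies
#' [bkyFdr()] per method, and returns an [AssociationTable-class]. Genes
#' with constant expression are untestable and are excluded from both the
#' tested set and the background (with a message).
#'
#' @param expr genes x species matrix (NA = missing) or
#'   [LifespanExperiment-class].
#' @param mls named vector of maximum lifespans in years (taken from
#'   `colData` if `expr` is a LifespanExperiment and `mls` is NULL).
#' @param trees tree ensemble (`multiPhylo` or list of covariance matrices);
#'   required when `"pgls"` is among `methods`.
#' @param methods any of `"spearman"`, `"pgls"`.
#' @param minSpecies coverage filter passed to [filterMinSpecies()].
#' @param fdrLevel nominal FDR for downstream calling (recorded in the
#'   table).
#' @return an [AssociationTable-class]; its `records` carry one row per
#'   (gene, method), with `sign_conflict` set for ensemble fits whose slope
#'   sign differed across trees.
#' @export
associateMLS <- function(expr, mls = NULL, trees = NULL,
                         methods = c("spearman", "pgls"),
                         minSpecies = 10L, fdrLevel = 0.10) {
  if (methods::is(expr, "LifespanExperiment")) {
    if (is.null(mls)) mls <- mlsYears(expr)
    expr <- exprValues(expr)
  }
  methods <- match.arg(methods, c("spearman", "pgls"), several.ok = TRUE)
  if ("pgls" %in% methods && is.null(trees))
    stop("PGLS requested but no tree ensemble supplied")
  if (is.null(names(mls))) stop("mls must be named by species")
  expr <- expr[, intersect(colnames(expr), names(mls)), drop = FALSE]
  expr <- filterMinSpecies(expr, minSpecies)
  trait <- log2(mls[colnames(expr)])

  if (!is.null(trees))
    trees <- lapply(trees, function(tr)
      if (is.matrix(tr)) tr else phyloCovariance(tr))

  recs <- list()
  skipped <- character()
  for (g in rownames(expr)) {
    yg <- expr[g, ]
    obs <- !is.na(yg)
    for (m in methods) {
      rec <- tryCatch({
        if (m == "spearman") {
          fit <- spearmanAssociation(yg[obs], trait[obs])
          data.frame(gene = g, method = m, statistic = fit$rho,
                     p_value = fit$p, n_species = fit$n,
                     sign = sign(fit$rho), sign_conflict = FALSE)
        } else {
          fit <- pglsEnsemble(yg[obs], trait, trees)
          data.frame(gene = g, method = m, statistic = fit$slope_ref,
                     p_value = fit$p_max, n_species = fit$n,
                     sign = sign(fit$slope_ref),
                     sign_conflict = fit$sign_conflict)
        }
      }, error = function(e) {
        skipped <<- c(skipped, paste0(g, " [", m, "]: ",
                                      conditionMessage(e)))
        NULL
      })
      if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
    }
  }
  if (length(skipped))
    message(length(skipped), " gene/method test(s) skipped (e.g. ",
            skipped[1L], ")")
  records <- do.call(rbind, recs)
  if (is.null(records)) stop("no testable genes")
  records$q_value <- NA_real_
  for (m in methods) {
    idx <- records$method == m
    records$q_value[idx] <- bkyFdr(records$p_value[idx], fdrLevel)$q_values
  }
  records <- records[, c("gene", "method", "statistic", "p_value",
                         "q_value", "n_species", "sign", "sign_conflict")]
  rownames(records) <- NULL
  AssociationTable(records, traitName = "mls", fdrMethod = "BKY",
                   fdrLevel = fdrLevel)
}

#' Call a signed gene set from an association table
#'
#' Genes with q strictly below `fdrLevel` are called, signed by their test
#' statistic. Ensemble fits whose slope sign disagreed across trees are
#' excluded (their direction is not trustworthy).
#'
#' @param table an [AssociationTable-class].
#' @param fdrLevel FDR threshold (strict `<`); defaults to the table's own
#'   level.
#' @param method restrict to one method (`"spearman"`/`"pgls"`); default all.
#' @return a [SignedGeneSet-class] with provenance recording trait, method
#'   and level.
#' @export
callSignedSet <- function(table, fdrLevel = NULL, method = NULL) {
  r <- associationRecords(table)
  if (is.null(fdrLevel)) fdrLevel <- fdrLevel(table)
  if (!is.null(method)) r <- r[r$method %in% method, , drop = FALSE]
  hit <- !is.na(r$q_value) & r$q_value < fdrLevel
  if ("sign_conflict" %in% names(r)) {
    nconf <- sum(hit & r$sign_conflict)
    if (nconf)
      warning(nconf, " significant gene(s) excluded for slope-sign ",
              "disagreement across trees")
    hit <- hit & !r$sign_conflict
  }
  r <- r[hit, , drop = FALSE]
  # a gene significant by several methods with opposite signs is ambiguous
  sgn <- tapply(r$sign, r$gene, function(s) {
    u <- unique(s)
    if (length(u) == 1L) u else NA_integer_
  })
  ambiguous <- names(sgn)[is.na(sgn)]
  if (length(ambiguous))
    warning(length(ambiguous), " gene(s) called with opposite signs by ",
            "different methods excluded")
  keep <- setdiff(names(sgn), ambiguous)
  SignedGeneSet(keep, as.integer(sgn[keep]),
                provenance = c(trait = table@traitName,
                               method = paste(unique(r$method),
                                              collapse = "+"),
                               fdr = as.character(fdrLevel)))
}

#' Merge gene calls from two methods
#'
#' Union of two signed sets; a gene called with opposite signs by the two
#' methods is contradictory and is excluded with a warning.
#'
#' @param a,b [SignedGeneSet-class] objects.
#' @return the merged [SignedGeneSet-class].
#' @export
mergeMethodCalls <- function(a, b) {
  sa <- geneSigns(a); sb <- geneSigns(b)
  common <- intersect(names(sa), names(sb))
  conflict <- common[sa[common] != sb[common]]
  if (length(conflict))
    warning(length(conflict), " gene(s) called with opposite signs by the ",
            "two methods excluded: ",
            paste(head(conflict, 5L), collapse = ", "))
  merged <- c(sa, sb[setdiff(names(sb), names(sa))])
  merged <- merged[setdiff(names(merged), conflict)]
  SignedGeneSet(names(merged), as.integer(merged),
                provenance = c(provenance(a),
                               merged_with = paste(provenance(b),
                                                   collapse = ",")))
}
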