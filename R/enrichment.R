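# Fisher-exact enrichment of a query gene set against an annotation library
# (GO terms, transcription-factor target sets) over an explicit background.

#' Fisher-exact enrichment against an annotation library
#'
#' For each term, builds the 2x2 table (in query x in term) over the
#' `background` universe, computes the two-sided Fisher exact p-value
#' (minimum-likelihood-sum convention) and the sample odds ratio ad/bc,
#' then controls the FDR across terms with [bkyFdr()]. The background is
#' the set of investigated genes — the genes that could have been called —
#' not the genome; term gene lists are intersected with it before testing.
#'
#' @param query character vector of genes (must be a subset of
#'   `background`).
#' @param library named list of term gene vectors (as from [readGmt()]).
#' @param background character vector: the investigated-gene universe.
#' @param fdr FDR level for the q-values (default 0.05).
#' @param haldane if TRUE, add 0.5 to every cell for the odds-ratio display
#'   when any cell is zero (p-values are never corrected).
#' @return data.frame: one row per term with counts, `odds_ratio`, `p`,
#'   `q`, sorted by p.
#' @export
fisherEnrichment <- function(query, library, background, fdr = 0.05,
                             haldane = FALSE) {
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query set")
  if (!all(query %in% background))
    stop("query genes outside the background: ",
         paste(head(setdiff(query, background), 5L), collapse = ", "))
  rows <- lapply(names(library), function(term) {
    tg <- intersect(library[[term]], background)
    a <- length(intersect(query, tg))
    b <- length(query) - a
    cc <- length(tg) - a
    d <- length(background) - a - b - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L),
                            alternative = "two.sided")$p.value
    or <- if (haldane && (a == 0 || b == 0 || cc == 0 || d == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else if (b == 0 || cc == 0) NA_real_
    else (a * d) / (b * cc)
    data.frame(term = term, query_hits = a, query_size = length(query),
               term_size = length(tg), background_size = length(background),
               odds_ratio = or, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bkyFdr(out$p, fdr)$q_values
  out[order(out$p), , drop = FALSE]
}
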