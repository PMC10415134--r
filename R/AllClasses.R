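#' @import methods
#' @useDynLib lifecon, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor pt rnorm runif rbinom sd setNames complete.cases
#'   binom.test fisher.test t.test wilcox.test p.adjust
#' @importFrom utils read.delim write.table packageVersion head
NULL

# ---------------------------------------------------------------------------
# SignedGeneSet
# ---------------------------------------------------------------------------

#' Signed gene set
#'
#' A set of genes each carrying a direction of association (+1 or -1) with a
#' trait, e.g. genes positively/negatively correlated with maximum lifespan,
#' or genes up/down-regulated with age. All concordance analyses operate on
#' pairs of these.
#'
#' @slot genes character vector of unique gene identifiers (opaque,
#'   case-sensitive strings).
#' @slot signs integer vector of +1/-1, parallel to `genes`.
#' @slot provenance named character vector of free-text labels
#'   (e.g. trait, tissue, method, fdr level).
#'
#' @exportClass SignedGeneSet
setClass("SignedGeneSet",
  representation(genes = "character", signs = "integer",
                 provenance = "character"))

setValidity("SignedGeneSet", function(object) {
  if (length(object@genes) != length(object@signs))
    return("genes and signs must have equal length")
  if (anyDuplicated(object@genes))
    return("duplicate gene ids in SignedGeneSet")
  if (length(object@signs) && !all(object@signs %in% c(-1L, 1L)))
    return("signs must be +1 or -1")
  TRUE
})

#' Construct a SignedGeneSet
#'
#' @param genes character vector of gene ids.
#' @param signs numeric/integer vector of +1/-1, or a character vector with
#'   tokens `+`, `-`, `+1`, `-1`.
#' @param provenance named character vector of labels.
#' @return a [SignedGeneSet-class] object.
#' @examples
#' SignedGeneSet(c("g1", "g2"), c(1, -1))
#' @export
SignedGeneSet <- function(genes = character(), signs = integer(),
                          provenance = character()) {
  if (is.character(signs)) signs <- parseSignTokens(signs)
  new("SignedGeneSet", genes = as.character(genes),
      signs = as.integer(signs), provenance = provenance)
}

parseSignTokens <- function(x) {
  out <- ifelse(x %in% c("+", "+1", "1"), 1L,
                ifelse(x %in% c("-", "-1"), -1L, NA_integer_))
  if (anyNA(out))
    stop("unknown sign token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

# ---------------------------------------------------------------------------
# MotifModel
# ---------------------------------------------------------------------------

#' Transcription-factor binding motif model
#'
#' A position frequency matrix converted to per-position base probabilities
#' (after adding a pseudocount) together with a background base composition
#' and the derived log2 odds matrix used for scanning.
#'
#' @slot motifId motif identifier (e.g. a JASPAR accession).
#' @slot tfName transcription factor name, possibly empty.
#' @slot frequencies 4 x width matrix of probabilities, rows A,C,G,T; each
#'   column sums to 1.
#' @slot background length-4 probability vector (A,C,G,T), sums to 1.
#' @slot logOdds 4 x width matrix, `log2(frequencies / background)` in bits.
#'
#' @exportClass MotifModel
setClass("MotifModel",
  representation(motifId = "character", tfName = "character",
                 frequencies = "matrix", background = "numeric",
                 logOdds = "matrix"))

setValidity("MotifModel", function(object) {
  f <- object@frequencies
  if (nrow(f) != 4L) return("frequencies must have 4 rows (A,C,G,T)")
  if (ncol(f) < 1L) return("motif width must be >= 1")
  if (any(abs(colSums(f) - 1) > 1e-9))
    return("frequency columns must each sum to 1")
  if (abs(sum(object@background) - 1) > 1e-9)
    return("background must sum to 1")
  if (!identical(dim(f), dim(object@logOdds)))
    return("logOdds and frequencies dimensions differ")
  lo <- log2(f / object@background)
  if (any(abs(lo[is.finite(lo)] - object@logOdds[is.finite(lo)]) > 1e-6))
    return("logOdds inconsistent with frequencies/background")
  TRUE
})

#' Construct a MotifModel from a count (PFM) or probability matrix
#'
#' Counts are converted to probabilities column-wise after adding
#' `pseudocount` to every cell; log-odds are taken against `background`.
#'
#' @param motifId motif identifier.
#' @param counts 4 x width numeric matrix of non-negative counts (rows
#'   A,C,G,T) or probabilities.
#' @param pseudocount non-negative value added to each cell before column
#'   normalization. Default 0.01, small enough to be below the count
#'   resolution of curated matrices while avoiding -Inf log-odds.
#' @param background length-4 base probability vector (A,C,G,T).
#' @param tfName optional transcription factor name.
#' @return a [MotifModel-class] object.
#' @examples
#' m <- MotifModel("M1", matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 0)
#' motifWidth(m)
#' @export
MotifModel <- function(motifId, counts, pseudocount = 0.01,
                       background = rep(0.25, 4), tfName = character()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)")
  if (any(counts < 0)) stop("negative counts in motif ", motifId)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive probabilities")
  background <- background / sum(background)
  freq <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  if (any(!is.finite(freq)))
    stop("motif ", motifId, " has an all-zero column and zero pseudocount")
  dimnames(freq) <- list(c("A", "C", "G", "T"), NULL)
  lo <- log2(freq / background)
  new("MotifModel", motifId = as.character(motifId),
      tfName = as.character(tfName), frequencies = freq,
      background = as.numeric(background), logOdds = lo)
}

# ---------------------------------------------------------------------------
# AssociationTable
# ---------------------------------------------------------------------------

#' Per-gene trait association results
#'
#' One record per (gene, method) with the test statistic (Spearman rho or
#' PGLS slope), raw and FDR-adjusted p-values, the number of species used,
#' and the association sign.
#'
#' @slot records data.frame with columns `gene`, `method`, `statistic`,
#'   `p_value`, `q_value`, `n_species`, `sign` (and optionally
#'   `sign_conflict` for ensemble fits).
#' @slot traitName trait the genes were tested against (e.g. "mls").
#' @slot fdrMethod multiple-testing method used for `q_value`.
#' @slot fdrLevel nominal FDR level used for calling.
#'
#' @exportClass AssociationTable
setClass("AssociationTable",
  representation(records = "data.frame", traitName = "character",
                 fdrMethod = "character", fdrLevel = "numeric"))

setValidity("AssociationTable", function(object) {
  need <- c("gene", "method", "statistic", "p_value", "q_value",
            "n_species", "sign")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  r <- object@records
  if (nrow(r)) {
    if (anyDuplicated(paste(r$gene, r$method)))
      return("more than one record per (gene, method)")
    ok <- is.finite(r$p_value)
    if (any(r$p_value[ok] < 0 | r$p_value[ok] > 1))
      return("p_value outside [0,1]")
  }
  TRUE
})

#' Construct an AssociationTable
#' @param records data.frame of per-gene association records.
#' @param traitName,fdrMethod,fdrLevel metadata strings / level.
#' @return an [AssociationTable-class] object.
#' @export
AssociationTable <- function(records, traitName = "mls",
                             fdrMethod = "BKY", fdrLevel = 0.10) {
  new("AssociationTable", records = as.data.frame(records),
      traitName = traitName, fdrMethod = fdrMethod, fdrLevel = fdrLevel)
}

# ---------------------------------------------------------------------------
# LifespanExperiment
# ---------------------------------------------------------------------------

#' Cross-species expression experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assay is a genes x
#' species matrix of (SVA-corrected) log2 TPM values with `NA` marking
#' missing species/gene measurements, and whose `colData` carries the species
#' trait table (maximum lifespan in years, optionally body weight and
#' sexual-maturity age).
#'
#' @exportClass LifespanExperiment
setClass("LifespanExperiment", contains = "SummarizedExperiment")

setValidity("LifespanExperiment", function(object) {
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("gene (row) and species (column) names are required")
  if (anyDuplicated(rownames(object))) return("duplicate gene ids")
  if (anyDuplicated(colnames(object))) return("duplicate species ids")
  cd <- SummarizedExperiment::colData(object)
  if ("mls_years" %in% names(cd)) {
    m <- cd$mls_years
    if (any(!is.na(m) & m <= 0)) return("mls_years must be positive")
  }
  TRUE
})

#' Construct a LifespanExperiment
#'
#' @param expr numeric matrix, genes x species, `NA` = missing.
#' @param species optional data.frame of species traits with a `species_id`
#'   column matching `colnames(expr)`; typically includes `mls_years`.
#' @return a [LifespanExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' sp <- data.frame(species_id = colnames(m), mls_years = c(4, 20, 80))
#' le <- LifespanExperiment(m, sp)
#' mlsYears(le)
#' @export
LifespanExperiment <- function(expr, species = NULL) {
  expr <- as.matrix(expr)
  if (is.null(species)) {
    cd <- S4Vectors::DataFrame(species_id = colnames(expr),
                               row.names = colnames(expr))
  } else {
    species <- as.data.frame(species)
    if (!"species_id" %in% names(species))
      stop("species table needs a species_id column")
    if (anyDuplicated(species$species_id))
      stop("duplicate species_id in species table")
    missingSp <- setdiff(colnames(expr), species$species_id)
    if (length(missingSp))
      stop("species absent from trait table: ",
           paste(missingSp, collapse = ", "))
    species <- species[match(colnames(expr), species$species_id), ,
                       drop = FALSE]
    cd <- S4Vectors::DataFrame(species, row.names = colnames(expr))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2tpm = expr), colData = cd)
  new("LifespanExperiment", se)
}
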