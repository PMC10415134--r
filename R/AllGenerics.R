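# Accessors and show methods for the package's S4 classes.

#' @describeIn SignedGeneSet-class gene identifiers.
#' @param object,x a SignedGeneSet (or MotifModel where noted).
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @describeIn SignedGeneSet-class named integer vector of +1/-1 signs.
#' @export
setGeneric("geneSigns", function(object) standardGeneric("geneSigns"))

#' @describeIn SignedGeneSet-class provenance labels.
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @export
setMethod("geneIds", "SignedGeneSet", function(object) object@genes)

#' @export
setMethod("geneSigns", "SignedGeneSet", function(object)
  setNames(object@signs, object@genes))

#' @export
setMethod("provenance", "SignedGeneSet", function(object) object@provenance)

#' @export
setMethod("length", "SignedGeneSet", function(x) length(x@genes))

setMethod("show", "SignedGeneSet", function(object) {
  cat("SignedGeneSet with", length(object@genes), "genes (",
      sum(object@signs == 1L), "positive,", sum(object@signs == -1L),
      "negative )\n")
  if (length(object@provenance))
    cat("provenance:",
        paste(names(object@provenance), object@provenance,
              sep = "=", collapse = "; "), "\n")
})

#' Restrict a SignedGeneSet to a gene universe
#' @param object a SignedGeneSet.
#' @param universe character vector of gene ids to keep.
#' @return a SignedGeneSet containing only genes in `universe`.
#' @export
restrictToUniverse <- function(object, universe) {
  keep <- object@genes %in% universe
  SignedGeneSet(object@genes[keep], object@signs[keep], object@provenance)
}

# --- MotifModel -----------------------------------------------------------

#' @describeIn MotifModel-class motif width (number of columns).
#' @param object a MotifModel.
#' @export
setGeneric("motifWidth", function(object) standardGeneric("motifWidth"))

#' @export
setMethod("motifWidth", "MotifModel",
          function(object) ncol(object@frequencies))

#' @describeIn MotifModel-class 4 x width log2-odds scoring matrix (bits).
#' @export
setGeneric("motifLogOdds", function(object) standardGeneric("motifLogOdds"))

#' @export
setMethod("motifLogOdds", "MotifModel", function(object) object@logOdds)

#' @describeIn MotifModel-class background base probabilities (A,C,G,T).
#' @export
setGeneric("motifBackground",
           function(object) standardGeneric("motifBackground"))

#' @export
setMethod("motifBackground", "MotifModel", function(object) object@background)

setMethod("show", "MotifModel", function(object) {
  cat("MotifModel", object@motifId,
      if (length(object@tfName)) paste0("(", object@tfName, ")") else "",
      "width", ncol(object@frequencies), "\n")
})

#' Consensus sequence of a motif
#'
#' The highest-probability base at each position (ties broken in A,C,G,T
#' order). Used by the promoter simulator to plant unambiguous occurrences.
#'
#' @param motif a MotifModel.
#' @return a single character string over ACGT.
#' @export
motifConsensus <- function(motif) {
  paste(rownames(motif@frequencies)[apply(motif@frequencies, 2, which.max)],
        collapse = "")
}

# --- AssociationTable -----------------------------------------------------

#' @describeIn AssociationTable-class the per-gene records data.frame.
#' @param object an AssociationTable.
#' @export
setGeneric("associationRecords",
           function(object) standardGeneric("associationRecords"))

#' @export
setMethod("associationRecords", "AssociationTable",
          function(object) object@records)

#' @describeIn AssociationTable-class nominal FDR level.
#' @export
setGeneric("fdrLevel", function(object) standardGeneric("fdrLevel"))

#' @export
setMethod("fdrLevel", "AssociationTable", function(object) object@fdrLevel)

setMethod("show", "AssociationTable", function(object) {
  r <- object@records
  cat("AssociationTable:", nrow(r), "records, trait", object@traitName,
      ", FDR", object@fdrMethod, "at", object@fdrLevel, "\n")
  for (m in unique(r$method))
    cat("  ", m, ": ", sum(r$method == m), " genes tested, ",
        sum(r$method == m & !is.na(r$q_value) &
              r$q_value < object@fdrLevel), " called\n", sep = "")
})

# --- LifespanExperiment ---------------------------------------------------

#' @describeIn LifespanExperiment-class genes x species expression matrix
#'   (log2 TPM, NA = missing).
#' @param object a LifespanExperiment.
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @export
setMethod("exprValues", "LifespanExperiment", function(object)
  SummarizedExperiment::assay(object, "log2tpm"))

#' @describeIn LifespanExperiment-class species trait table as a data.frame.
#' @export
setGeneric("speciesInfo", function(object) standardGeneric("speciesInfo"))

#' @export
setMethod("speciesInfo", "LifespanExperiment", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

#' @describeIn LifespanExperiment-class named vector of maximum lifespans
#'   (years).
#' @export
setGeneric("mlsYears", function(object) standardGeneric("mlsYears"))

#' @export
setMethod("mlsYears", "LifespanExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"mls_years" %in% names(cd))
    stop("no mls_years column in species data")
  setNames(cd$mls_years, rownames(cd))
})
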