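# Readers and writers for the external formats the pipeline touches:
# expression TSV, Newick tree ensembles, JASPAR PFM text, promoter FASTA,
# signed gene set TSV, GMT annotation libraries. Plus tree utilities
# (pruning, Brownian-motion covariance).

tsvHeaderComment <- function(params = character()) {
  paste0("# lifecon ", as.character(utils::packageVersion("lifecon")),
         if (length(params))
           paste0(" | ", paste(names(params), params, sep = "=",
                               collapse = " ")) else "")
}

#' Read a genes x species expression table
#'
#' Expects a TSV whose header row holds species ids and whose first column
#' holds gene ids; empty cells or `NA` denote missing measurements. Values
#' are assumed to be on a log2 (e.g. SVA-corrected log2 TPM) scale already;
#' no normalization is applied.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes x species, with `NA` for missing entries.
#'   Row/column order follows the file.
#' @export
readExpressionTsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 2L) stop("expression table needs gene column + species")
  genes <- tab[[1L]]
  speciesIds <- colnames(tab)[-1L]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s) in expression table: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(speciesIds))
    stop("duplicate species id(s) in expression table")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  vals[vals == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- !is.na(vals) & vals != "NA" & is.na(num)
  if (any(bad))
    stop("non-numeric expression value(s), e.g. ",
         vals[which(bad)[1L]])
  dimnames(num) <- list(genes, speciesIds)
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpressionTsv()]; missing entries are written as `NA`.
#' A comment line records the tool version.
#'
#' @param expr numeric matrix with gene rownames and species colnames.
#' @param path output path.
#' @param params optional named character vector recorded in the header
#'   comment.
#' @export
writeExpressionTsv <- function(expr, path, params = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsvHeaderComment(params), con)
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

#' Read a species trait table
#'
#' TSV with columns `species_id`, `mls_years` and optionally
#' `body_weight_g`, `sexual_maturity_days`, `order_name`.
#'
#' @param path path to the TSV.
#' @return data.frame, one row per species.
#' @export
readSpeciesTable <- function(path) {
  sp <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
  if (!all(c("species_id", "mls_years") %in% names(sp)))
    stop("species table needs species_id and mls_years columns")
  if (anyDuplicated(sp$species_id)) stop("duplicate species_id")
  if (any(!is.na(sp$mls_years) & sp$mls_years <= 0))
    stop("mls_years must be positive")
  sp
}

#' Write a species trait table
#' @param species data.frame with at least `species_id`, `mls_years`.
#' @param path output path.
#' @export
writeSpeciesTable <- function(species, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsvHeaderComment(), con)
  suppressWarnings(utils::write.table(species, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read an ensemble of Newick trees
#'
#' One semicolon-terminated Newick string per non-blank line. All trees must
#' be over the same leaf set; an ensemble of candidate phylogenies is used to
#' propagate phylogenetic uncertainty into PGLS p-values.
#'
#' @param path path to the Newick file.
#' @return an [ape::multiPhylo] object.
#' @export
readNewickEnsemble <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no trees in ", path)
  trees <- lapply(seq_along(lines), function(i) {
    tr <- tryCatch(ape::read.tree(text = lines[[i]]),
                   error = function(e) NULL)
    if (is.null(tr)) stop("unparsable Newick on line ", i)
    tr
  })
  leafSets <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(leafSets))
    if (!identical(leafSets[[i]], leafSets[[1L]]))
      stop("tree on line ", i, " has a different leaf set")
  class(trees) <- "multiPhylo"
  trees
}

#' Write a tree ensemble as one Newick string per line
#' @param trees a `multiPhylo` or list of `phylo` objects.
#' @param path output path.
#' @export
writeNewickEnsemble <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, function(t) ape::write.tree(t), character(1)),
             path)
  invisible(path)
}

#' Prune a tree to a subset of species
#'
#' Drops all other tips and collapses the resulting degree-2 internal nodes,
#' summing branch lengths, so root-to-tip path lengths (and hence all shared
#' path lengths among the retained leaves) are preserved exactly.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (>= 3).
#' @return the pruned `phylo`.
#' @export
pruneTree <- function(tree, keep) {
  keep <- unique(as.character(keep))
  if (!all(keep %in% tree$tip.label))
    stop("species not in tree: ",
         paste(setdiff(keep, tree$tip.label), collapse = ", "))
  if (length(keep) < 3L) stop("need at least 3 species to prune to")
  ape::keep.tip(tree, keep)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Under Brownian motion on the tree, the covariance between the tip values
#' of species i and j is (proportional to) the shared branch length from the
#' root to their most recent common ancestor; the variance of tip i is its
#' root-to-tip distance.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param speciesOrder optional character vector (subset of tips) giving the
#'   row/column order of the result; defaults to the tree's tip order.
#' @return symmetric positive semidefinite matrix with species dimnames.
#' @export
phyloCovariance <- function(tree, speciesOrder = NULL) {
  V <- ape::vcv(tree)
  if (!is.null(speciesOrder)) {
    speciesOrder <- as.character(speciesOrder)
    bad <- setdiff(speciesOrder, rownames(V))
    if (length(bad))
      stop("species not in tree: ", paste(bad, collapse = ", "))
    V <- V[speciesOrder, speciesOrder, drop = FALSE]
  }
  V
}

#' Read JASPAR-style PFM motif records
#'
#' Parses JASPAR 2020-style text: a `>ID NAME` header followed by four count
#' rows (A, C, G, T), with or without the `A [ ... ]` bracket decoration.
#'
#' @param path path to the PFM text file.
#' @inheritParams MotifModel
#' @return a list of [MotifModel-class] objects, in file order, named by
#'   motif id.
#' @export
readJasparPfm <- function(path, pseudocount = 0.01,
                          background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif records (no '>' headers) in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  motifs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    bits <- strsplit(hdr, "\\s+")[[1L]]
    id <- bits[1L]
    nm <- if (length(bits) > 1L) bits[2L] else character()
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 4L)
      stop("motif ", id, ": expected 4 count rows, got ", length(body))
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", "", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
      if (anyNA(v)) stop("motif ", id, ": non-numeric count row")
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("motif ", id, ": count rows of unequal width")
    counts <- do.call(rbind, rows)
    if (any(counts < 0)) stop("motif ", id, ": negative counts")
    motifs[[k]] <- MotifModel(id, counts, pseudocount = pseudocount,
                              background = background, tfName = nm)
  }
  names(motifs) <- vapply(motifs, function(m) m@motifId, character(1))
  motifs
}

#' Read promoter sequences from FASTA
#'
#' Headers follow the convention `geneID|speciesID` (this pipeline's own
#' convention for keying promoters by gene and species). Sequences are
#' uppercased and must be valid IUPAC DNA; scanning later treats any
#' non-ACGT code as N.
#'
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet] named `gene|species`.
#' @export
readFastaPromoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA header(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  up <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(up) <- names(seqs)
  up
}

#' Write promoter sequences to FASTA
#' @param seqs named character vector or DNAStringSet, names `gene|species`.
#' @param path output path.
#' @export
writeFastaPromoters <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Split `gene|species` promoter names
#' @param x character vector of promoter names.
#' @return data.frame with columns `gene`, `species`.
#' @export
splitPromoterNames <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("promoter names must follow 'gene|species'")
  data.frame(gene = vapply(parts, `[`, "", 1L),
             species = vapply(parts, `[`, "", 2L))
}

#' Read a signed gene set from TSV
#'
#' Columns `gene_id` and `sign` (tokens `+`, `-`, `+1`, `-1`). A gene listed
#' with both signs is contradictory and is dropped with a warning, mirroring
#' the exclusion of genes flagged in opposite directions by different
#' microarray probes in lifespan-association studies.
#'
#' @param path TSV path.
#' @param provenance optional named character vector of labels.
#' @return a [SignedGeneSet-class].
#' @export
readSignedGeneSet <- function(path, provenance = character()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character")
  if (!all(c("gene_id", "sign") %in% names(tab)))
    stop("signed gene set needs gene_id and sign columns")
  signs <- parseSignTokens(tab$sign)
  agg <- tapply(signs, tab$gene_id, function(s) length(unique(s)))
  conflicted <- names(agg)[agg > 1L]
  if (length(conflicted))
    warning(length(conflicted),
            " gene(s) listed with both signs dropped: ",
            paste(head(conflicted, 5L), collapse = ", "))
  keep <- !(tab$gene_id %in% conflicted) & !duplicated(tab$gene_id)
  SignedGeneSet(tab$gene_id[keep], signs[keep], provenance)
}

#' Write a signed gene set as TSV
#' @param set a SignedGeneSet.
#' @param path output path.
#' @export
writeSignedGeneSet <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsvHeaderComment(provenance(set)), con)
  writeLines("gene_id\tsign", con)
  if (length(set))
    writeLines(paste(geneIds(set),
                     ifelse(geneSigns(set) > 0, "+1", "-1"), sep = "\t"),
               con)
  invisible(path)
}

#' Read a GMT annotation library
#'
#' Tab-separated: term, description, then member genes. Used for
#' Fisher-exact enrichment against e.g. transcription-factor target
#' libraries.
#'
#' @param path GMT path.
#' @return named list of character vectors (term -> genes).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT term ", f[1L], " has no genes")
    out[[f[1L]]] <- genes
  }
  out
}

#' Write a GMT annotation library
#' @param library named list of gene vectors.
#' @param path output path.
#' @export
writeGmt <- function(library, path) {
  writeLines(vapply(names(library), function(nm)
    paste(c(nm, nm, library[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}
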