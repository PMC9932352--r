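#' @include go-ontology.R
NULL

.G2G_COLUMNS <- c("tax_id", "GeneID", "GO_ID", "Evidence", "Qualifier",
                  "GO_term", "PubMed", "Category")

# build the bidirectional maps from a (gene, term) pair data.frame
.annotationSetFromPairs <- function(gene, term, propagated, taxon) {
  key <- paste(gene, term, sep = "\r")
  keep <- !duplicated(key)
  gene <- gene[keep]; term <- term[keep]
  g2t <- split(term, gene)
  t2g <- split(gene, term)
  new("AnnotationSet",
      geneToTerms = lapply(g2t, unique),
      termToGenes = lapply(t2g, unique),
      propagated = propagated,
      taxon = as.integer(taxon))
}

#' Read NCBI gene2go annotations for one taxon
#'
#' Parses the tab-separated NCBI gene2go format (columns `#tax_id`,
#' `GeneID`, `GO_ID`, `Evidence`, `Qualifier`, `GO_term`, `PubMed`,
#' `Category`; a leading `#` on the header is tolerated; plain or
#' gzip-compressed). Only rows for the requested taxon are kept; rows whose
#' qualifier contains `NOT` are excluded rather than treated as negative
#' evidence, following standard over-representation practice; duplicate
#' (gene, term) pairs from multiple evidence lines collapse to one.
#'
#' @param path path to a gene2go file (optionally `.gz`).
#' @param taxon NCBI taxonomy id to keep; default 9606 (human).
#' @return An [AnnotationSet-class] with `propagated = FALSE`. Gene ids are
#'   Entrez GeneIDs kept as character strings.
#' @export
readGene2go <- function(path, taxon = 9606) {
  if (!file.exists(path)) {
    stop("gene2go file not found: ", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df)[1L] <- sub("^[#X.]+", "", names(df)[1L])
  missing <- setdiff(.G2G_COLUMNS, names(df))
  if (length(missing)) {
    stop("gene2go file lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[df$tax_id == as.character(taxon), , drop = FALSE]
  if (!nrow(df)) {
    stop("no annotation rows for taxon ", taxon, " in ", path)
  }
  df <- df[!grepl("NOT", df$Qualifier, fixed = TRUE), , drop = FALSE]
  if (!nrow(df)) {
    stop("all rows for taxon ", taxon, " are NOT-qualified")
  }
  .annotationSetFromPairs(df$GeneID, df$GO_ID,
                          propagated = FALSE, taxon = taxon)
}

#' Propagate annotations to ancestor terms
#'
#' Extends every gene's direct annotations to all ancestors of its terms
#' (the true-path rule), so that a gene annotated to a specific term also
#' counts for every more general term above it. By default only `is_a`
#' parentage is followed, the universally safe relation; set
#' `partOf = TRUE` to also follow `part_of`. Propagation never changes the
#' set of annotated genes, only adds terms, and is idempotent: propagating
#' an already-closed set returns it unchanged.
#'
#' @param ann an [AnnotationSet-class] with `propagated = FALSE`.
#' @param dag the [OntologyDAG-class] the term ids live in.
#' @param partOf also follow `part_of` edges (default FALSE).
#' @return A propagated [AnnotationSet-class].
#' @export
propagateAnnotations <- function(ann, dag, partOf = FALSE) {
  stopifnot(is(ann, "AnnotationSet"), is(dag, "OntologyDAG"))
  if (ann@propagated) {
    stop("annotation set is already propagated")
  }
  usedTerms <- names(ann@termToGenes)
  canon <- vapply(usedTerms, function(t) resolveTerm(dag, t), character(1))
  relations <- if (partOf) c("is_a", "part_of") else "is_a"
  anc <- .allAncestors(dag, relations)
  closureOf <- stats::setNames(
    lapply(seq_along(usedTerms),
           function(i) unique(c(canon[[i]], anc[[canon[[i]]]]))),
    usedTerms)
  gene <- rep(names(ann@geneToTerms), lengths(ann@geneToTerms))
  term <- unlist(ann@geneToTerms, use.names = FALSE)
  expanded <- closureOf[term]
  geneRep <- rep(gene, lengths(expanded))
  termRep <- unlist(expanded, use.names = FALSE)
  out <- .annotationSetFromPairs(geneRep, termRep,
                                 propagated = TRUE, taxon = ann@taxon)
  stopifnot(length(out@geneToTerms) == length(ann@geneToTerms))
  out
}

#' Genes annotated to a term, within a universe
#'
#' @param ann an [AnnotationSet-class].
#' @param termId a GO term id.
#' @param universe character vector of gene ids to intersect with.
#' @return Character vector of annotated genes in the universe; an unknown
#'   term yields an empty set, not an error.
#' @export
genesForTerm <- function(ann, termId, universe) {
  stopifnot(is(ann, "AnnotationSet"))
  g <- ann@termToGenes[[termId]]
  if (is.null(g)) character(0) else intersect(g, universe)
}
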