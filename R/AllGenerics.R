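#' @include AllClasses.R
NULL

#' Accessors for expression tables and derived objects
#'
#' `geneIds()` returns gene identifiers, `foldChanges()` the log2 fold
#' changes, `pValues()` the p-values, `sourceLabel()` the dataset label and
#' `nGenes()` the number of genes. On classified tables, `expressionClass()`
#' returns the per-gene class factor, `negLog10P()` the volcano y
#' coordinates and `alphaThreshold()` the significance threshold used.
#'
#' @param x an [ExpressionTable-class] or [ClassifiedTable-class] object.
#' @return A vector of the requested per-gene values (or a scalar for
#'   `sourceLabel`, `nGenes`, `alphaThreshold`).
#' @name expression-accessors
#' @examples
#' tab <- ExpressionTable(c("G1", "G2"), c(1.5, -0.2), c(0.01, 0.5))
#' geneIds(tab)
#' nGenes(tab)
NULL

#' @rdname expression-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname expression-accessors
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))
#' @rdname expression-accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname expression-accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))
#' @rdname expression-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @rdname expression-accessors
#' @export
setGeneric("expressionClass", function(x) standardGeneric("expressionClass"))
#' @rdname expression-accessors
#' @export
setGeneric("negLog10P", function(x) standardGeneric("negLog10P"))
#' @rdname expression-accessors
#' @export
setGeneric("alphaThreshold", function(x) standardGeneric("alphaThreshold"))

#' @rdname expression-accessors
setMethod("geneIds", "ExpressionTable", function(x) x@geneId)
#' @rdname expression-accessors
setMethod("foldChanges", "ExpressionTable", function(x) x@logFC)
#' @rdname expression-accessors
setMethod("pValues", "ExpressionTable", function(x) x@pValue)
#' @rdname expression-accessors
setMethod("sourceLabel", "ExpressionTable", function(x) x@sourceLabel)
#' @rdname expression-accessors
setMethod("nGenes", "ExpressionTable", function(x) length(x@geneId))
#' @rdname expression-accessors
setMethod("expressionClass", "ClassifiedTable", function(x) x@expressionClass)
#' @rdname expression-accessors
setMethod("negLog10P", "ClassifiedTable", function(x) x@negLog10P)
#' @rdname expression-accessors
setMethod("alphaThreshold", "ClassifiedTable", function(x) x@alpha)

#' Coerce expression tables to data.frame
#'
#' @param x table object.
#' @param row.names,optional,... passed for interface compatibility; unused.
#' @return data.frame with columns `GeneID`, `log2FC`, `pvalue` and, for
#'   classified tables, `expression_class` and `neg_log10_p`.
#' @export
setMethod("as.data.frame", "ExpressionTable",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(GeneID = x@geneId, log2FC = x@logFC, pvalue = x@pValue,
               stringsAsFactors = FALSE)
  })

#' @rdname as.data.frame-ExpressionTable-method
#' @export
setMethod("as.data.frame", "ClassifiedTable",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(GeneID = x@geneId, log2FC = x@logFC, pvalue = x@pValue,
               expression_class = as.character(x@expressionClass),
               neg_log10_p = x@negLog10P,
               stringsAsFactors = FALSE)
  })

setMethod("show", "ExpressionTable", function(object) {
  cat("ExpressionTable with", length(object@geneId), "genes",
      if (nzchar(object@sourceLabel))
        paste0("[", object@sourceLabel, "]") else "", "\n")
  cat("  logFC range:",
      paste(signif(range(object@logFC), 3), collapse = " .. "), "\n")
})

setMethod("show", "ClassifiedTable", function(object) {
  cat("ClassifiedTable with", length(object@geneId),
      "genes (alpha =", object@alpha, ")\n")
  print(table(object@expressionClass))
})

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG with", nrow(object@terms), "terms\n")
  print(table(object@terms$namespace))
  cat(" ", length(object@obsoleteIds), "obsolete,",
      length(object@altIds), "alt ids\n")
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@geneToTerms), "genes,",
      length(object@termToGenes), "terms, taxon", object@taxon,
      if (object@propagated) "(propagated)" else "(direct)", "\n")
})

setMethod("show", "EnrichmentRun", function(object) {
  cat("EnrichmentRun:", nrow(object@results), "term results in",
      nrow(unique(object@results[, c("direction", "namespace")])),
      "group(s); universe", object@universeSize, "genes\n")
})

setMethod("show", "MergedTable", function(object) {
  cat("MergedTable:", nrow(object@rows), "common genes;",
      length(object@onlyIn1), "only in dataset 1;",
      length(object@onlyIn2), "only in dataset 2\n")
})

#' Accessors for ontology, annotation, enrichment and comparison objects
#'
#' @param x the object.
#' @return `ontologyTerms()`: the term data.frame of an [OntologyDAG-class].
#'   `enrichmentResults()`: the result data.frame of an
#'   [EnrichmentRun-class]. `mergedRows()`: the per-gene data.frame of a
#'   [MergedTable-class]. `onlyIn()`: gene ids specific to dataset 1 or 2.
#'   `isPropagated()`: whether an [AnnotationSet-class] is
#'   ancestor-propagated.
#' @name object-accessors
NULL

#' @rdname object-accessors
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))
#' @rdname object-accessors
setMethod("ontologyTerms", "OntologyDAG", function(x) x@terms)

#' @rdname object-accessors
#' @export
setGeneric("enrichmentResults",
           function(x) standardGeneric("enrichmentResults"))
#' @rdname object-accessors
setMethod("enrichmentResults", "EnrichmentRun", function(x) x@results)

#' @rdname object-accessors
#' @export
setGeneric("mergedRows", function(x) standardGeneric("mergedRows"))
#' @rdname object-accessors
setMethod("mergedRows", "MergedTable", function(x) x@rows)

#' @rdname object-accessors
#' @param which 1 or 2: which dataset's specific genes to return.
#' @export
setGeneric("onlyIn", function(x, which) standardGeneric("onlyIn"))
#' @rdname object-accessors
setMethod("onlyIn", "MergedTable", function(x, which) {
  stopifnot(which %in% c(1L, 2L))
  if (which == 1L) x@onlyIn1 else x@onlyIn2
})

#' @rdname object-accessors
#' @export
setGeneric("isPropagated", function(x) standardGeneric("isPropagated"))
#' @rdname object-accessors
setMethod("isPropagated", "AnnotationSet", function(x) x@propagated)
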