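#' @import methods
NULL

#' Expression class labels
#'
#' The three expression classes a gene can be assigned, in the fixed axis
#' order used throughout the package (contingency tables, factor levels,
#' plot legends).
#'
#' @return Character vector of length 3.
#' @export
#' @examples
#' expressionClassLevels()
expressionClassLevels <- function() {
  c("Downregulated", "Not differentially expressed", "Upregulated")
}

#' ExpressionTable: per-gene expression statistics for one dataset
#'
#' Holds one record per gene: an opaque gene identifier, a log2 fold change
#' and a p-value in \[0, 1\]. Gene identifiers must be unique and non-empty;
#' a table is never empty after validation.
#'
#' @slot geneId character vector of unique, non-empty gene identifiers.
#' @slot logFC numeric vector of finite log2 fold changes.
#' @slot pValue numeric vector of p-values in \[0, 1\].
#' @slot sourceLabel single string naming the dataset (may be "").
#'
#' @seealso [readExpressionTable()], [classifyTable()]
#' @export
setClass("ExpressionTable",
  representation(
    geneId = "character",
    logFC = "numeric",
    pValue = "numeric",
    sourceLabel = "character"
  ),
  prototype(sourceLabel = "")
)

setValidity("ExpressionTable", function(object) {
  n <- length(object@geneId)
  msgs <- character()
  if (n == 0L) {
    msgs <- c(msgs, "table must contain at least one gene")
  }
  if (length(object@logFC) != n || length(object@pValue) != n) {
    msgs <- c(msgs, "geneId, logFC and pValue must have equal length")
  }
  if (any(!nzchar(object@geneId)) || anyNA(object@geneId)) {
    msgs <- c(msgs, "gene identifiers must be non-empty and non-NA")
  }
  if (anyDuplicated(object@geneId)) {
    dup <- unique(object@geneId[duplicated(object@geneId)])
    msgs <- c(msgs, paste0(
      "duplicate gene identifiers: ",
      paste(utils::head(dup, 5L), collapse = ", "),
      if (length(dup) > 5L) ", ..." else ""
    ))
  }
  if (length(object@logFC) == n && any(!is.finite(object@logFC))) {
    msgs <- c(msgs, "logFC values must be finite")
  }
  if (length(object@pValue) == n &&
      (anyNA(object@pValue) ||
       any(object@pValue < 0 | object@pValue > 1))) {
    msgs <- c(msgs, "p-values must lie in [0, 1]")
  }
  if (length(object@sourceLabel) != 1L) {
    msgs <- c(msgs, "sourceLabel must be a single string")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionTable
#'
#' @param geneId character vector of gene identifiers.
#' @param logFC numeric vector of log2 fold changes.
#' @param pValue numeric vector of p-values.
#' @param sourceLabel optional dataset label.
#' @return An [ExpressionTable-class] object.
#' @export
#' @examples
#' ExpressionTable(c("G1", "G2"), c(1.5, -0.2), c(0.01, 0.5))
ExpressionTable <- function(geneId, logFC, pValue, sourceLabel = "") {
  new("ExpressionTable",
      geneId = as.character(geneId),
      logFC = as.numeric(logFC),
      pValue = as.numeric(pValue),
      sourceLabel = as.character(sourceLabel))
}

#' ClassifiedTable: an ExpressionTable with expression classes
#'
#' Extends [ExpressionTable-class] with the expression class assigned under
#' a significance threshold `alpha` and the volcano-plot y coordinate
#' `-log10(max(p, 1e-300))`. Classification itself uses the raw p-value;
#' the floor applies only to the plot coordinate so that p = 0 stays finite.
#'
#' @slot expressionClass factor with levels [expressionClassLevels()].
#' @slot negLog10P numeric, `-log10(max(pValue, 1e-300))`, always >= 0.
#' @slot alpha the significance threshold the classes were derived under.
#' @export
setClass("ClassifiedTable",
  contains = "ExpressionTable",
  representation(
    expressionClass = "factor",
    negLog10P = "numeric",
    alpha = "numeric"
  )
)

setValidity("ClassifiedTable", function(object) {
  n <- length(object@geneId)
  msgs <- character()
  if (length(object@expressionClass) != n || length(object@negLog10P) != n) {
    msgs <- c(msgs, "class and coordinate vectors must match table length")
  }
  if (!identical(levels(object@expressionClass), expressionClassLevels())) {
    msgs <- c(msgs, "expressionClass must use the canonical three levels")
  }
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha <= 0 || object@alpha >= 1) {
    msgs <- c(msgs, "alpha must be a single value in (0, 1)")
  }
  if (any(object@negLog10P < 0)) {
    msgs <- c(msgs, "negLog10P must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' OntologyDAG: a parsed Gene Ontology
#'
#' Directed acyclic graph of GO terms across the three namespaces
#' (biological_process, molecular_function, cellular_component), with
#' `is_a` and `part_of` parentage kept separately. Obsolete terms are
#' indexed but excluded from queries; alternative ids resolve to their
#' canonical term.
#'
#' @slot terms data.frame with columns `term_id`, `name`, `namespace`
#'   (non-obsolete terms only).
#' @slot isAParents named list: term_id -> character vector of is_a parents.
#' @slot partOfParents named list: term_id -> part_of parents.
#' @slot altIds named character: alternative id -> canonical term_id.
#' @slot obsoleteIds character vector of obsolete term ids.
#' @seealso [parseOBO()], [termAncestors()], [resolveTerm()]
#' @export
setClass("OntologyDAG",
  representation(
    terms = "data.frame",
    isAParents = "list",
    partOfParents = "list",
    altIds = "character",
    obsoleteIds = "character"
  )
)

setValidity("OntologyDAG", function(object) {
  msgs <- character()
  need <- c("term_id", "name", "namespace")
  if (!all(need %in% names(object@terms))) {
    msgs <- c(msgs, "terms must have columns term_id, name, namespace")
  } else {
    if (anyDuplicated(object@terms$term_id)) {
      msgs <- c(msgs, "term ids must be unique")
    }
    bad <- !grepl("^GO:[0-9]{7}$", object@terms$term_id)
    if (any(bad)) {
      msgs <- c(msgs, "term ids must match GO:NNNNNNN")
    }
    ok_ns <- c("biological_process", "molecular_function",
               "cellular_component")
    if (!all(object@terms$namespace %in% ok_ns)) {
      msgs <- c(msgs, "namespace must be one of the three GO namespaces")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' AnnotationSet: gene-to-GO-term annotations
#'
#' Bidirectional gene/term maps filtered to one taxon. `propagated = TRUE`
#' means every gene's annotations are closed under ancestor propagation
#' (the true-path rule), so counting genes per term respects the DAG.
#'
#' @slot geneToTerms named list: gene id -> character vector of term ids.
#' @slot termToGenes named list: term id -> character vector of gene ids.
#' @slot propagated logical flag.
#' @slot taxon NCBI taxonomy id the annotations were filtered to.
#' @seealso [readGene2go()], [propagateAnnotations()]
#' @export
setClass("AnnotationSet",
  representation(
    geneToTerms = "list",
    termToGenes = "list",
    propagated = "logical",
    taxon = "integer"
  )
)

setValidity("AnnotationSet", function(object) {
  msgs <- character()
  if (length(object@propagated) != 1L || is.na(object@propagated)) {
    msgs <- c(msgs, "propagated must be TRUE or FALSE")
  }
  if (length(object@taxon) != 1L) {
    msgs <- c(msgs, "taxon must be a single integer")
  }
  # inverse-map consistency: same total number of (gene, term) pairs and
  # every forward pair present in the reverse map
  n_fwd <- sum(lengths(object@geneToTerms))
  n_rev <- sum(lengths(object@termToGenes))
  if (n_fwd != n_rev) {
    msgs <- c(msgs, "gene->term and term->gene maps disagree in size")
  }
  if (length(msgs)) msgs else TRUE
})

#' EnrichmentRun: over-representation results for up to six analyses
#'
#' One row per tested term per (direction, namespace) group. Columns:
#' `term_id`, `name`, `namespace`, `direction`, `k` (study genes annotated),
#' `n` (annotated study size), `K` (annotated population genes), `N`
#' (annotated population size), `p_value` (hypergeometric upper tail),
#' `fdr` (Benjamini-Hochberg within the group), `fold` ((k/n)/(K/N)) and
#' `percent` (100 * k / total genes in the direction). Rows are sorted by
#' ascending p-value within each group.
#'
#' @slot results data.frame as described above.
#' @slot alphaFdr FDR threshold attached to the run.
#' @slot universeSize number of genes in the background universe.
#' @seealso [runEnrichment()], [significantTerms()]
#' @export
setClass("EnrichmentRun",
  representation(
    results = "data.frame",
    alphaFdr = "numeric",
    universeSize = "integer"
  )
)

.enrichmentColumns <- c("term_id", "name", "namespace", "direction",
                        "k", "n", "K", "N", "p_value", "fdr", "fold",
                        "percent")

setValidity("EnrichmentRun", function(object) {
  msgs <- character()
  if (!all(.enrichmentColumns %in% names(object@results))) {
    msgs <- c(msgs, paste("results must have columns:",
                          paste(.enrichmentColumns, collapse = ", ")))
  } else if (nrow(object@results)) {
    r <- object@results
    if (any(r$k > pmin(r$n, r$K)) || any(r$n > r$N) || any(r$K > r$N)) {
      msgs <- c(msgs, "count bounds violated (need k <= min(n, K) <= N)")
    }
    if (any(r$p_value <= 0 | r$p_value > 1)) {
      msgs <- c(msgs, "p-values must lie in (0, 1]")
    }
    if (any(r$fdr < r$p_value - 1e-12)) {
      msgs <- c(msgs, "BH-adjusted values cannot fall below raw p-values")
    }
    if (any(r$percent < 0 | r$percent > 100)) {
      msgs <- c(msgs, "percent must lie in [0, 100]")
    }
    if (!all(r$direction %in% c("up", "down"))) {
      msgs <- c(msgs, "direction must be 'up' or 'down'")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' MergedTable: two classified datasets joined on common genes
#'
#' Inner join of two [ClassifiedTable-class] objects on exact gene id, plus
#' the identifiers specific to each dataset. Rows keep dataset 1's order
#' restricted to the common genes.
#'
#' @slot rows data.frame with columns `gene_id`, `log_fc_1`, `p_1`,
#'   `class_1`, `log_fc_2`, `p_2`, `class_2`.
#' @slot onlyIn1 gene ids present only in dataset 1.
#' @slot onlyIn2 gene ids present only in dataset 2.
#' @slot alpha shared significance threshold both tables were classified at.
#' @seealso [mergeDatasets()], [contingencyTable()]
#' @export
setClass("MergedTable",
  representation(
    rows = "data.frame",
    onlyIn1 = "character",
    onlyIn2 = "character",
    alpha = "numeric"
  )
)

setValidity("MergedTable", function(object) {
  msgs <- character()
  need <- c("gene_id", "log_fc_1", "p_1", "class_1",
            "log_fc_2", "p_2", "class_2")
  if (!all(need %in% names(object@rows))) {
    msgs <- c(msgs, paste("rows must have columns:",
                          paste(need, collapse = ", ")))
  }
  common <- object@rows$gene_id
  if (length(intersect(common, object@onlyIn1)) ||
      length(intersect(common, object@onlyIn2)) ||
      length(intersect(object@onlyIn1, object@onlyIn2))) {
    msgs <- c(msgs, "common and dataset-specific gene sets must be disjoint")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticConfig: parameters for the synthetic fixture generators
#'
#' Bundles every knob of the toy-data generators: ontology size, annotation
#' rates, the planted (term, direction) signals, differential-expression
#' fractions and effect sizes. A single integer seed drives one named
#' pseudorandom stream per generator, so adding a generator never perturbs
#' existing fixtures.
#'
#' @slot seed integer master seed.
#' @slot nGenes number of genes (Entrez-style numeric ids "1".."nGenes").
#' @slot nTermsPerNamespace terms per namespace including the root (>= 2).
#' @slot plantedTerms data.frame with columns `term_id`, `direction`
#'   ("up"/"down"), `rate_de` (annotation rate inside the planted DE set)
#'   and `rate_bg` (annotation rate elsewhere); `rate_de > rate_bg`.
#' @slot fracUp,fracDown fractions of genes planted as up-/down-regulated;
#'   their sum must stay below 1.
#' @slot dePMin,dePMax bounds of the uniform p-value distribution for
#'   planted DE genes (kept below alpha so planted genes are significant).
#' @slot lfcEffect mean absolute log2 fold change of planted DE genes.
#' @slot bgAnnotationRate per-(gene, leaf-term) background annotation rate.
#' @slot overlapFrac fraction of gene ids shared between the two tables in
#'   two-dataset mode.
#' @seealso [syntheticConfig()], [makeToyOntology()], [simulateExpression()]
#' @export
setClass("SyntheticConfig",
  representation(
    seed = "integer",
    nGenes = "integer",
    nTermsPerNamespace = "integer",
    plantedTerms = "data.frame",
    fracUp = "numeric",
    fracDown = "numeric",
    dePMin = "numeric",
    dePMax = "numeric",
    lfcEffect = "numeric",
    bgAnnotationRate = "numeric",
    overlapFrac = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  if (object@nTermsPerNamespace < 2L) {
    msgs <- c(msgs, "need at least 2 terms per namespace")
  }
  if (object@fracUp < 0 || object@fracDown < 0 ||
      object@fracUp + object@fracDown >= 1) {
    msgs <- c(msgs, "fracUp + fracDown must be in [0, 1)")
  }
  pt <- object@plantedTerms
  need <- c("term_id", "direction", "rate_de", "rate_bg")
  if (!all(need %in% names(pt))) {
    msgs <- c(msgs, "plantedTerms needs term_id, direction, rate_de, rate_bg")
  } else if (nrow(pt)) {
    if (any(pt$rate_de < 0 | pt$rate_de > 1 |
            pt$rate_bg < 0 | pt$rate_bg > 1)) {
      msgs <- c(msgs, "planted annotation rates must lie in [0, 1]")
    }
    if (any(pt$rate_de <= pt$rate_bg)) {
      msgs <- c(msgs, "rate_de must exceed rate_bg for every planted term")
    }
    if (!all(pt$direction %in% c("up", "down"))) {
      msgs <- c(msgs, "planted direction must be 'up' or 'down'")
    }
  }
  if (object@bgAnnotationRate < 0 || object@bgAnnotationRate > 1) {
    msgs <- c(msgs, "bgAnnotationRate must lie in [0, 1]")
  }
  if (object@dePMin <= 0 || object@dePMax <= object@dePMin) {
    msgs <- c(msgs, "need 0 < dePMin < dePMax")
  }
  if (object@overlapFrac < 0 || object@overlapFrac > 1) {
    msgs <- c(msgs, "overlapFrac must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})
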