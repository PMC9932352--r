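#' @include go-annotations.R
NULL

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a population of `N` genes of which `K` are annotated. Computed by
#' summing log-space terms (log-binomial coefficients combined through a
#' log-sum-exp) so small tails keep full relative accuracy.
#'
#' @param k observed count of annotated genes in the draw.
#' @param n draw (study) size.
#' @param K annotated genes in the population.
#' @param N population size.
#' @return The upper-tail probability, a value in (0, 1].
#' @export
#' @examples
#' hypergeomUpperTail(3, 5, 4, 10)  # 11/42
hypergeomUpperTail <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L,
            length(N) == 1L)
  if (k < 0 || n < 0 || K < 0 || N < 0 ||
      k > min(n, K) || n > N || K > N) {
    stop("invalid counts: need 0 <= k <= min(n, K) and n, K <= N")
  }
  if (k == 0L) {
    return(1)
  }
  i <- seq.int(max(k, n - (N - K)), min(n, K))
  logTerms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logTerms)
  p <- exp(m + log(sum(exp(logTerms - m))))
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by the
#' Benjamini-Hochberg step-up rule: with the m p-values sorted ascending,
#' the i-th adjusted value is `min over j >= i of m * p_(j) / j`, capped at
#' 1, returned in the original input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
#' @examples
#' bhAdjust(c(0.005, 0.1))
bhAdjust <- function(p) {
  if (!length(p)) {
    return(numeric(0))
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, cummin((m / m:1) * p[ord][m:1])[m:1])
  adj[order(ord)]
}

#' Over-representation analysis of one study set
#'
#' Tests, per namespace, every GO term annotated to at least one study gene
#' for over-representation of the study set within the universe, using the
#' hypergeometric upper tail. For each namespace the effective population is
#' the universe restricted to genes with at least one propagated annotation
#' in that namespace (`N`), and the effective study is the study set
#' restricted the same way (`n`). Benjamini-Hochberg adjustment is applied
#' within each (direction, namespace) family independently — up to six
#' families per full analysis, mirroring the six reported barplots. The
#' `percent` statistic is 100 * k / (total genes in the direction), the
#' x-axis of the barplots.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `universe`); typically the up- or down-regulated set.
#' @param direction `"up"` or `"down"`, a label carried into the results.
#' @param ann a propagated [AnnotationSet-class].
#' @param dag the [OntologyDAG-class].
#' @param universe character vector of background gene ids.
#' @param alphaFdr FDR threshold stored on the run (used by
#'   [significantTerms()]).
#' @param mtMethod multiple-testing correction: `"BH"` (default) or
#'   `"bonferroni"`; applied per family either way, reported in the `fdr`
#'   column.
#' @return An [EnrichmentRun-class] whose results cover the namespaces with
#'   at least one testable term, sorted by ascending p-value within each
#'   namespace. An unannotated or empty study yields an empty run with a
#'   warning.
#' @export
enrichStudy <- function(study, direction = c("up", "down"), ann, dag,
                        universe, alphaFdr = 0.05,
                        mtMethod = c("BH", "bonferroni")) {
  direction <- match.arg(direction)
  mtMethod <- match.arg(mtMethod)
  stopifnot(is(ann, "AnnotationSet"), is(dag, "OntologyDAG"))
  if (!ann@propagated) {
    stop("annotation set must be propagated before enrichment")
  }
  study <- unique(study)
  universe <- unique(universe)
  if (length(setdiff(study, universe))) {
    stop("study set must be a subset of the universe")
  }
  emptyRun <- function() {
    new("EnrichmentRun",
        results = .emptyEnrichmentResults(),
        alphaFdr = alphaFdr,
        universeSize = length(universe))
  }
  if (!length(study)) {
    warning("empty ", direction, " study set: nothing to test")
    return(emptyRun())
  }

  ns_of <- stats::setNames(dag@terms$namespace, dag@terms$term_id)
  directionTotal <- length(study)
  groups <- list()
  for (ns in c("biological_process", "molecular_function",
               "cellular_component")) {
    nsTerms <- dag@terms$term_id[dag@terms$namespace == ns]
    nsTerms <- intersect(nsTerms, names(ann@termToGenes))
    if (!length(nsTerms)) next
    # genes with >= 1 propagated annotation in this namespace
    nsAnnotated <- unique(unlist(ann@termToGenes[nsTerms],
                                 use.names = FALSE))
    popNS <- intersect(universe, nsAnnotated)
    studyNS <- intersect(study, popNS)
    Nn <- length(popNS)
    nn <- length(studyNS)
    if (nn == 0L) next
    rows <- lapply(nsTerms, function(t) {
      genes <- ann@termToGenes[[t]]
      k <- length(intersect(genes, studyNS))
      if (k == 0L) return(NULL)
      K <- length(intersect(genes, popNS))
      data.frame(term_id = t,
                 name = .termName(dag, t),
                 namespace = ns,
                 direction = direction,
                 k = k, n = nn, K = K, N = Nn,
                 p_value = hypergeomUpperTail(k, nn, K, Nn),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) next
    rows$fdr <- if (mtMethod == "BH") {
      bhAdjust(rows$p_value)
    } else {
      pmin(1, length(rows$p_value) * rows$p_value)
    }
    rows$fold <- (rows$k / rows$n) / (rows$K / rows$N)
    rows$percent <- 100 * rows$k / directionTotal
    rows <- rows[order(rows$p_value, rows$term_id), , drop = FALSE]
    groups[[ns]] <- rows
  }
  if (!length(groups)) {
    warning("no annotated gene in the ", direction,
            " study set: nothing to test")
    return(emptyRun())
  }
  res <- do.call(rbind, groups)
  rownames(res) <- NULL
  new("EnrichmentRun", results = res, alphaFdr = alphaFdr,
      universeSize = length(universe))
}

.termName <- function(dag, termId) {
  dag@terms$name[match(termId, dag@terms$term_id)]
}

.emptyEnrichmentResults <- function() {
  data.frame(term_id = character(0), name = character(0),
             namespace = character(0), direction = character(0),
             k = integer(0), n = integer(0), K = integer(0), N = integer(0),
             p_value = numeric(0), fdr = numeric(0), fold = numeric(0),
             percent = numeric(0), stringsAsFactors = FALSE)
}

#' Run over-representation analysis for both DE directions
#'
#' Builds the up- and down-regulated study sets from a classified table,
#' takes as background universe the genes of the table (restricted per
#' namespace to annotated genes inside [enrichStudy()]), and analyses the
#' two directions separately — never pooled. The result holds up to six
#' (direction, namespace) groups.
#'
#' @param table a [ClassifiedTable-class].
#' @param ann a propagated [AnnotationSet-class].
#' @param dag the [OntologyDAG-class].
#' @param alphaFdr FDR threshold for [significantTerms()]; default 0.05.
#' @param universe background gene ids; defaults to all genes of `table`.
#'   An unmatched fraction above 50% between table genes and annotated
#'   genes triggers a prominent warning (usually a gene-id-space mismatch:
#'   gene2go uses Entrez GeneIDs).
#' @param mtMethod multiple-testing correction, `"BH"` or `"bonferroni"`.
#' @return An [EnrichmentRun-class].
#' @export
runEnrichment <- function(table, ann, dag, alphaFdr = 0.05,
                          universe = geneIds(table),
                          mtMethod = c("BH", "bonferroni")) {
  mtMethod <- match.arg(mtMethod)
  stopifnot(is(table, "ClassifiedTable"))
  matched <- mean(universe %in% names(ann@geneToTerms))
  if (matched < 0.5) {
    warning(sprintf(paste0(
      "only %.1f%% of the %d universe genes have any annotation; ",
      "check that the expression table uses the same gene-id space ",
      "as the annotation file (Entrez GeneIDs for gene2go)"),
      100 * matched, length(universe)))
  }
  sets <- classGeneSets(table)
  runUp <- enrichStudy(intersect(sets$up, universe), "up", ann, dag,
                       universe, alphaFdr, mtMethod)
  runDown <- enrichStudy(intersect(sets$down, universe), "down", ann, dag,
                         universe, alphaFdr, mtMethod)
  res <- rbind(runUp@results, runDown@results)
  rownames(res) <- NULL
  new("EnrichmentRun", results = res, alphaFdr = alphaFdr,
      universeSize = length(unique(universe)))
}

#' Filter an enrichment run to significant, over-represented terms
#'
#' Keeps terms with `fdr < alphaFdr` and `fold > 1`: only over-represented
#' terms are reported and plotted; depleted terms (fold <= 1) are computed
#' upstream but dropped here. Grouping and within-group p-value order are
#' preserved.
#'
#' @param run an [EnrichmentRun-class].
#' @param alphaFdr FDR threshold; defaults to the run's own.
#' @return A filtered [EnrichmentRun-class].
#' @export
significantTerms <- function(run, alphaFdr = run@alphaFdr) {
  stopifnot(is(run, "EnrichmentRun"))
  res <- run@results
  res <- res[res$fdr < alphaFdr & res$fold > 1, , drop = FALSE]
  rownames(res) <- NULL
  new("EnrichmentRun", results = res, alphaFdr = alphaFdr,
      universeSize = run@universeSize)
}

#' Percentage of direction genes annotated to a term
#'
#' The barplot x-axis statistic: the share of all genes in a direction
#' (up- or down-regulated) annotated to the term, as a percentage.
#'
#' @param k genes of the direction annotated to the term.
#' @param directionTotal total genes in the direction (>= 1).
#' @return `100 * k / directionTotal`.
#' @export
#' @examples
#' termPercentage(4, 10)
termPercentage <- function(k, directionTotal) {
  if (directionTotal < 1) {
    stop("directionTotal must be at least 1")
  }
  if (k < 0 || k > directionTotal) {
    stop("k must lie in [0, directionTotal]")
  }
  100 * k / directionTotal
}

#' Write enrichment results as TSV
#'
#' @param run an [EnrichmentRun-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeEnrichmentTSV <- function(run, path) {
  stopifnot(is(run, "EnrichmentRun"))
  df <- run@results
  for (col in c("p_value", "fdr", "fold", "percent")) {
    df[[col]] <- .fmtNum(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
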