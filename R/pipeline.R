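#' @include plots.R
#' @include synthetic.R
NULL

# run expr, collecting warning messages without muffling errors
.collectWarnings <- function(expr) {
  warnings <- character(0)
  value <- withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = value, warnings = warnings)
}

.writeManifest <- function(manifest, outdir) {
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the single-dataset analysis pipeline
#'
#' End-to-end first pipeline: read an expression CSV, classify every gene
#' at the significance threshold, render the volcano plot, run the GO
#' over-representation analysis for the up- and down-regulated sets across
#' the three namespaces, and render up to six barplots of the significant
#' terms. Writes into `outdir`: `classified.csv`, `volcano.{format}`,
#' `enrichment.tsv` (all tested terms), `enrichment_significant.tsv`, the
#' barplots, and `manifest.json` recording inputs, parameters, class
#' counts, outputs and collected warnings. On error, partial outputs are
#' removed and the error is re-raised.
#'
#' @param input path to the expression CSV.
#' @param obo path to the GO ontology in OBO format.
#' @param gene2go path to the NCBI gene2go annotation TSV.
#' @param outdir output directory, created if missing.
#' @param taxon NCBI taxonomy id for the annotation filter; default 9606.
#' @param alpha significance threshold for classification; default 0.05.
#' @param alphaFdr FDR threshold for reporting significant terms.
#' @param geneCol,lfcCol,pCol input column names, as in
#'   [readExpressionTable()].
#' @param dedupe duplicate-id policy, as in [readExpressionTable()].
#' @param plotFormat `"png"` or `"svg"`.
#' @param maxTerms barplot readability cap, as in
#'   [renderOntologyBarplots()].
#' @param mtMethod multiple-testing correction, `"BH"` or `"bonferroni"`.
#' @return The manifest, invisibly (a named list).
#' @export
runAnalyze <- function(input, obo, gene2go, outdir,
                       taxon = 9606, alpha = 0.05, alphaFdr = 0.05,
                       geneCol = "GeneID", lfcCol = "log2FC",
                       pCol = "pvalue", dedupe = "error",
                       plotFormat = "png", maxTerms = 20,
                       mtMethod = "BH") {
  for (arg in c(input = input, obo = obo, gene2go = gene2go)) {
    if (!file.exists(arg)) {
      stop("input file not found: ", arg)
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }

  res <- tryCatch({
    .collectWarnings({
      table <- readExpressionTable(input, geneCol, lfcCol, pCol,
                                   dedupe = dedupe)
      ct <- classifyTable(table, alpha = alpha)
      writeExpressionTable(ct, note(file.path(outdir, "classified.csv")))
      renderVolcano(ct, note(file.path(outdir,
                                       paste0("volcano.", plotFormat))))
      dag <- parseOBO(obo)
      ann <- propagateAnnotations(readGene2go(gene2go, taxon = taxon),
                                  dag)
      run <- runEnrichment(ct, ann, dag, alphaFdr = alphaFdr,
                           mtMethod = mtMethod)
      writeEnrichmentTSV(run, note(file.path(outdir, "enrichment.tsv")))
      sig <- significantTerms(run)
      writeEnrichmentTSV(sig, note(file.path(outdir,
                                             "enrichment_significant.tsv")))
      plots <- renderOntologyBarplots(sig, outdir, maxTerms = maxTerms,
                                      format = plotFormat)
      written <<- c(written, plots)
      list(table = table, classified = ct, run = run, significant = sig,
           barplots = plots)
    })
  }, error = function(e) {
    file.remove(written[file.exists(written)])
    stop(e)
  })

  ct <- res$value$classified
  counts <- as.list(table(expressionClass(ct)))
  manifest <- list(
    pipeline = "analyze",
    inputs = list(expression = input, obo = obo, gene2go = gene2go),
    parameters = list(taxon = taxon, alpha = alpha, alphaFdr = alphaFdr,
                      dedupe = dedupe, mtMethod = mtMethod),
    n_genes = nGenes(ct),
    dropped_rows = attr(res$value$table, "droppedRows"),
    class_counts = counts,
    n_terms_tested = nrow(enrichmentResults(res$value$run)),
    n_terms_significant = nrow(enrichmentResults(res$value$significant)),
    n_barplots = length(res$value$barplots),
    outputs = as.list(written),
    warnings = as.list(res$warnings),
    errors = list())
  .writeManifest(manifest, outdir)
  invisible(manifest)
}

#' Run the two-dataset comparison pipeline
#'
#' End-to-end second pipeline: read and classify two expression CSVs under
#' one shared significance threshold, join them on their common genes, and
#' write `combined.csv`, `contingency.csv` (the 3x3 expression-class
#' table), the two dataset-specific gene lists and `manifest.json`.
#'
#' @param input1,input2 paths to the two expression CSVs.
#' @param outdir output directory, created if missing.
#' @param alpha shared significance threshold; default 0.05.
#' @param geneCol,lfcCol,pCol,dedupe as in [readExpressionTable()].
#' @param normalizeIds id matching policy, as in [mergeDatasets()].
#' @return The manifest, invisibly.
#' @export
runCompare <- function(input1, input2, outdir, alpha = 0.05,
                       geneCol = "GeneID", lfcCol = "log2FC",
                       pCol = "pvalue", dedupe = "error",
                       normalizeIds = "none") {
  for (arg in c(input1 = input1, input2 = input2)) {
    if (!file.exists(arg)) {
      stop("input file not found: ", arg)
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- .collectWarnings({
    t1 <- classifyTable(readExpressionTable(input1, geneCol, lfcCol, pCol,
                                            dedupe = dedupe),
                        alpha = alpha)
    t2 <- classifyTable(readExpressionTable(input2, geneCol, lfcCol, pCol,
                                            dedupe = dedupe),
                        alpha = alpha)
    merged <- mergeDatasets(t1, t2, normalizeIds = normalizeIds)
    ctab <- contingencyTable(merged)
    paths <- writeComparison(merged, ctab, outdir)
    list(merged = merged, ctab = ctab, paths = paths)
  })
  merged <- res$value$merged
  manifest <- list(
    pipeline = "compare",
    inputs = list(expression1 = input1, expression2 = input2),
    parameters = list(alpha = alpha, dedupe = dedupe,
                      normalizeIds = normalizeIds),
    n_common = nrow(mergedRows(merged)),
    n_only_in_1 = length(onlyIn(merged, 1L)),
    n_only_in_2 = length(onlyIn(merged, 2L)),
    contingency = unclass(res$value$ctab),
    outputs = as.list(unname(res$value$paths)),
    warnings = as.list(res$warnings),
    errors = list())
  .writeManifest(manifest, outdir)
  invisible(manifest)
}

#' Generate a complete set of synthetic fixtures
#'
#' Emits `toy.obo`, `toy_gene2go.tsv`, `expr1.csv`, `expr2.csv` and
#' `truth.csv` into `outdir` — a self-contained input set for
#' [runAnalyze()] and [runCompare()].
#'
#' @param seed master seed.
#' @param outdir output directory, created if missing.
#' @param config optional [SyntheticConfig-class]; defaults to
#'   `syntheticConfig(seed = seed)`.
#' @return Named list of the five file paths, invisibly.
#' @export
runSimulate <- function(seed = 1L, outdir,
                        config = syntheticConfig(seed = seed)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  onto <- makeToyOntology(config, file.path(outdir, "toy.obo"))
  anns <- makeToyAnnotations(onto$dag, config,
                             file.path(outdir, "toy_gene2go.tsv"))
  sim <- simulateExpression(config, outdir, twoDatasets = TRUE)
  invisible(c(list(obo = onto$path, gene2go = anns$path),
              as.list(sim$paths)))
}
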