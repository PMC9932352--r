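#' @include deg-classify.R
NULL

#' Merge two classified expression datasets
#'
#' Inner join on exact, case-sensitive gene id equality (silent
#' case-folding across id systems is dangerous; use
#' `normalizeIds = "upper"` to fold both sides to upper case first). Both
#' tables must have been classified with the same significance threshold.
#' The merged rows follow dataset 1's order restricted to the common genes;
#' the identifiers specific to each dataset are kept alongside. An empty
#' intersection is a warning, not an error.
#'
#' @param t1,t2 [ClassifiedTable-class] objects.
#' @param normalizeIds `"none"` (default) or `"upper"`.
#' @return A [MergedTable-class].
#' @export
mergeDatasets <- function(t1, t2, normalizeIds = c("none", "upper")) {
  normalizeIds <- match.arg(normalizeIds)
  stopifnot(is(t1, "ClassifiedTable"), is(t2, "ClassifiedTable"))
  if (!isTRUE(all.equal(t1@alpha, t2@alpha))) {
    stop("both tables must be classified with the same alpha (",
         t1@alpha, " vs ", t2@alpha, ")")
  }
  id1 <- t1@geneId
  id2 <- t2@geneId
  if (normalizeIds == "upper") {
    id1 <- toupper(id1)
    id2 <- toupper(id2)
    if (anyDuplicated(id1) || anyDuplicated(id2)) {
      stop("upper-casing gene ids created duplicates")
    }
  }
  common <- id1[id1 %in% id2]           # keeps t1 order
  if (!length(common)) {
    warning("no genes shared between the two datasets")
  }
  i1 <- match(common, id1)
  i2 <- match(common, id2)
  rows <- data.frame(
    gene_id = common,
    log_fc_1 = t1@logFC[i1],
    p_1 = t1@pValue[i1],
    class_1 = as.character(t1@expressionClass[i1]),
    log_fc_2 = t2@logFC[i2],
    p_2 = t2@pValue[i2],
    class_2 = as.character(t2@expressionClass[i2]),
    stringsAsFactors = FALSE)
  new("MergedTable",
      rows = rows,
      onlyIn1 = setdiff(id1, id2),
      onlyIn2 = setdiff(id2, id1),
      alpha = t1@alpha)
}

#' 3x3 expression-class contingency table of common genes
#'
#' Cross-classifies the genes common to two datasets by their expression
#' class in each: rows are dataset 1's class, columns dataset 2's, both in
#' the fixed order Downregulated, Not differentially expressed,
#' Upregulated. The grand total equals the number of common genes.
#'
#' @param merged a [MergedTable-class].
#' @return 3x3 integer matrix with dimnames `data1_expression` (rows) and
#'   `data2_expression` (columns).
#' @export
contingencyTable <- function(merged) {
  stopifnot(is(merged, "MergedTable"))
  lv <- expressionClassLevels()
  tab <- table(factor(merged@rows$class_1, levels = lv),
               factor(merged@rows$class_2, levels = lv))
  m <- matrix(as.integer(tab), nrow = 3L,
              dimnames = list(data1_expression = lv,
                              data2_expression = lv))
  m
}

#' Write the two-dataset comparison artifacts
#'
#' Writes four CSV files into `outdir`: `combined.csv` (per common gene,
#' both datasets' statistics and classes, headers suffixed `_1`/`_2`),
#' `contingency.csv` (the 3x3 class table, dataset-1 classes as rows),
#' and `only_in_dataset1.csv` / `only_in_dataset2.csv` (one-column lists of
#' dataset-specific gene ids).
#'
#' @param merged a [MergedTable-class].
#' @param ctab the matching 3x3 matrix from [contingencyTable()]; computed
#'   from `merged` when omitted.
#' @param outdir output directory, created if missing.
#' @return Named character vector of the four file paths, invisibly.
#' @export
writeComparison <- function(merged, ctab = contingencyTable(merged),
                            outdir) {
  stopifnot(is(merged, "MergedTable"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(combined = file.path(outdir, "combined.csv"),
             contingency = file.path(outdir, "contingency.csv"),
             only1 = file.path(outdir, "only_in_dataset1.csv"),
             only2 = file.path(outdir, "only_in_dataset2.csv"))

  comb <- merged@rows
  names(comb) <- c("GeneID", "log2FC_1", "pvalue_1", "expression_class_1",
                   "log2FC_2", "pvalue_2", "expression_class_2")
  for (col in c("log2FC_1", "pvalue_1", "log2FC_2", "pvalue_2")) {
    comb[[col]] <- .fmtNum(comb[[col]])
  }
  utils::write.csv(comb, paths[["combined"]], row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")

  cdf <- data.frame(data1_expression = rownames(ctab),
                    ctab, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(cdf, paths[["contingency"]], row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")

  utils::write.csv(data.frame(GeneID = merged@onlyIn1),
                   paths[["only1"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(GeneID = merged@onlyIn2),
                   paths[["only2"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a combined comparison CSV back into merged rows
#'
#' Inverse of the `combined.csv` writer, for round-trip checks and
#' downstream reuse.
#'
#' @param path path to a `combined.csv` written by [writeComparison()].
#' @return data.frame in the [MergedTable-class] row layout.
#' @export
readComparisonCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  data.frame(gene_id = as.character(df$GeneID),
             log_fc_1 = df$log2FC_1, p_1 = df$pvalue_1,
             class_1 = df$expression_class_1,
             log_fc_2 = df$log2FC_2, p_2 = df$pvalue_2,
             class_2 = df$expression_class_2,
             stringsAsFactors = FALSE)
}
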