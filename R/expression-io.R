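#' @include AllGenerics.R
NULL

#' Read an expression CSV into an ExpressionTable
#'
#' Reads a comma-separated file with a header row and at least a gene id
#' column, a log2 fold-change column and a p-value column. Rows whose fold
#' change or p-value is missing or unparseable are dropped with a warning
#' that reports the count; rows are never imputed. Duplicate gene ids are a
#' hard error by default because silent duplicates corrupt the enrichment
#' universe; `dedupe = "keep-min-p"` instead keeps, per gene, the row with
#' the smallest p-value (first occurrence on ties).
#'
#' @param path path to a CSV file (RFC 4180, UTF-8, header required).
#' @param geneCol,lfcCol,pCol header names of the identifier, log2
#'   fold-change and p-value columns.
#' @param dedupe `"error"` (default) or `"keep-min-p"`.
#' @param sourceLabel dataset label stored on the table; defaults to the
#'   file name.
#' @return An [ExpressionTable-class]; rows keep file order. The number of
#'   dropped rows is attached as attribute `"droppedRows"`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("GeneID,log2FC,pvalue", "G1,1.5,0.01", "G2,-0.2,0.5"), f)
#' readExpressionTable(f)
readExpressionTable <- function(path,
                                geneCol = "GeneID",
                                lfcCol = "log2FC",
                                pCol = "pvalue",
                                dedupe = c("error", "keep-min-p"),
                                sourceLabel = basename(path)) {
  dedupe <- match.arg(dedupe)
  if (!file.exists(path)) {
    stop("expression file not found: ", path)
  }
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  for (col in c(geneCol, lfcCol, pCol)) {
    if (!col %in% names(raw)) {
      stop("column '", col, "' not found in ", path,
           " (available: ", paste(names(raw), collapse = ", "), ")")
    }
  }
  gene <- trimws(raw[[geneCol]])
  lfc <- suppressWarnings(as.numeric(raw[[lfcCol]]))
  p <- suppressWarnings(as.numeric(raw[[pCol]]))

  drop <- is.na(lfc) | !is.finite(lfc) | is.na(p) | !nzchar(gene) |
    is.na(gene)
  nDropped <- sum(drop)
  if (nDropped > 0L) {
    warning(nDropped, " row(s) dropped from ", basename(path),
            " (missing or unparseable values)")
    gene <- gene[!drop]; lfc <- lfc[!drop]; p <- p[!drop]
  }
  if (length(gene) == 0L) {
    stop("no usable rows left in ", path, " after filtering")
  }
  if (any(p < 0 | p > 1)) {
    stop("p-values outside [0, 1] in ", path)
  }
  if (anyDuplicated(gene)) {
    if (dedupe == "error") {
      dup <- unique(gene[duplicated(gene)])
      stop("duplicate gene id(s) in ", path, ": ",
           paste(utils::head(dup, 5L), collapse = ", "),
           "; rerun with dedupe = \"keep-min-p\" to aggregate")
    }
    # keep-min-p: stable selection of the minimum-p row per gene
    ord <- order(match(gene, gene), p)  # file order within gene, then p
    keepIdx <- ord[!duplicated(gene[ord])]
    keepIdx <- sort(keepIdx)
    gene <- gene[keepIdx]; lfc <- lfc[keepIdx]; p <- p[keepIdx]
  }
  out <- ExpressionTable(gene, lfc, p, sourceLabel = sourceLabel)
  attr(out, "droppedRows") <- nDropped
  out
}

#' Write an expression table to CSV
#'
#' Writes a plain or classified table as CSV with headers `GeneID`,
#' `log2FC`, `pvalue` (plus `expression_class` and `neg_log10_p` for
#' classified tables). The output round-trips: reading it back with
#' [readExpressionTable()] reproduces the table field for field.
#'
#' @param table an [ExpressionTable-class] or [ClassifiedTable-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeExpressionTable <- function(table, path) {
  stopifnot(is(table, "ExpressionTable"))
  df <- as.data.frame(table)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- .fmtNum(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
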