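#' @include AllGenerics.R
NULL

# p-value floor for the volcano y coordinate only; classification always
# uses the raw p-value.
.P_FLOOR <- 1e-300

#' Classify genes as up-, down- or not differentially expressed
#'
#' Applies the three-way rule: a gene is differentially expressed when its
#' p-value falls strictly below `alpha` (default 5%); significant genes
#' with positive log2 fold change are "Upregulated" and those with negative
#' fold change "Downregulated"; everything else is "Not differentially
#' expressed". Two boundary cases the rule leaves open are resolved
#' conservatively: p exactly equal to `alpha` is not significant, and a
#' significant gene with fold change exactly 0 stays not differentially
#' expressed (with a warning, since it usually signals degenerate input).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param logFC numeric vector of finite log2 fold changes.
#' @param alpha significance threshold in (0, 1).
#' @return Factor with levels [expressionClassLevels()], one per gene.
#' @export
#' @examples
#' classifyGene(c(0.01, 0.01, 0.2), c(1.5, -0.5, 3), alpha = 0.05)
classifyGene <- function(p, logFC, alpha = 0.05) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)")
  }
  if (length(p) != length(logFC)) {
    stop("p and logFC must have equal length")
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  if (any(!is.finite(logFC))) {
    stop("logFC values must be finite")
  }
  lv <- expressionClassLevels()
  cls <- rep(lv[2L], length(p))                 # Not differentially expressed
  sig <- p < alpha
  cls[sig & logFC > 0] <- lv[3L]                # Upregulated
  cls[sig & logFC < 0] <- lv[1L]                # Downregulated
  zeroSig <- sig & logFC == 0
  if (any(zeroSig)) {
    warning(sum(zeroSig), " significant gene(s) with logFC exactly 0 kept",
            " as 'Not differentially expressed'")
  }
  factor(cls, levels = lv)
}

#' Classify every gene of an expression table
#'
#' Runs [classifyGene()] over the whole table and attaches the volcano
#' y coordinate `-log10(max(p, 1e-300))`; the floor keeps p = 0 finite on
#' the plot while classification uses the raw p-value.
#'
#' @param table an [ExpressionTable-class].
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @return A [ClassifiedTable-class] with one class per gene; the class
#'   counts always sum to [nGenes()].
#' @export
#' @examples
#' tab <- ExpressionTable(c("G1", "G2", "G3"),
#'                        c(1.5, -0.5, 3.0), c(0.01, 0.01, 0.2))
#' classifyTable(tab)
classifyTable <- function(table, alpha = 0.05) {
  stopifnot(is(table, "ExpressionTable"))
  cls <- classifyGene(table@pValue, table@logFC, alpha)
  new("ClassifiedTable",
      geneId = table@geneId,
      logFC = table@logFC,
      pValue = table@pValue,
      sourceLabel = table@sourceLabel,
      expressionClass = cls,
      negLog10P = -log10(pmax(table@pValue, .P_FLOOR)),
      alpha = alpha)
}

#' Volcano-plot coordinates of a classified table
#'
#' @param table a [ClassifiedTable-class].
#' @return data.frame with one row per gene and columns `gene_id`,
#'   `log_fc` (x), `neg_log10_p` (y) and `class` for colouring.
#' @seealso [renderVolcano()]
#' @export
volcanoCoordinates <- function(table) {
  stopifnot(is(table, "ClassifiedTable"))
  data.frame(gene_id = table@geneId,
             log_fc = table@logFC,
             neg_log10_p = table@negLog10P,
             class = table@expressionClass,
             stringsAsFactors = FALSE)
}

#' Gene sets per expression class
#'
#' Convenience extractor for the up- and down-regulated study sets used in
#' over-representation analysis.
#'
#' @param table a [ClassifiedTable-class].
#' @return Named list with character vectors `up`, `down` and `notde`.
#' @export
classGeneSets <- function(table) {
  stopifnot(is(table, "ClassifiedTable"))
  lv <- expressionClassLevels()
  list(up = table@geneId[table@expressionClass == lv[3L]],
       down = table@geneId[table@expressionClass == lv[1L]],
       notde = table@geneId[table@expressionClass == lv[2L]])
}
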