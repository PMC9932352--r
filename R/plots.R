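#' @include enrichment.R
#' @include dataset-compare.R
#' @importFrom rlang .data
NULL

# ggsave's svg default needs svglite; use the cairo-based base device
# instead so both formats work with base-library graphics only.
.ggsaveCompat <- function(file, plot, dpi, width, height) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "svg") {
    ggplot2::ggsave(file, plot, device = grDevices::svg,
                    width = width, height = height)
  } else {
    ggplot2::ggsave(file, plot, dpi = dpi, width = width, height = height)
  }
}

.CLASS_COLOURS <- c("Downregulated" = "#2166ac",
                    "Not differentially expressed" = "grey60",
                    "Upregulated" = "#b2182b")

#' Render a volcano plot
#'
#' Scatter of log2 fold change (x) against -log10 p (y), one point per
#' gene, coloured by expression class, with a horizontal guide line at
#' `-log10(alpha)` separating significant from non-significant genes.
#'
#' @param table a [ClassifiedTable-class] (or the data.frame from
#'   [volcanoCoordinates()] plus an explicit `alpha`).
#' @param file output image path; the extension picks the device (`.png`
#'   or `.svg`).
#' @param title plot title.
#' @param dpi raster resolution; default 150.
#' @param width,height device size in inches.
#' @param alpha significance threshold for the guide line; taken from the
#'   table when it is a [ClassifiedTable-class].
#' @return The file path, invisibly.
#' @export
renderVolcano <- function(table, file, title = "Volcano plot", dpi = 150,
                          width = 7, height = 5, alpha = NULL) {
  if (is(table, "ClassifiedTable")) {
    pts <- volcanoCoordinates(table)
    if (is.null(alpha)) alpha <- table@alpha
  } else {
    pts <- as.data.frame(table)
    if (is.null(alpha)) alpha <- 0.05
  }
  if (!nrow(pts)) {
    stop("no points to plot")
  }
  .checkExtension(file)
  gg <- ggplot2::ggplot(pts, ggplot2::aes(
          x = .data$log_fc, y = .data$neg_log10_p, colour = .data$class)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey30") +
    ggplot2::scale_colour_manual(values = .CLASS_COLOURS, drop = FALSE,
                                 name = NULL) +
    ggplot2::labs(title = title, x = "log2 fold change",
                  y = expression(-log[10] ~ "p-value")) +
    ggplot2::theme_bw()
  .ggsaveCompat(file, gg, dpi = dpi, width = width, height = height)
  invisible(file)
}

#' Render the per-direction, per-namespace ontology barplots
#'
#' One horizontal barplot per non-empty (direction, namespace) group of a
#' significance-filtered enrichment run — up to six files, covering the
#' biological-process, molecular-function and cellular-component terms of
#' the up- and down-regulated gene sets. Term names run along the y-axis;
#' the x-axis is the percentage of the direction's genes annotated to the
#' term; bars are sorted by descending percentage. A group with no
#' significant term produces a message instead of a file. Files are named
#' `{direction}_{namespace}.{format}`.
#'
#' @param run an [EnrichmentRun-class], normally already filtered by
#'   [significantTerms()].
#' @param outdir output directory, created if missing.
#' @param maxTerms plot at most this many terms per group, keeping the
#'   smallest p-values (readability cap; the full table is in the TSV).
#' @param format `"png"` or `"svg"`.
#' @param dpi raster resolution; default 150.
#' @return Character vector of files written (length 0-6), invisibly.
#' @export
renderOntologyBarplots <- function(run, outdir, maxTerms = 20,
                                   format = c("png", "svg"), dpi = 150) {
  format <- match.arg(format)
  stopifnot(is(run, "EnrichmentRun"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- run@results
  written <- character(0)
  for (dir_ in c("up", "down")) {
    for (ns in c("biological_process", "molecular_function",
                 "cellular_component")) {
      grp <- res[res$direction == dir_ & res$namespace == ns, ,
                 drop = FALSE]
      if (!nrow(grp)) {
        message("no significant ", ns, " terms for ", dir_,
                "-regulated genes; no barplot written")
        next
      }
      grp <- grp[order(grp$p_value, grp$term_id), , drop = FALSE]
      grp <- utils::head(grp, maxTerms)
      grp <- grp[order(grp$percent, decreasing = FALSE), , drop = FALSE]
      grp$name <- factor(grp$name, levels = unique(grp$name))
      gg <- ggplot2::ggplot(grp, ggplot2::aes(
              x = .data$percent, y = .data$name)) +
        ggplot2::geom_col(fill = if (dir_ == "up") "#b2182b"
                                 else "#2166ac") +
        ggplot2::labs(
          title = paste0(gsub("_", " ", ns), ", ", dir_,
                         "-regulated genes"),
          x = "% of genes in direction annotated to term", y = NULL) +
        ggplot2::theme_bw()
      file <- file.path(outdir, paste0(dir_, "_", ns, ".", format))
      h <- max(2.5, 0.8 + 0.25 * nrow(grp))
      .ggsaveCompat(file, gg, dpi = dpi, width = 7, height = h)
      written <- c(written, file)
    }
  }
  invisible(written)
}

.checkExtension <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (!ext %in% c("png", "svg")) {
    stop("unsupported image format '", ext, "' (use png or svg)")
  }
  invisible(ext)
}
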