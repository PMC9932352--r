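#' @include go-annotations.R
NULL

.NAMESPACES <- c(biological_process = "Process",
                 molecular_function = "Function",
                 cellular_component = "Component")

# deterministic term-id scheme: namespace block + index, root at index 1
.toyTermId <- function(nsIndex, j) sprintf("GO:%07d", nsIndex * 1000000 + j)

#' Build a synthetic-data configuration
#'
#' Collects every parameter of the toy-data generators. The defaults are
#' the study conditions used throughout the package's tests: 1000 genes,
#' 10% planted up- and 10% down-regulated, one planted biological-process
#' term annotated to 80% of the up-regulated genes against a 10%
#' background, planted p-values uniform on \[1e-6, 0.025\] (below the 5%
#' threshold) and a mean absolute log2 fold change of 2 for DE genes.
#'
#' @param seed master integer seed; each generator derives its own named
#'   pseudorandom stream from it.
#' @param nGenes number of genes; ids are the strings "1" .. "nGenes".
#' @param nTermsPerNamespace terms per namespace, root included (>= 2).
#' @param plantedTerms data.frame(term_id, direction, rate_de, rate_bg);
#'   defaults to one up-planted biological-process term.
#' @param fracUp,fracDown planted DE fractions (sum < 1).
#' @param dePMin,dePMax uniform p-value bounds for planted DE genes.
#' @param lfcEffect mean |log2 fold change| of planted DE genes.
#' @param bgAnnotationRate background per-(gene, leaf-term) annotation
#'   probability.
#' @param overlapFrac fraction of gene ids shared in two-dataset mode.
#' @return A validated [SyntheticConfig-class].
#' @export
#' @examples
#' syntheticConfig(seed = 1, nGenes = 200)
syntheticConfig <- function(seed = 1L,
                            nGenes = 1000L,
                            nTermsPerNamespace = 8L,
                            plantedTerms = data.frame(
                              term_id = .toyTermId(1L, 2L),
                              direction = "up",
                              rate_de = 0.8,
                              rate_bg = 0.1,
                              stringsAsFactors = FALSE),
                            fracUp = 0.1,
                            fracDown = 0.1,
                            dePMin = 1e-6,
                            dePMax = 0.025,
                            lfcEffect = 2,
                            bgAnnotationRate = 0.1,
                            overlapFrac = 0.8) {
  new("SyntheticConfig",
      seed = as.integer(seed),
      nGenes = as.integer(nGenes),
      nTermsPerNamespace = as.integer(nTermsPerNamespace),
      plantedTerms = plantedTerms,
      fracUp = fracUp, fracDown = fracDown,
      dePMin = dePMin, dePMax = dePMax,
      lfcEffect = lfcEffect,
      bgAnnotationRate = bgAnnotationRate,
      overlapFrac = overlapFrac)
}

# planted DE gene layout shared by the annotation and expression
# generators: the first block of ids is up-regulated, the next block
# down-regulated, the rest null.
.plantedSets <- function(config) {
  n <- config@nGenes
  nUp <- round(config@fracUp * n)
  nDown <- round(config@fracDown * n)
  ids <- as.character(seq_len(n))
  list(up = ids[seq_len(nUp)],
       down = ids[nUp + seq_len(nDown)],
       null = ids[setdiff(seq_len(n), seq_len(nUp + nDown))],
       all = ids)
}

#' Generate a toy GO ontology
#'
#' Builds three rooted trees, one per namespace, with occasional extra
#' `is_a` edges (making a genuine DAG, not just a tree) and one `part_of`
#' edge per namespace, serialises the result as a valid OBO file and
#' parses it back. Byte-identical output for a fixed seed.
#'
#' @param config a [SyntheticConfig-class].
#' @param path where to write the OBO file.
#' @return List with elements `dag` (an [OntologyDAG-class]) and `path`.
#' @export
makeToyOntology <- function(config,
                            path = tempfile(fileext = ".obo")) {
  stopifnot(is(config, "SyntheticConfig"))
  nT <- config@nTermsPerNamespace
  stanzas <- character(0)
  .withStream(config@seed, "ontology", {
    for (nsIndex in 1:3) {
      ns <- names(.NAMESPACES)[nsIndex]
      for (j in seq_len(nT)) {
        id <- .toyTermId(nsIndex, j)
        lines <- c("[Term]",
                   paste0("id: ", id),
                   paste0("name: toy ", sub("_", " ", ns), " term ", j),
                   paste0("namespace: ", ns))
        if (j > 1L) {
          # index 2 is reserved as a leaf-level term in every namespace
          # (the planted-signal slot): were it to acquire descendants,
          # propagation would dilute any signal planted on it with the
          # descendants' background annotations
          cand <- setdiff(seq_len(j - 1L), 2L)
          if (!length(cand)) cand <- 1L
          parent <- .toyTermId(nsIndex,
                               cand[sample.int(length(cand), 1L)])
          lines <- c(lines, paste0("is_a: ", parent, " ! parent"))
          # extra edge with prob 0.25 to an earlier term, forming a DAG
          if (j > 2L && stats::runif(1) < 0.25) {
            extra <- .toyTermId(nsIndex,
                                cand[sample.int(length(cand), 1L)])
            if (extra != parent) {
              lines <- c(lines, paste0("is_a: ", extra, " ! extra"))
            }
          }
        }
        if (j == nT && nT > 2L) {
          lines <- c(lines,
                     paste0("relationship: part_of ",
                            .toyTermId(nsIndex, 1L), " ! root"))
        }
        stanzas <- c(stanzas, paste(lines, collapse = "\n"))
      }
    }
  })
  text <- paste0("format-version: 1.2\nontology: toy-go\n\n",
                 paste(stanzas, collapse = "\n\n"), "\n")
  writeLines(text, path, sep = "")
  list(dag = parseOBO(path), path = path)
}

#' Generate toy gene2go annotations
#'
#' Annotates genes to the leaf terms of a toy ontology at the background
#' rate, and annotates the planted DE gene blocks to the planted terms at
#' their elevated rate (other genes at that term's own background rate).
#' Output is a valid NCBI gene2go TSV for taxon 9606, byte-identical for a
#' fixed seed.
#'
#' @param dag the [OntologyDAG-class] from [makeToyOntology()].
#' @param config the same [SyntheticConfig-class].
#' @param path where to write the gene2go TSV.
#' @return List with elements `ann` (an unpropagated
#'   [AnnotationSet-class] read back from the file) and `path`.
#' @export
makeToyAnnotations <- function(dag, config,
                               path = tempfile(fileext = ".tsv")) {
  stopifnot(is(dag, "OntologyDAG"), is(config, "SyntheticConfig"))
  sets <- .plantedSets(config)
  genes <- sets$all
  planted <- config@plantedTerms
  # leaves: terms that are nobody's parent
  parents <- unique(unlist(dag@isAParents, use.names = FALSE))
  leaves <- setdiff(dag@terms$term_id, parents)
  bgTerms <- setdiff(leaves, planted$term_id)

  pairsGene <- character(0)
  pairsTerm <- character(0)
  .withStream(config@seed, "annotations", {
    for (t in bgTerms) {
      hit <- stats::runif(length(genes)) < config@bgAnnotationRate
      pairsGene <- c(pairsGene, genes[hit])
      pairsTerm <- c(pairsTerm, rep(t, sum(hit)))
    }
    for (i in seq_len(nrow(planted))) {
      t <- planted$term_id[i]
      target <- sets[[planted$direction[i]]]
      rest <- setdiff(genes, target)
      hitT <- stats::runif(length(target)) < planted$rate_de[i]
      hitR <- stats::runif(length(rest)) < planted$rate_bg[i]
      pairsGene <- c(pairsGene, target[hitT], rest[hitR])
      pairsTerm <- c(pairsTerm, rep(t, sum(hitT) + sum(hitR)))
    }
  })
  ord <- order(as.integer(pairsGene), pairsTerm)
  pairsGene <- pairsGene[ord]
  pairsTerm <- pairsTerm[ord]
  ns <- dag@terms$namespace[match(pairsTerm, dag@terms$term_id)]
  df <- data.frame(tax_id = "9606",
                   GeneID = pairsGene,
                   GO_ID = pairsTerm,
                   Evidence = "IEA",
                   Qualifier = "-",
                   GO_term = .termName(dag, pairsTerm),
                   PubMed = "-",
                   Category = unname(.NAMESPACES[ns]),
                   stringsAsFactors = FALSE)
  header <- paste0("#", paste(.G2G_COLUMNS, collapse = "\t"))
  body <- do.call(paste, c(df, sep = "\t"))
  writeLines(c(header, body), path)
  list(ann = readGene2go(path, taxon = 9606), path = path)
}

#' Simulate expression tables with known truth labels
#'
#' Draws one (or two) expression tables matching the planted-DE layout:
#' up-regulated genes get p ~ Uniform(dePMin, dePMax) and
#' logFC = |Normal(lfcEffect, 0.2 lfcEffect)|, down-regulated genes the
#' mirrored negative fold change, and the remaining genes null statistics
#' (p ~ Uniform(0, 1), logFC ~ Normal(0, 0.3)). Truth labels go to a
#' sidecar CSV, never into the expression files, so the fixtures are
#' indistinguishable from real inputs. In two-dataset mode the second
#' table shares `overlapFrac` of the gene ids and carries its own
#' independent statistics and truth labels. Byte-identical files for a
#' fixed seed.
#'
#' @param config a [SyntheticConfig-class].
#' @param outdir output directory, created if missing.
#' @param twoDatasets also generate `expr2.csv` (default FALSE).
#' @return List with `tables` (one or two [ExpressionTable-class]
#'   objects), `truth` (data.frame gene_id/dataset/truth_class) and
#'   `paths` (named: expr1, optionally expr2, truth).
#' @export
simulateExpression <- function(config, outdir = tempfile(),
                               twoDatasets = FALSE) {
  stopifnot(is(config, "SyntheticConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lv <- expressionClassLevels()

  drawTable <- function(ids, stream) {
    n <- length(ids)
    nUp <- round(config@fracUp * n)
    nDown <- round(config@fracDown * n)
    truth <- rep(lv[2L], n)
    truth[seq_len(nUp)] <- lv[3L]
    truth[nUp + seq_len(nDown)] <- lv[1L]
    p <- numeric(n); lfc <- numeric(n)
    .withStream(config@seed, stream, {
      p[truth == lv[3L]] <- stats::runif(nUp, config@dePMin, config@dePMax)
      lfc[truth == lv[3L]] <- abs(stats::rnorm(nUp, config@lfcEffect,
                                               0.2 * config@lfcEffect))
      p[truth == lv[1L]] <- stats::runif(nDown, config@dePMin,
                                         config@dePMax)
      lfc[truth == lv[1L]] <- -abs(stats::rnorm(nDown, config@lfcEffect,
                                                0.2 * config@lfcEffect))
      nNull <- n - nUp - nDown
      p[truth == lv[2L]] <- stats::runif(nNull)
      lfc[truth == lv[2L]] <- stats::rnorm(nNull, 0, 0.3)
    })
    list(table = ExpressionTable(ids, lfc, p), truth = truth)
  }

  sets <- .plantedSets(config)
  d1 <- drawTable(sets$all, "expression1")
  paths <- c(expr1 = file.path(outdir, "expr1.csv"),
             truth = file.path(outdir, "truth.csv"))
  writeExpressionTable(d1$table, paths[["expr1"]])
  tables <- list(d1$table)
  truth <- data.frame(gene_id = sets$all, dataset = 1L,
                      truth_class = d1$truth, stringsAsFactors = FALSE)

  if (twoDatasets) {
    n <- config@nGenes
    nShared <- round(config@overlapFrac * n)
    ids2 <- c(as.character(seq_len(nShared)),
              as.character(n + seq_len(n - nShared)))
    d2 <- drawTable(ids2, "expression2")
    paths <- c(paths, expr2 = file.path(outdir, "expr2.csv"))
    writeExpressionTable(d2$table, paths[["expr2"]])
    tables <- c(tables, list(d2$table))
    truth <- rbind(truth,
                   data.frame(gene_id = ids2, dataset = 2L,
                              truth_class = d2$truth,
                              stringsAsFactors = FALSE))
  }
  utils::write.csv(truth, paths[["truth"]], row.names = FALSE,
                   quote = FALSE)
  list(tables = tables, truth = truth, paths = paths)
}
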