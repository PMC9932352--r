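test_that("config invariants are enforced", {
  expect_s4_class(syntheticConfig(), "SyntheticConfig")
  expect_error(syntheticConfig(fracUp = 0.6, fracDown = 0.5), "fracUp")
  expect_error(syntheticConfig(nTermsPerNamespace = 1), "2 terms")
  expect_error(syntheticConfig(plantedTerms = data.frame(
    term_id = "GO:1000002", direction = "up",
    rate_de = 0.1, rate_bg = 0.5)), "rate_de")
})

test_that("toy ontology has three namespaces, three roots and parses back", {
  cfg <- syntheticConfig(seed = 5, nTermsPerNamespace = 2L)
  onto <- makeToyOntology(cfg)
  terms <- ontologyTerms(onto$dag)
  expect_equal(nrow(terms), 6L)
  expect_equal(as.integer(table(terms$namespace)), c(2L, 2L, 2L))
  roots <- terms$term_id[lengths(onto$dag@isAParents[terms$term_id]) == 0]
  expect_length(roots, 3L)

  bigger <- makeToyOntology(syntheticConfig(seed = 5))
  expect_s4_class(bigger$dag, "OntologyDAG")
  expect_equal(nrow(ontologyTerms(bigger$dag)), 24L)
})

test_that("fixture generation is byte-identical under a fixed seed", {
  cfg <- syntheticConfig(seed = 11, nGenes = 120L)
  o1 <- makeToyOntology(cfg); o2 <- makeToyOntology(cfg)
  expect_identical(readLines(o1$path), readLines(o2$path))
  a1 <- makeToyAnnotations(o1$dag, cfg)
  a2 <- makeToyAnnotations(o2$dag, cfg)
  expect_identical(readLines(a1$path), readLines(a2$path))
  s1 <- simulateExpression(cfg, twoDatasets = TRUE)
  s2 <- simulateExpression(cfg, twoDatasets = TRUE)
  expect_identical(readLines(s1$paths[["expr1"]]),
                   readLines(s2$paths[["expr1"]]))
  expect_identical(readLines(s1$paths[["expr2"]]),
                   readLines(s2$paths[["expr2"]]))
  # different seeds diverge
  s3 <- simulateExpression(syntheticConfig(seed = 12, nGenes = 120L))
  expect_false(identical(readLines(s1$paths[["expr1"]]),
                         readLines(s3$paths[["expr1"]])))
})

test_that("annotation rate boundaries are exact", {
  cfg <- syntheticConfig(seed = 3, nGenes = 50L,
                         nTermsPerNamespace = 3L,
                         bgAnnotationRate = 0,
                         plantedTerms = data.frame(
                           term_id = "GO:1000002", direction = "up",
                           rate_de = 1.0, rate_bg = 0,
                           stringsAsFactors = FALSE))
  onto <- makeToyOntology(cfg)
  ann <- makeToyAnnotations(onto$dag, cfg)$ann
  upGenes <- as.character(1:5)  # fracUp 0.1 of 50
  expect_setequal(ann@termToGenes[["GO:1000002"]], upGenes)
  # zero background: only the planted term carries annotations
  expect_identical(names(ann@termToGenes), "GO:1000002")
})

test_that("generated gene2go and OBO files satisfy their own readers", {
  cfg <- syntheticConfig(seed = 21, nGenes = 80L)
  onto <- makeToyOntology(cfg)
  ann <- makeToyAnnotations(onto$dag, cfg)$ann
  expect_s4_class(ann, "AnnotationSet")
  expect_false(isPropagated(ann))
  prop <- propagateAnnotations(ann, onto$dag)
  expect_true(all(names(prop@termToGenes) %in%
                    ontologyTerms(onto$dag)$term_id))
})

test_that("planted truth labels are recovered by classification", {
  cfg <- syntheticConfig(seed = 17)
  sim <- simulateExpression(cfg)
  ct <- classifyTable(sim$tables[[1L]], alpha = 0.05)
  truth <- sim$truth
  cls <- as.character(expressionClass(ct))
  up <- truth$truth_class == "Upregulated"
  down <- truth$truth_class == "Downregulated"
  # planted p-values are bounded below alpha and fold changes are signed,
  # so recovery of planted labels is essentially total
  expect_gte(mean(cls[up] == "Upregulated"), 0.9)
  expect_gte(mean(cls[down] == "Downregulated"), 0.9)
  # null genes reach significance at roughly the alpha rate, never en masse
  nullSel <- truth$truth_class == "Not differentially expressed"
  expect_lt(mean(cls[nullSel] != "Not differentially expressed"), 0.15)
})

test_that("a null configuration yields only chance-level DE calls", {
  cfg <- syntheticConfig(seed = 19, fracUp = 0, fracDown = 0,
                         nGenes = 500L)
  sim <- simulateExpression(cfg)
  expect_true(all(sim$truth$truth_class ==
                    "Not differentially expressed"))
  ct <- classifyTable(sim$tables[[1L]])
  deRate <- mean(expressionClass(ct) != "Not differentially expressed")
  expect_lt(deRate, 0.12)  # ~ alpha under the null
})

test_that("two-dataset mode shares the configured overlap of gene ids", {
  cfg <- syntheticConfig(seed = 23, nGenes = 200L, overlapFrac = 0.7)
  sim <- simulateExpression(cfg, twoDatasets = TRUE)
  ids1 <- geneIds(sim$tables[[1L]])
  ids2 <- geneIds(sim$tables[[2L]])
  expect_length(intersect(ids1, ids2), 140L)
  expect_length(ids2, 200L)
  expect_equal(nrow(sim$truth), 400L)
})

test_that("truth labels live in the sidecar, not the expression CSV", {
  cfg <- syntheticConfig(seed = 29, nGenes = 60L)
  sim <- simulateExpression(cfg)
  header <- readLines(sim$paths[["expr1"]], n = 1L)
  expect_identical(header, "GeneID,log2FC,pvalue")
  truthHeader <- readLines(sim$paths[["truth"]], n = 1L)
  expect_identical(truthHeader, "gene_id,dataset,truth_class")
})
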