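test_that("gene2go rows are filtered by taxon and NOT qualifier", {
  f <- toyGene2goFile(c(
    g2gRow("1", "GO:0000003"),
    g2gRow("2", "GO:0000003"),
    g2gRow("3", "GO:0000005"),
    g2gRow("9", "GO:0000003", tax = "10090")))
  ann <- readGene2go(f, taxon = 9606)
  expect_equal(sum(lengths(ann@geneToTerms)), 3L)
  expect_false(isPropagated(ann))
  expect_equal(ann@taxon, 9606L)

  fNot <- toyGene2goFile(c(
    g2gRow("1", "GO:0000003"),
    g2gRow("2", "GO:0000003", qualifier = "NOT"),
    g2gRow("3", "GO:0000003", qualifier = "NOT|contributes_to")))
  annNot <- readGene2go(fNot)
  expect_identical(names(annNot@geneToTerms), "1")
})

test_that("duplicate evidence rows collapse to one (gene, term) pair", {
  f <- toyGene2goFile(c(
    g2gRow("1", "GO:0000003"),
    g2gRow("1", "GO:0000003"),
    g2gRow("1", "GO:0000003")))
  ann <- readGene2go(f)
  expect_identical(ann@geneToTerms[["1"]], "GO:0000003")
  expect_identical(ann@termToGenes[["GO:0000003"]], "1")
})

test_that("gzip-compressed gene2go files read transparently", {
  plain <- toyGene2goFile(c(g2gRow("1", "GO:0000003"),
                            g2gRow("2", "GO:0000005")))
  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(plain), con)
  close(con)
  expect_identical(readGene2go(gz), readGene2go(plain))
})

test_that("missing columns or empty taxon are errors", {
  bad <- tempfile()
  writeLines(c("#tax_id\tGeneID\tGO_ID", "9606\t1\tGO:0000003"), bad)
  expect_error(readGene2go(bad), "lacks column")
  f <- toyGene2goFile(g2gRow("1", "GO:0000003", tax = "10090"))
  expect_error(readGene2go(f, taxon = 9606), "no annotation rows")
})

test_that("propagation closes annotations over is_a chains and diamonds", {
  dag <- parseOBO(toyOBOFile())
  # chain: gene 1 at GO:0000003 reaches the bp root through the mid term
  f <- toyGene2goFile(c(g2gRow("1", "GO:0000003"),
                        g2gRow("2", "GO:0000005")))
  prop <- propagateAnnotations(readGene2go(f), dag)
  expect_true(isPropagated(prop))
  expect_setequal(prop@geneToTerms[["1"]],
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  # diamond: gene 2 reaches GO:0000002 by two paths, annotated once
  expect_setequal(prop@geneToTerms[["2"]],
                  c("GO:0000005", "GO:0000003", "GO:0000004",
                    "GO:0000002", "GO:0000001"))
  expect_false(anyDuplicated(prop@geneToTerms[["2"]]) > 0)
  # gene set unchanged
  expect_setequal(names(prop@geneToTerms), c("1", "2"))
})

test_that("part_of propagation is off by default and additive when on", {
  dag <- parseOBO(toyOBOFile())
  f <- toyGene2goFile(g2gRow("1", "GO:0000005"))
  isaOnly <- propagateAnnotations(readGene2go(f), dag)
  withPO <- propagateAnnotations(readGene2go(f), dag, partOf = TRUE)
  expect_true(all(isaOnly@geneToTerms[["1"]] %in%
                    withPO@geneToTerms[["1"]]))
})

test_that("propagating an already-closed annotation set is a fixed point", {
  dag <- parseOBO(toyOBOFile())
  f <- toyGene2goFile(c(g2gRow("1", "GO:0000003"),
                        g2gRow("1", "GO:0000002"),
                        g2gRow("1", "GO:0000001")))
  ann <- readGene2go(f)
  prop <- propagateAnnotations(ann, dag)
  expect_setequal(prop@geneToTerms[["1"]], ann@geneToTerms[["1"]])
  expect_error(propagateAnnotations(prop, dag), "already propagated")
})

test_that("propagation equals per-gene brute-force closure on random DAGs", {
  set.seed(23)
  for (rep in 1:8) {
    parents <- randomParentList(sample(8:40, 1))
    dag <- parseOBO(parentListToOBO(parents))
    ids <- names(parents)
    genes <- as.character(1:15)
    rows <- unlist(lapply(genes, function(g) {
      terms <- sample(ids, sample(1:4, 1))
      vapply(terms, function(t) g2gRow(g, t), character(1))
    }))
    ann <- readGene2go(toyGene2goFile(rows))
    prop <- propagateAnnotations(ann, dag)
    # oracle: per gene, union of each direct term with its ancestors
    for (g in genes) {
      direct <- ann@geneToTerms[[g]]
      expected <- unique(unlist(lapply(direct, function(t) {
        c(t, bruteAncestors(parents, t))
      })))
      expect_setequal(prop@geneToTerms[[g]], expected)
    }
    # inverse-map consistency after propagation
    for (g in names(prop@geneToTerms)) {
      for (t in prop@geneToTerms[[g]]) {
        expect_true(g %in% prop@termToGenes[[t]])
      }
    }
  }
})

test_that("term counts only grow under propagation and parents dominate", {
  set.seed(29)
  parents <- randomParentList(20)
  dag <- parseOBO(parentListToOBO(parents))
  rows <- unlist(lapply(1:30, function(g) {
    vapply(sample(names(parents), 2L), function(t)
      g2gRow(as.character(g), t), character(1))
  }))
  ann <- readGene2go(toyGene2goFile(rows))
  prop <- propagateAnnotations(ann, dag)
  for (t in names(ann@termToGenes)) {
    expect_gte(length(prop@termToGenes[[t]]),
               length(ann@termToGenes[[t]]))
  }
  for (t in names(prop@termToGenes)) {
    for (p in parents[[t]]) {
      expect_gte(length(prop@termToGenes[[p]]),
                 length(prop@termToGenes[[t]]))
    }
  }
})

test_that("genesForTerm intersects with the universe and tolerates unknowns", {
  dag <- parseOBO(toyOBOFile())
  f <- toyGene2goFile(c(g2gRow("g1", "GO:0000003"),
                        g2gRow("g2", "GO:0000003")))
  ann <- readGene2go(f)
  expect_setequal(genesForTerm(ann, "GO:0000003", c("g1", "g3")), "g1")
  expect_length(genesForTerm(ann, "GO:9999999", c("g1")), 0L)
  expect_setequal(genesForTerm(ann, "GO:0000003", c("g1", "g2")),
                  c("g1", "g2"))
})
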