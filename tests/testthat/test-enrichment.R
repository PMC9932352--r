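test_that("hypergeometric upper tail matches closed-form spot values", {
  expect_identical(hypergeomUpperTail(0, 5, 4, 10), 1)
  expect_identical(hypergeomUpperTail(3, 3, 5, 5), 1)
  expect_equal(hypergeomUpperTail(3, 5, 4, 10), 11 / 42, tolerance = 1e-14)
})

test_that("upper tail equals exhaustive enumeration on a sampled grid", {
  set.seed(31)
  for (rep in 1:60) {
    N <- sample(1:12, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    for (k in 0:min(n, K)) {
      expect_equal(hypergeomUpperTail(k, n, K, N),
                   enumUpperTail(k, n, K, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("upper tail cross-checks against the survival function and stays stable for tiny tails", {
  cases <- list(c(20, 50, 30, 200), c(5, 10, 10, 1000),
                c(40, 40, 40, 5000), c(1, 3, 7, 12))
  for (cs in cases) {
    expect_equal(hypergeomUpperTail(cs[1], cs[2], cs[3], cs[4]),
                 stats::phyper(cs[1] - 1, cs[3], cs[4] - cs[3], cs[2],
                               lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # log-space evaluation keeps relative accuracy where naive sums underflow
  tiny <- hypergeomUpperTail(90, 100, 100, 10000)
  expect_gt(tiny, 0)
  expect_lt(tiny, 1e-100)
})

test_that("invalid hypergeometric bounds are rejected", {
  expect_error(hypergeomUpperTail(4, 3, 5, 10), "invalid")
  expect_error(hypergeomUpperTail(2, 5, 1, 10), "invalid")
  expect_error(hypergeomUpperTail(1, 11, 5, 10), "invalid")
})

test_that("BH adjustment reproduces hand-derived and oracle values", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bhAdjust(0.73), 0.73)
  expect_equal(bhAdjust(numeric(0)), numeric(0))
  expect_error(bhAdjust(c(0.1, 1.3)), "\\[0, 1\\]")
})

test_that("BH equals the step-up oracle on random vectors of varied length", {
  set.seed(37)
  for (rep in 1:200) {
    m <- sample(1:200, 1)
    p <- stats::runif(m)
    adj <- bhAdjust(p)
    expect_equal(adj, stepUpBH(p), tolerance = 1e-13)
    expect_equal(adj, stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-13)
    expect_true(all(adj >= p - 1e-15))
    # permutation equivariance
    perm <- sample.int(m)
    expect_equal(bhAdjust(p[perm]), adj[perm], tolerance = 1e-13)
  }
})

# small fully-specified enrichment scenario used by several blocks below
enrichScenario <- function() {
  dag <- parseOBO(toyOBOFile())
  universe <- as.character(1:100)
  # genes 1..5 annotated to the bp leaf; 6..30 and 31..35 elsewhere in
  # bp (so no two bp terms share identical propagated gene sets);
  # 1..50 annotated in mf so both namespaces are testable
  rows <- c(
    vapply(1:5, function(g) g2gRow(g, "GO:0000005"), character(1)),
    vapply(6:30, function(g) g2gRow(g, "GO:0000004"), character(1)),
    vapply(31:35, function(g) g2gRow(g, "GO:0000003"), character(1)),
    vapply(1:50, function(g) g2gRow(g, "GO:0000012",
                                    category = "Function"), character(1)))
  ann <- propagateAnnotations(readGene2go(toyGene2goFile(rows)), dag)
  list(dag = dag, ann = ann, universe = universe)
}

test_that("a study set equal to a term's annotated genes ranks that term first", {
  sc <- enrichScenario()
  run <- enrichStudy(as.character(1:5), "up", sc$ann, sc$dag,
                     sc$universe, alphaFdr = 0.05)
  res <- enrichmentResults(run)
  bp <- res[res$namespace == "biological_process", ]
  expect_identical(bp$term_id[1L], "GO:0000005")
  # oracle: direct hypergeometric evaluation over every bp term
  bpAnnotated <- unique(unlist(sc$ann@termToGenes[
    c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004",
      "GO:0000005")]))
  popNS <- intersect(sc$universe, bpAnnotated)
  studyNS <- intersect(as.character(1:5), popNS)
  for (i in seq_len(nrow(bp))) {
    genes <- sc$ann@termToGenes[[bp$term_id[i]]]
    k <- length(intersect(genes, studyNS))
    K <- length(intersect(genes, popNS))
    expect_equal(bp$p_value[i],
                 enumUpperTail(k, length(studyNS), K, length(popNS)),
                 tolerance = 1e-10)
  }
  expect_false(is.unsorted(bp$p_value))
})

test_that("per-namespace populations and study sizes are used", {
  sc <- enrichScenario()
  run <- enrichStudy(as.character(1:5), "up", sc$ann, sc$dag,
                     sc$universe)
  res <- enrichmentResults(run)
  expect_equal(unique(res$N[res$namespace == "biological_process"]), 35)
  expect_equal(unique(res$N[res$namespace == "molecular_function"]), 50)
  expect_equal(unique(res$n[res$namespace == "biological_process"]), 5)
  # percent uses the direction total, not the namespace-restricted study
  expect_equal(res$percent, 100 * res$k / 5)
})

test_that("degenerate study sets behave as documented", {
  sc <- enrichScenario()
  expect_warning(empty <- enrichStudy(character(0), "up", sc$ann, sc$dag,
                                      sc$universe), "empty")
  expect_equal(nrow(enrichmentResults(empty)), 0L)
  expect_warning(none <- enrichStudy("99", "down", sc$ann, sc$dag,
                                     sc$universe), "no annotated gene")
  expect_equal(nrow(enrichmentResults(none)), 0L)
  # study = universe makes every upper tail exactly 1
  all_ <- enrichStudy(sc$universe, "up", sc$ann, sc$dag, sc$universe)
  expect_true(all(enrichmentResults(all_)$p_value == 1))
  expect_error(enrichStudy("not-in-universe", "up", sc$ann, sc$dag,
                           sc$universe), "subset")
})

test_that("ancestors dominate descendants in study and population counts", {
  sc <- enrichScenario()
  run <- enrichStudy(as.character(1:5), "up", sc$ann, sc$dag, sc$universe)
  res <- enrichmentResults(run)
  byId <- function(col, id) res[[col]][res$term_id == id]
  for (id in c("GO:0000003", "GO:0000004", "GO:0000005")) {
    anc <- termAncestors(sc$dag, id, "is_a")
    for (a in intersect(anc, res$term_id)) {
      expect_gte(byId("k", a), byId("k", id))
      expect_gte(byId("K", a), byId("K", id))
    }
  }
})

test_that("significance filtering keeps over-represented terms only", {
  res <- data.frame(
    term_id = c("GO:0000001", "GO:0000002", "GO:0000003"),
    name = c("a", "b", "c"),
    namespace = "biological_process",
    direction = "up",
    k = c(5L, 2L, 1L), n = 10L, K = c(6L, 30L, 40L), N = 100L,
    p_value = c(0.0001, 0.2, 0.01),
    fdr = c(0.001, 0.2, 0.01),
    fold = c(3, 1.2, 0.25),
    percent = c(50, 20, 10),
    stringsAsFactors = FALSE)
  run <- new("EnrichmentRun", results = res, alphaFdr = 0.05,
             universeSize = 100L)
  kept <- enrichmentResults(significantTerms(run))
  # fdr 0.2 dropped; fold < 1 dropped despite small fdr
  expect_identical(kept$term_id, "GO:0000001")
})

test_that("term percentages follow the definition and reject bad input", {
  expect_equal(termPercentage(4, 10), 40)
  expect_equal(termPercentage(0, 10), 0)
  expect_equal(termPercentage(10, 10), 100)
  expect_error(termPercentage(1, 0), "at least 1")
  expect_error(termPercentage(11, 10))
})

test_that("bonferroni correction is available and per-family", {
  sc <- enrichScenario()
  bh <- enrichStudy(as.character(1:5), "up", sc$ann, sc$dag, sc$universe)
  bf <- enrichStudy(as.character(1:5), "up", sc$ann, sc$dag, sc$universe,
                    mtMethod = "bonferroni")
  resBH <- enrichmentResults(bh); resBF <- enrichmentResults(bf)
  expect_identical(resBH$p_value, resBF$p_value)
  for (ns in unique(resBF$namespace)) {
    sel <- resBF$namespace == ns
    expect_equal(resBF$fdr[sel], pmin(1, sum(sel) * resBF$p_value[sel]))
  }
})

test_that("runEnrichment analyses directions separately and warns on id mismatch", {
  sc <- enrichScenario()
  tab <- ExpressionTable(sc$universe,
                         c(rep(2, 5), rep(-2, 5), rep(0.1, 90)),
                         c(rep(0.001, 10), rep(0.9, 90)))
  ct <- classifyTable(tab)
  run <- runEnrichment(ct, sc$ann, sc$dag)
  res <- enrichmentResults(run)
  expect_setequal(unique(res$direction), c("up", "down"))
  upBP <- res[res$direction == "up" & res$namespace == "biological_process", ]
  expect_identical(upBP$term_id[1L], "GO:0000005")
  # unmatched-id warning: universe mostly absent from the annotations
  bigTab <- classifyTable(ExpressionTable(paste0("SYM", 1:100),
                                          rep(1, 100), rep(0.5, 100)))
  w <- capture_warnings(runEnrichment(bigTab, sc$ann, sc$dag))
  expect_match(w, "gene-id space", all = FALSE)
})

test_that("enrichment TSV output round-trips the result table", {
  sc <- enrichScenario()
  run <- enrichStudy(as.character(1:5), "up", sc$ann, sc$dag, sc$universe)
  f <- tempfile(fileext = ".tsv")
  writeEnrichmentTSV(run, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_identical(back$term_id, enrichmentResults(run)$term_id)
  expect_equal(back$p_value, enrichmentResults(run)$p_value)
})
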