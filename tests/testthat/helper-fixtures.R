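# Shared fixture builders and independent oracles for the test suite.

writeCSVFixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# A small hand-written ontology: a diamond in biological_process
# (T5 -> {T3, T4} -> T2 -> T1 root), one molecular_function chain and one
# cellular_component pair, plus an obsolete term and an alt_id.
toyOBOText <- function() {
  c("format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: bp root",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: bp mid",
    "namespace: biological_process",
    "alt_id: GO:0000099",
    "is_a: GO:0000001 ! bp root",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: bp left",
    "namespace: biological_process",
    "is_a: GO:0000002 ! bp mid",
    "",
    "[Term]",
    "id: GO:0000004",
    "name: bp right",
    "namespace: biological_process",
    "is_a: GO:0000002 ! bp mid",
    "",
    "[Term]",
    "id: GO:0000005",
    "name: bp leaf",
    "namespace: biological_process",
    "is_a: GO:0000003 ! bp left",
    "is_a: GO:0000004 ! bp right",
    "relationship: part_of GO:0000001 ! bp root",
    "",
    "[Term]",
    "id: GO:0000011",
    "name: mf root",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0000012",
    "name: mf leaf",
    "namespace: molecular_function",
    "is_a: GO:0000011 ! mf root",
    "",
    "[Term]",
    "id: GO:0000021",
    "name: cc root",
    "namespace: cellular_component",
    "",
    "[Term]",
    "id: GO:0000022",
    "name: cc leaf",
    "namespace: cellular_component",
    "is_a: GO:0000021 ! cc root",
    "",
    "[Term]",
    "id: GO:0000091",
    "name: gone",
    "namespace: biological_process",
    "is_obsolete: true")
}

toyOBOFile <- function(path = tempfile(fileext = ".obo")) {
  writeLines(toyOBOText(), path)
  path
}

# gene2go rows as tab-joined strings; header included
toyGene2goFile <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste0("#", paste(c("tax_id", "GeneID", "GO_ID", "Evidence",
                                "Qualifier", "GO_term", "PubMed",
                                "Category"), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

g2gRow <- function(gene, term, tax = "9606", qualifier = "-",
                   category = "Process") {
  paste(tax, gene, term, "IEA", qualifier, "some term", "-", category,
        sep = "\t")
}

# ---- independent oracles -------------------------------------------------

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws:
# the population is 1..N with 1..K annotated.
enumUpperTail <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)  # unreachable when k >= 1 given bounds
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# BH step-up by the direct definition min_{j >= i} m * p_(j) / j.
stepUpBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  adj[order(ord)]
}

# Ancestors by repeated single-step edge expansion until a fixed point.
bruteAncestors <- function(parentList, term) {
  anc <- character(0)
  frontier <- term
  repeat {
    step <- unique(unlist(parentList[frontier], use.names = FALSE))
    new <- setdiff(step, anc)
    if (!length(new)) break
    anc <- c(anc, new)
    frontier <- new
  }
  sort(anc)
}

# Random DAG as a parent list: term i may point to any earlier terms.
randomParentList <- function(nTerms, pEdge = 0.3) {
  ids <- sprintf("GO:%07d", seq_len(nTerms))
  parents <- stats::setNames(vector("list", nTerms), ids)
  for (i in seq_len(nTerms)) {
    if (i == 1L) { parents[[i]] <- character(0); next }
    cand <- ids[seq_len(i - 1L)]
    pick <- cand[stats::runif(i - 1L) < pEdge]
    if (!length(pick)) pick <- sample(cand, 1L)
    parents[[ids[i]]] <- pick
  }
  parents
}

# Serialise a parent list as a one-namespace OBO file.
parentListToOBO <- function(parents, path = tempfile(fileext = ".obo"),
                            namespace = "biological_process") {
  stanzas <- vapply(names(parents), function(id) {
    paste(c("[Term]",
            paste0("id: ", id),
            paste0("name: term ", id),
            paste0("namespace: ", namespace),
            sprintf("is_a: %s ! p", parents[[id]])),
          collapse = "\n")
  }, character(1))
  writeLines(paste0("format-version: 1.2\n\n",
                    paste(stanzas, collapse = "\n\n")), path)
  path
}

randomExpressionTable <- function(n, prefix = "G") {
  ExpressionTable(paste0(prefix, seq_len(n)),
                  stats::rnorm(n),
                  stats::runif(n))
}
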