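---
title: "Classifying differential expression and mapping it onto the Gene Ontology"
author: "degscope maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying differential expression and mapping it onto the Gene Ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degscope)
```

# Scope and model

`degscope` works on *processed* expression tables: one row per gene with a
log2 fold change and a p-value from an upstream case-vs-control analysis
(microarray or RNA-seq; the package performs no normalisation or raw-signal
statistics of its own). On top of such tables it provides two pipelines:

1. **Single dataset** — classify every gene, draw a volcano plot, and run a
   Gene Ontology over-representation analysis (ORA) separately for the up-
   and down-regulated sets in each of the three GO namespaces (biological
   process, molecular function, cellular component), rendering up to six
   barplots of the significant terms.
2. **Two datasets** — classify both tables under one threshold, join them
   on their common genes, and summarise agreement in a 3×3
   expression-class contingency table.

## Expression classification

Classification is a fixed three-way rule at a significance threshold
$\alpha$ (default 0.05, the conventional 5% level):

* $p \ge \alpha$: *Not differentially expressed*;
* $p < \alpha$ and $\mathrm{logFC} > 0$: *Upregulated*;
* $p < \alpha$ and $\mathrm{logFC} < 0$: *Downregulated*.

The rule uses the **sign** of the fold change only; no magnitude cutoff is
offered, deliberately, so the class partition depends on exactly one
tunable. Two boundary cases are undefined by the inequalities above and
are resolved conservatively: $p = \alpha$ exactly is treated as not
significant (significance requires strict inequality), and a significant
gene with $\mathrm{logFC} = 0$ exactly stays unclassified as DE (it is kept
in the *Not differentially expressed* class, with a warning, since a fold
change of exactly zero almost always indicates degenerate input rather
than biology). Whatever p-value the upstream analysis produced — raw or
already adjusted — is used as-is; the package does not second-guess the
input's multiplicity handling, and this should be kept in mind when
choosing $\alpha$.

For the volcano plot, the y coordinate is $-\log_{10} p$ with $p$ floored
at $10^{-300}$ so that $p = 0$ (as printed by some upstream tools) stays
finite; the floor affects only plotting, never classification.

## Over-representation analysis

For a study set $S$ (the up- or the down-regulated genes, never pooled)
and a background universe $U$, each term $t$ with at least one annotated
study gene is scored with the hypergeometric upper tail

$$
P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),
$$

with $k$ the annotated study genes, $n$ the annotated study size, $K$ the
annotated universe genes and $N$ the annotated universe size. The tail is
summed in log space (log-binomial coefficients combined by log-sum-exp), so
p-values in the $10^{-100}$ range keep full relative accuracy instead of
underflowing.

Annotations are first **propagated**: each gene's direct GO annotations
are closed over `is_a` ancestors (the true-path rule), so a gene counted
for a specific term is also counted for every more general term.
`part_of` edges are parsed but excluded from propagation by default —
`is_a` is the one relation that is universally safe to propagate over —
and can be enabled explicitly.

Design choices that were genuinely open, and how they were fixed:

* **Universe** — the genes present in the input expression table,
  restricted per namespace to genes with at least one propagated
  annotation in that namespace. The genes a platform measured are the
  natural background for what it can report as enriched; the whole
  annotated genome is available as an alternative through the `universe`
  argument.
* **Multiplicity** — Benjamini–Hochberg at 0.05, applied *within each
  (direction, namespace) family independently* — six separate corrections,
  mirroring the six reported analyses. Bonferroni is available via
  `mtMethod`.
* **Reporting direction** — only over-represented terms (fold enrichment
  $(k/n)/(K/N) > 1$) are reported as significant and plotted; depleted
  terms are computed but filtered out, since the barplots describe genes
  *associated with* ontology terms.
* **Barplot statistic** — the x-axis is $100 \cdot k / |S|$: the
  percentage of all genes in the direction annotated to the term, with
  $|S|$ the full direction total rather than its annotated subset, so
  percentages remain comparable across namespaces. Bars are sorted by
  descending percentage, and at most 20 terms (smallest p first) are drawn
  per plot for readability; the full table is always written as TSV.

## Identifier spaces

NCBI gene2go annotations key genes by Entrez GeneID. The expression table
must use the same identifier space; no symbol↔Entrez translation is
attempted, because silent cross-space matching is a classic source of
wrong enrichments. When more than half of the universe has no annotation
at all, the analysis warns loudly — that pattern is nearly always an
identifier mismatch rather than biology. Similarly, the two-dataset join
is exact, case-sensitive string matching, with an explicit opt-in
(`normalizeIds = "upper"`) for case folding.

# The synthetic-data generators

Every stage is testable offline through three deterministic generators,
driven by one master seed. Each generator draws from its own named
pseudorandom stream derived from that seed, so adding a generator never
perturbs the fixtures another one produces.

* `makeToyOntology()` builds three rooted trees (one per namespace, 8
  terms each by default) with occasional extra `is_a` edges, making true
  DAGs with diamond motifs, serialised as parseable OBO. The index-2 term
  of each namespace is kept leaf-level by construction: it is the slot
  where signal is planted, and a planted term that acquired descendants
  would have its specificity diluted by the descendants' background
  annotations after propagation.
* `makeToyAnnotations()` annotates each gene to the ontology's leaf terms
  at a background rate of 0.1 and annotates the planted DE gene block to
  the planted term at rate 0.8 (others at that term's own background
  rate), written as valid gene2go for taxon 9606.
* `simulateExpression()` draws 1000 genes by default: 10% planted
  up-regulated with $p \sim U(10^{-6}, 0.025)$ and
  $\mathrm{logFC} = |N(2,\, 0.4)|$, 10% down-regulated mirrored negative,
  and the rest null ($p \sim U(0,1)$, $\mathrm{logFC} \sim N(0, 0.3)$).
  Planted p-values are bounded below $\alpha/2$, so label recovery by the
  classifier is essentially total and deviations in tests indicate real
  defects, not sampling noise. Truth labels go to a sidecar CSV so the
  expression files are indistinguishable from real inputs. Two-dataset
  mode shares 80% of gene ids between the tables.

These defaults were chosen as a realistic desk-scale emulation of a
processed differential-expression table: DE fractions around 10% per
direction, effect sizes around 2 log2 units, and annotation rates that
make the planted term clearly but not trivially enriched. What the
fixtures deliberately do **not** emulate: intensity-level noise, probe
effects, correlated genes, annotation bias toward well-studied genes, and
the scale (tens of thousands of genes, tens of thousands of GO terms) of
real data. Passing tests therefore demonstrate correctness of the rules
and statistics, not robustness to real-data pathologies.

# Numerical and degenerate-input behaviour

* Hypergeometric tails are exact sums in log space; `k = 0` returns 1
  exactly, and the test suite verifies agreement with exhaustive
  enumeration over every population of size ≤ 12.
* BH adjustment is the step-up rule $\min_{j \ge i} m\,p_{(j)}/j$ capped
  at 1, returned in input order; ties and permutations are handled by
  construction.
* Enrichment results are ordered by ascending p-value with the term id as
  a deterministic tie-break, so repeated runs produce byte-identical
  tables.
* Duplicate gene ids in an input CSV are a hard error by default
  (duplicates silently corrupt both class counts and the ORA universe);
  an explicit `keep-min-p` aggregation is available. Rows with missing or
  unparseable values are dropped, warned about and counted — never
  imputed. An empty study set, an empty gene intersection between two
  datasets, or a namespace without testable terms each produce an empty
  result plus a warning, not an error, so batch runs degrade gracefully.
* Ontology loading fails fast on cycles (checked by topological sort),
  dangling parent references, and ambiguous `alt_id` claims; obsolete
  terms are indexed for id resolution but excluded from queries.

# Problem sizes used in the test suite

The shipped tests run the full pipeline on the default 1000-gene, 24-term
configuration; the property-style checks use 50 random DAGs of up to 60
terms for propagation, the complete $N \le 12$ grid for the
hypergeometric oracle, 1000 random vectors for BH, and 100 seeded
replicates for planted-term recovery, where the planted biological-process
term must rank first among up-regulated BP terms in at least 95 runs.
These sizes keep the suite fast while leaving each statistic's behaviour
fully exercised.

# Worked example

```{r example, eval = FALSE}
fixtures <- runSimulate(seed = 1, outdir = "fixtures")
manifest <- runAnalyze(fixtures$expr1, fixtures$obo, fixtures$gene2go,
                       outdir = "out")
manifest$class_counts
cmp <- runCompare(fixtures$expr1, fixtures$expr2, outdir = "out2")
cmp$contingency
```

# Known limitations

* ORA only: no rank-based (GSEA-style) enrichment, no term clustering or
  redundancy reduction, no KEGG or other non-GO vocabularies.
* OBO support covers the go-basic dialect (`is_a`, `part_of`, `alt_id`,
  obsoletion); `regulates`-type relations, cross-namespace edges and OWL
  are out of scope.
* gene2go is the only annotation format (GAF/GPAD are not read), and no
  identifier translation is performed.
* The comparison pipeline reports agreement counts only; it deliberately
  computes no meta-analysis statistics (no combined p-values, no
  concordance tests).
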