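#' @include AllGenerics.R
NULL

#' Parse a GO ontology in OBO flat-file format
#'
#' Reads an OBO 1.2/1.4 file (the go-basic dialect) into an
#' [OntologyDAG-class]. Only the tags `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, `alt_id` and `is_obsolete` are honoured; other
#' tags (`def`, `synonym`, `xref`, ...) and `[Typedef]` stanzas are skipped
#' silently. `is_a` and `relationship` targets are parsed up to the `" ! "`
#' comment. Obsolete terms are indexed but excluded from queries. The load
#' fails on a malformed stanza, a parent reference to a term that does not
#' exist (or is obsolete), an alternative id claimed by two terms, or a
#' cycle in the combined is_a/part_of graph.
#'
#' @param path path to an OBO file.
#' @return An [OntologyDAG-class].
#' @seealso [termAncestors()], [resolveTerm()]
#' @export
parseOBO <- function(path) {
  if (!file.exists(path)) {
    stop("OBO file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\\r$", "", lines)

  # stanza boundaries
  headerIdx <- grep("^\\[", lines)
  if (!length(headerIdx)) {
    stop("no stanzas found in ", path)
  }
  stanzaType <- lines[headerIdx]
  stanzaEnd <- c(headerIdx[-1L] - 1L, length(lines))

  ids <- character(); names_ <- character(); namespaces <- character()
  obsolete <- logical()
  isA <- list(); partOf <- list(); altList <- list()

  for (s in seq_along(headerIdx)) {
    if (stanzaType[s] != "[Term]") next
    body <- lines[(headerIdx[s] + 1L):stanzaEnd[s]]
    body <- body[nzchar(body)]
    keyed <- regmatches(body, regexec("^([A-Za-z_]+): (.*)$", body))
    keys <- vapply(keyed, function(m) if (length(m)) m[2L] else NA_character_,
                   character(1))
    vals <- vapply(keyed, function(m) if (length(m)) m[3L] else NA_character_,
                   character(1))
    id <- vals[keys == "id"]
    if (length(id) != 1L) {
      stop("stanza without a single id near line ", headerIdx[s])
    }
    nm <- vals[keys == "name"]
    ns <- vals[keys == "namespace"]
    obs <- any(keys == "is_obsolete" & grepl("^true", vals))
    if (!obs && (length(nm) != 1L || length(ns) != 1L)) {
      stop("term ", id, " lacks a name or namespace")
    }
    stripTarget <- function(x) trimws(sub(" ! .*$", "", x))
    isaTargets <- stripTarget(vals[keys == "is_a"])
    relVals <- vals[keys == "relationship"]
    poTargets <- stripTarget(sub("^part_of +", "",
                                 relVals[grepl("^part_of ", relVals)]))
    ids <- c(ids, id)
    names_ <- c(names_, if (length(nm)) nm[1L] else "")
    namespaces <- c(namespaces, if (length(ns)) ns[1L] else "")
    obsolete <- c(obsolete, obs)
    isA[[id]] <- isaTargets
    partOf[[id]] <- poTargets
    altList[[id]] <- vals[keys == "alt_id"]
  }

  if (anyDuplicated(ids)) {
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  keep <- !obsolete
  live <- ids[keep]
  terms <- data.frame(term_id = live,
                      name = names_[keep],
                      namespace = namespaces[keep],
                      stringsAsFactors = FALSE)
  isA <- isA[live]
  partOf <- partOf[live]

  allParents <- unique(c(unlist(isA), unlist(partOf)))
  dangling <- setdiff(allParents, live)
  if (length(dangling)) {
    stop("parent reference(s) to missing or obsolete term(s): ",
         paste(utils::head(dangling, 5L), collapse = ", "))
  }

  # alt_id index over all stanzas (obsolete terms keep their alt ids indexed)
  altFlat <- unlist(altList, use.names = FALSE)
  altOwner <- rep(names(altList), lengths(altList))
  if (anyDuplicated(altFlat)) {
    stop("alt_id claimed by more than one term: ",
         paste(unique(altFlat[duplicated(altFlat)]), collapse = ", "))
  }
  clash <- intersect(altFlat, ids)
  if (length(clash)) {
    stop("alt_id collides with a primary id: ",
         paste(clash, collapse = ", "))
  }
  altIds <- if (length(altFlat)) stats::setNames(altOwner, altFlat)
            else stats::setNames(character(0), character(0))

  dag <- new("OntologyDAG",
             terms = terms,
             isAParents = isA,
             partOfParents = partOf,
             altIds = altIds,
             obsoleteIds = ids[obsolete])
  .checkAcyclic(dag)
  dag
}

# Kahn topological sort over the union of is_a and part_of edges; errors on
# a cycle. Also returns the order (children before parents) for reuse.
.checkAcyclic <- function(dag) {
  ids <- dag@terms$term_id
  parents <- mapply(function(a, b) unique(c(a, b)),
                    dag@isAParents, dag@partOfParents,
                    SIMPLIFY = FALSE)
  # out-degree = number of parents; repeatedly remove terms with none left
  remaining <- parents
  order <- character(0)
  noParent <- names(remaining)[lengths(remaining) == 0L]
  childrenOf <- list()
  for (id in ids) {
    for (p in parents[[id]]) {
      childrenOf[[p]] <- c(childrenOf[[p]], id)
    }
  }
  # invert: process parents-first is equivalent; here we peel leaves upward
  deg <- lengths(remaining)
  queue <- names(deg)[deg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    seen <- seen + 1L
    order <- c(order, t)
    for (ch in childrenOf[[t]]) {
      deg[ch] <- deg[ch] - 1L
      if (deg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(ids)) {
    stop("cycle detected in ontology graph (",
         length(ids) - seen, " term(s) unreachable from roots)")
  }
  invisible(order)
}

#' Resolve a GO identifier to its canonical term id
#'
#' Primary ids resolve to themselves; alternative ids resolve to the term
#' that lists them. Unknown ids, and ids that only refer to obsolete terms,
#' raise an error.
#'
#' @param dag an [OntologyDAG-class].
#' @param id a GO identifier.
#' @return The canonical term id (character scalar).
#' @export
resolveTerm <- function(dag, id) {
  stopifnot(is(dag, "OntologyDAG"), length(id) == 1L)
  if (id %in% dag@terms$term_id) {
    return(id)
  }
  if (id %in% names(dag@altIds)) {
    canon <- unname(dag@altIds[[id]])
    if (canon %in% dag@terms$term_id) {
      return(canon)
    }
    stop("id ", id, " resolves only to obsolete term ", canon)
  }
  if (id %in% dag@obsoleteIds) {
    stop("term ", id, " is obsolete")
  }
  stop("unknown term id: ", id)
}

#' Ancestors of a term
#'
#' Transitive closure of the selected parent relations, excluding the term
#' itself. With `relations = "is_a"` only (the default elsewhere in the
#' package), all ancestors share the query term's namespace.
#'
#' @param dag an [OntologyDAG-class].
#' @param termId a GO id, primary or alternative.
#' @param relations subset of `c("is_a", "part_of")`.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
termAncestors <- function(dag, termId, relations = c("is_a", "part_of")) {
  stopifnot(is(dag, "OntologyDAG"))
  relations <- match.arg(relations, several.ok = TRUE)
  start <- resolveTerm(dag, termId)
  parentsOf <- function(t) {
    out <- character(0)
    if ("is_a" %in% relations) out <- c(out, dag@isAParents[[t]])
    if ("part_of" %in% relations) out <- c(out, dag@partOfParents[[t]])
    out
  }
  seen <- character(0)
  frontier <- parentsOf(start)
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
    frontier <- unlist(lapply(frontier, parentsOf), use.names = FALSE)
  }
  seen
}

# Ancestor sets for every term at once (memoised along a topological order,
# parents before reuse). relations as in termAncestors. Used by annotation
# propagation, where per-term queries would be quadratic.
.allAncestors <- function(dag, relations = "is_a") {
  ids <- dag@terms$term_id
  parents <- if (identical(relations, "is_a")) {
    dag@isAParents
  } else {
    mapply(function(a, b) unique(c(a, b)),
           dag@isAParents, dag@partOfParents, SIMPLIFY = FALSE)
  }
  order <- .checkAcyclic(dag)  # roots first
  anc <- stats::setNames(vector("list", length(ids)), ids)
  for (t in order) {
    ps <- if (identical(relations, "is_a")) dag@isAParents[[t]]
          else parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}
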