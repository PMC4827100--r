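#' Construct an ontology from a parent map
#'
#' Builds an immutable rooted DAG of terms connected by "is-a" edges from a
#' named list mapping each term to its direct parents. The constructor checks
#' acyclicity, identifies the root (the unique term without parents), and
#' precomputes the ancestor closure of every term.
#'
#' @param parents Named list; `parents[[t]]` is a character vector of the
#'   direct is-a parents of term `t` (empty or `NULL` for the root).
#' @param name Optional named character vector of human-readable labels.
#' @param root Optional term ID. Required when more than one term lacks
#'   parents, in which case terms that are not descendants of `root` are
#'   dropped.
#' @param alt Named character vector mapping alternative (secondary) IDs to
#'   canonical term IDs.
#' @return An object of class `"phe_ontology"` with elements `id` (terms in
#'   topological order, root first), `name`, `parents`, `children`,
#'   `ancestors` (each term plus all of its transitive ancestors), `root`
#'   and `alt`.
#' @seealso [read_obo()], [term_ancestors()], [minimal_set()]
#' @export
phe_ontology <- function(parents, name = NULL, root = NULL, alt = character()) {
  ids <- names(parents)
  if (is.null(ids) || anyDuplicated(ids))
    stop("'parents' must be a uniquely named list of terms")
  parents <- lapply(parents, function(p) {
    p <- as.character(p[!is.na(p)])
    unique(p)
  })
  names(parents) <- ids
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown))
    stop("parent terms not present in the ontology: ",
         paste(unknown, collapse = ", "))

  roots <- ids[vapply(parents, length, 1L) == 0L]
  if (length(roots) == 0L)
    stop("no root term found (cycle through every term?)")
  if (length(roots) > 1L) {
    if (is.null(root))
      stop("multiple root terms found (",
           paste(roots, collapse = ", "),
           "); supply 'root' to select one")
    if (!root %in% ids) stop("requested root '", root, "' is not a term")
  } else {
    if (is.null(root)) root <- roots
  }

  # Kahn topological sort; also the cycle check
  indeg <- vapply(parents, length, 1L)
  children <- lapply(ids, function(i) character(0))
  names(children) <- ids
  for (t in ids) for (p in parents[[t]])
    children[[p]] <- c(children[[p]], t)
  queue <- roots
  topo <- character(0)
  indeg_w <- indeg
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg_w[[ch]] <- indeg_w[[ch]] - 1L
      if (indeg_w[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(ids))
    stop("cycle detected in ontology (terms involved: ",
         paste(utils::head(setdiff(ids, topo), 5L), collapse = ", "), ")")

  # restrict to descendants of the chosen root
  anc <- vector("list", length(ids))
  names(anc) <- ids
  for (t in topo) {
    ps <- parents[[t]]
    anc[[t]] <- if (length(ps))
      unique(c(t, unlist(anc[ps], use.names = FALSE))) else t
  }
  keep <- ids[vapply(anc, function(a) root %in% a, TRUE)]
  if (length(keep) < length(ids)) {
    drop <- setdiff(ids, keep)
    parents <- lapply(parents[keep], function(p) intersect(p, keep))
    children <- lapply(children[keep], function(cset) intersect(cset, keep))
    anc <- lapply(anc[keep], function(a) intersect(a, keep))
    topo <- topo[topo %in% keep]
    alt <- alt[alt %in% keep]
    ids <- keep
  }

  nm <- structure(character(length(ids)), names = ids)
  if (!is.null(name)) {
    common <- intersect(names(name), ids)
    nm[common] <- name[common]
  }
  structure(
    list(id = topo, name = nm, parents = parents[topo],
         children = children[topo], ancestors = anc[topo],
         root = root, alt = alt),
    class = "phe_ontology")
}

#' @export
print.phe_ontology <- function(x, ...) {
  cat("Ontology: ", length(x$id), " terms, root ", x$root,
      if (nzchar(x$name[[x$root]])) paste0(" (", x$name[[x$root]], ")"),
      "\n", sep = "")
  nleaf <- sum(vapply(x$children, length, 1L) == 0L)
  cat("  ", nleaf, " leaf terms; ", length(x$alt),
      " alternative IDs\n", sep = "")
  invisible(x)
}

#' Read an ontology from an OBO flat file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file, retaining only `is_a`
#' edges. Obsolete terms are dropped and their edges removed; `alt_id`
#' entries are recorded so that annotations using secondary IDs resolve to
#' the canonical term.
#'
#' @param path Path to an OBO file.
#' @param root Optional root term ID, required if the file contains several
#'   connected components (see [phe_ontology()]).
#' @return A `"phe_ontology"` object.
#' @export
read_obo <- function(path, root = NULL) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanza found in ", path)
  stanza_starts <- grep("^\\[", lines)
  ends <- c(stanza_starts[-1L] - 1L, length(lines))
  id <- character(0); nm <- character(0)
  parents <- list(); alt <- character(0); obsolete <- character(0)
  for (s in term_starts) {
    e <- ends[match(s, stanza_starts)]
    block <- lines[(s + 1L):e]
    kv <- regmatches(block, regexec("^([A-Za-z_]+):\\s*(.*)$", block))
    kv <- kv[vapply(kv, length, 1L) == 3L]
    keys <- vapply(kv, `[[`, "", 2L)
    vals <- vapply(kv, `[[`, "", 3L)
    tid <- vals[keys == "id"][1L]
    if (is.na(tid)) next
    tid <- trimws(tid)
    if (any(keys == "is_obsolete" & trimws(vals) == "true")) {
      obsolete <- c(obsolete, tid)
      next
    }
    isa <- vals[keys == "is_a"]
    isa <- trimws(vapply(strsplit(isa, "!", fixed = TRUE), `[[`, "", 1L))
    tname <- trimws(vals[keys == "name"][1L])
    aids <- trimws(vals[keys == "alt_id"])
    id <- c(id, tid)
    nm[tid] <- if (is.na(tname)) "" else tname
    parents[[tid]] <- isa
    if (length(aids)) alt[aids] <- tid
  }
  if (anyDuplicated(id)) stop("duplicated term IDs in ", path)
  # edges pointing at obsolete or unknown terms are dropped
  parents <- lapply(parents, function(p) p[p %in% id])
  phe_ontology(parents, name = nm, root = root, alt = alt)
}

# Resolve possibly-alternative IDs to canonical IDs; error on unknown terms
# unless drop = TRUE, in which case unknown terms are removed with a count
# attached as an attribute.
resolve_terms <- function(ontology, terms, drop = FALSE) {
  terms <- as.character(terms)
  hit <- match(terms, names(ontology$alt))
  terms[!is.na(hit)] <- ontology$alt[hit[!is.na(hit)]]
  known <- terms %in% ontology$id
  if (all(known)) return(terms)
  if (!drop)
    stop("unknown ontology term(s): ",
         paste(unique(terms[!known]), collapse = ", "))
  structure(terms[known], n_dropped = sum(!known),
            dropped = unique(terms[!known]))
}

#' Term plus all of its ancestors
#'
#' Returns the set `anc(t)`: the term itself together with every term
#' reachable from it through is-a edges. `anc(t)` always contains the root.
#'
#' @param ontology A `"phe_ontology"` object.
#' @param term A single term ID (alternative IDs are resolved).
#' @return Character vector of term IDs.
#' @export
term_ancestors <- function(ontology, term) {
  term <- resolve_terms(ontology, term)
  if (length(term) != 1L) stop("'term' must be a single term ID")
  ontology$ancestors[[term]]
}

#' Reduce a term vector to its minimal set
#'
#' Deduplicates and removes every term that is a strict ancestor of another
#' member, leaving an antichain: a redundancy-free phenotype encoding in
#' which no member implies another (for instance a set containing both
#' "Abnormal bleeding" and "Joint hemorrhage" reduces to the more specific
#' "Joint hemorrhage"). The reduction is idempotent and does not depend on
#' the input order.
#'
#' @param ontology A `"phe_ontology"` object.
#' @param terms Character vector of term IDs (duplicates allowed).
#' @return Character vector: the minimal set, in ontology (topological)
#'   order. May be empty if `terms` is empty.
#' @export
minimal_set <- function(ontology, terms) {
  if (!length(terms)) return(character(0))
  terms <- unique(resolve_terms(ontology, terms))
  # pool every member's strict ancestors; members found in the pool are implied
  strict_anc <- unique(unlist(
    lapply(terms, function(t) setdiff(ontology$ancestors[[t]], t)),
    use.names = FALSE))
  keep <- terms[!terms %in% strict_anc]
  keep[order(match(keep, ontology$id))]
}

#' Annotation-propagated information content
#'
#' Computes, for every ontology term, the frequency with which it is
#' annotated in a collection of subject phenotypes, counting implicit
#' annotation through more specific descendant terms, and returns the
#' information content `-log(frequency)` in nats. Terms annotated in no
#' subject receive infinite IC and are regarded as unusable for the
#' characteristic-phenotype search space (see [usable_terms()]).
#'
#' @param ontology A `"phe_ontology"` object.
#' @param phenotypes List of character vectors, one per subject (empty
#'   phenotypes allowed; they only contribute to the denominator).
#' @param smooth If `TRUE`, add-one smoothing `(n_t + 1) / (N + 1)` is
#'   applied so no term has infinite IC. Default `FALSE`, matching
#'   frequency derived purely from appearance in the case collection.
#' @return Named numeric vector of IC values (nats) over all terms.
#' @export
information_content <- function(ontology, phenotypes, smooth = FALSE) {
  if (!length(phenotypes)) stop("at least one subject is required")
  counts <- structure(integer(length(ontology$id)), names = ontology$id)
  for (x in phenotypes) {
    if (!length(x)) next
    x <- resolve_terms(ontology, x)
    implied <- unique(unlist(ontology$ancestors[x], use.names = FALSE))
    counts[implied] <- counts[implied] + 1L
  }
  n <- length(phenotypes)
  freq <- if (smooth) (counts + 1) / (n + 1) else counts / n
  ic <- -log(freq)
  ic[counts == 0L & !smooth] <- Inf
  ic
}

#' Terms eligible for the characteristic phenotype
#'
#' The characteristic-phenotype search space consists of terms with finite,
#' strictly positive IC: terms annotated (directly or through descendants)
#' in at least one subject but not in every subject. IC-0 terms (the root,
#' and any term implied by every subject) have zero similarity to every
#' term under the restricted Lin measure and carry no discriminative
#' information.
#'
#' @param ontology A `"phe_ontology"` object.
#' @param ic Named IC vector from [information_content()].
#' @return Character vector of usable term IDs in ontology order.
#' @export
usable_terms <- function(ontology, ic) {
  ontology$id[is.finite(ic[ontology$id]) & ic[ontology$id] > 0]
}

#' Count unrestricted vectors mapping to a minimal set
#'
#' The sampler works on ordered k-vectors of terms rather than on minimal
#' sets directly; this function counts how many ordered k-vectors over a
#' term universe reduce (via [minimal_set()]) to a given antichain `phi`.
#' A vector reduces to `phi` exactly when every coordinate lies in the
#' ancestor closure of `phi` (restricted to the universe) and every member
#' of `phi` appears, so the count is an inclusion-exclusion sum
#' `sum_i (-1)^i C(p, i) (a - i)^k` with `p = |phi|` and `a` the closure
#' size.
#'
#' @param ontology A `"phe_ontology"` object.
#' @param phi Character vector; a nonempty minimal set with `|phi| <= k`.
#' @param k Vector length.
#' @param terms Term universe from which vectors are drawn, typically
#'   [usable_terms()]. Must contain `phi`.
#' @return The number of ordered k-vectors whose minimal reduction is `phi`.
#' @export
count_preimage <- function(ontology, phi, k, terms) {
  phi <- resolve_terms(ontology, phi)
  p <- length(phi)
  if (p < 1L) stop("'phi' must be nonempty")
  if (p > k) stop("|phi| = ", p, " exceeds k = ", k)
  if (!setequal(minimal_set(ontology, phi), phi))
    stop("'phi' is not a minimal set")
  if (!all(phi %in% terms))
    stop("'phi' contains terms outside the supplied universe")
  closure <- intersect(
    unique(unlist(ontology$ancestors[phi], use.names = FALSE)), terms)
  a <- length(closure)
  i <- 0:p
  sum((-1)^i * choose(p, i) * (a - i)^k)
}

#' Enumerate all minimal sets of size at most k
#'
#' Exhaustively lists the antichains of size 1..k over a term universe.
#' Exponential in `k`; intended for small ontologies and for validating
#' [count_min_sets()].
#'
#' @inheritParams count_preimage
#' @param terms Term universe (e.g. [usable_terms()]).
#' @return List of character vectors, each a minimal set.
#' @export
enumerate_min_sets <- function(ontology, k, terms) {
  terms <- unique(resolve_terms(ontology, terms))
  out <- list()
  for (m in seq_len(k)) {
    if (m > length(terms)) break
    combs <- utils::combn(terms, m, simplify = FALSE)
    ok <- vapply(combs, function(s)
      length(minimal_set(ontology, s)) == m, TRUE)
    out <- c(out, combs[ok])
  }
  out
}

#' Count minimal sets of size at most k without enumeration
#'
#' Counts antichains of size 1, 2 and 3 over a term universe from pairwise
#' comparability alone: incomparable pairs come from subtracting
#' ancestor-descendant pairs, and incomparable triples from the
#' triple-counting identity (any three mutually comparable terms of a
#' partial order form a chain). Used for the uniform characteristic-
#' phenotype prior normaliser `|Phi(k)|` when the universe is too large to
#' enumerate; agrees exactly with [enumerate_min_sets()] on small cases.
#'
#' @inheritParams enumerate_min_sets
#' @return The number of minimal sets of size between 1 and `k`.
#' @export
count_min_sets <- function(ontology, k, terms) {
  terms <- unique(resolve_terms(ontology, terms))
  u <- length(terms)
  if (k < 1L) stop("k must be >= 1")
  if (k > 3L)
    return(length(enumerate_min_sets(ontology, k, terms)))
  total <- u
  if (k == 1L) return(total)
  # strict ancestors within the universe, per term
  anc_u <- lapply(terms, function(t) {
    a <- ontology$ancestors[[t]]
    a[a != t & a %in% terms]
  })
  names(anc_u) <- terms
  n_anc <- vapply(anc_u, length, 1L)
  cp <- sum(n_anc)                      # comparable pairs
  n2 <- choose(u, 2) - cp
  total <- total + n2
  if (k == 2L) return(total)
  # descendant counts by transposing the ancestor lists
  n_desc <- structure(numeric(u), names = terms)
  tab <- table(unlist(anc_u, use.names = FALSE))
  n_desc[names(tab)] <- as.numeric(tab)
  d <- n_anc + n_desc                   # comparability degree
  cherries <- sum(choose(d, 2))
  chains3 <- sum(n_anc * n_desc)        # mutually comparable triples
  n3 <- choose(u, 3) - cp * (u - 2) + cherries - chains3
  total + n3
}
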