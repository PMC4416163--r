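#' Ontology DAG container
#'
#' An `ontology_graph` holds the term DAG of an ontology: the set of term
#' identifiers, the directed child-to-parent edges (restricted to the
#' `is_a` and `part_of` relations), the namespace (sub-ontology) of each
#' term and the root term(s) of each namespace. Ancestor/descendant
#' closures over the DAG are what the annotation-unfolding step and the
#' term-frequency statistic consume.
#'
#' @param terms character vector of term identifiers (opaque strings).
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`); may have zero rows.
#' @param namespace named character vector mapping every term to its
#'   namespace label; unnamed scalar recycles to all terms.
#'
#' @return An object of class `ontology_graph` with fields `terms`,
#'   `edges`, `namespace` and `roots` (named list: namespace -> root terms).
#' @export
ontology_graph <- function(terms, edges, namespace = "GO") {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop_input("duplicated term identifiers")
  if (length(namespace) == 1L && is.null(names(namespace)))
    namespace <- stats::setNames(rep(namespace, length(terms)), terms)
  if (!all(terms %in% names(namespace)))
    stop_input("namespace map must cover every term")
  namespace <- namespace[terms]

  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))

  unknown <- setdiff(c(edges$child, edges$parent), terms)
  if (length(unknown) > 0L) {
    warning(sprintf("dropping %d edge(s) referencing unknown terms (e.g. %s)",
                    sum(edges$child %in% unknown | edges$parent %in% unknown),
                    unknown[1L]))
    edges <- edges[!(edges$child %in% unknown) & !(edges$parent %in% unknown), ,
                   drop = FALSE]
  }
  cross <- namespace[edges$child] != namespace[edges$parent]
  if (any(cross)) {
    warning(sprintf("dropping %d edge(s) crossing namespaces", sum(cross)))
    edges <- edges[!cross, , drop = FALSE]
  }

  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(terms)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(edges$child, edges$parent))
  if (!igraph::is_dag(g)) {
    fas <- igraph::feedback_arc_set(g)
    bad <- igraph::ends(g, fas[1])
    stop_input("ontology is not acyclic: cycle through edge %s -> %s",
               bad[1], bad[2])
  }

  has_parent <- terms %in% edges$child
  roots <- split(terms[!has_parent], namespace[!has_parent])
  multi <- names(roots)[lengths(roots) > 1L]
  if (length(multi) > 0L)
    warning(sprintf("namespace(s) with more than one root: %s",
                    paste(multi, collapse = ", ")))

  structure(
    list(terms = terms, edges = edges, namespace = namespace, roots = roots,
         .igraph = g, .cache = new.env(parent = emptyenv())),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, %d edges, %d namespace(s)\n",
              length(x$terms), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Parse an OBO flat file into an ontology DAG
#'
#' Reads the stanza-based OBO 1.2/1.4 format. Only `[Term]` stanzas are
#' used; obsolete terms are dropped, as are all relationship types other
#' than `is_a` and `part_of`. Each `is_a:` line and each
#' `relationship: part_of` line becomes one child-to-parent edge.
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @return An [ontology_graph].
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else unlist(strsplit(x, "\n", fixed = TRUE))

  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function() if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur

  for (i in seq_along(lines)) {
    ln <- sub("\\s+$", "", lines[i])
    if (ln == "" || startsWith(ln, "!")) next
    if (startsWith(ln, "[")) {
      flush(); cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(line = i, is_a = character(),
                               part_of = character(), obsolete = FALSE)
      next
    }
    if (!in_term) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 0L)
      stop_parse("malformed OBO line %d: %s", i, ln)
    key <- m[2]; val <- sub("\\s*!.*$", "", m[3])  # strip trailing comment
    if (key == "id") {
      if (val == "") stop_parse("empty term id at line %d", i)
      cur$id <- val
    } else if (key == "namespace") {
      cur$namespace <- val
    } else if (key == "is_a") {
      if (val == "") stop_parse("is_a with no target at line %d", i)
      cur$is_a <- c(cur$is_a, val)
    } else if (key == "relationship") {
      parts <- strsplit(trimws(val), "\\s+")[[1]]
      if (length(parts) < 2L)
        stop_parse("malformed relationship at line %d: %s", i, ln)
      if (parts[1] == "part_of") cur$part_of <- c(cur$part_of, parts[2])
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    }
  }
  flush()

  if (length(stanzas) == 0L) stop_parse("no [Term] stanzas found")
  no_id <- vapply(stanzas, function(s) is.null(s$id), logical(1))
  if (any(no_id))
    stop_parse("[Term] stanza starting at line %d has no id",
               stanzas[[which(no_id)[1]]]$line)
  stanzas <- Filter(function(s) !s$obsolete, stanzas)
  if (length(stanzas) == 0L) stop_parse("all terms are obsolete")

  terms <- vapply(stanzas, `[[`, character(1), "id")
  ns <- vapply(stanzas, function(s) s$namespace %||% "default", character(1))
  edge_list <- lapply(stanzas, function(s) {
    rbind(
      if (length(s$is_a)) data.frame(child = s$id, parent = s$is_a,
                                     relation = "is_a"),
      if (length(s$part_of)) data.frame(child = s$id, parent = s$part_of,
                                        relation = "part_of")
    )
  })
  edges <- do.call(rbind, Filter(Negate(is.null), edge_list))
  if (is.null(edges))
    edges <- data.frame(child = character(), parent = character(),
                        relation = character())
  ontology_graph(terms, edges, stats::setNames(ns, terms))
}

#' Transitive closure of a term
#'
#' Returns all ancestors (transitively reachable parents) or descendants
#' of a term over the `is_a`/`part_of` edges, excluding the term itself.
#' Results are memoized on the graph object; terms reachable by multiple
#' paths (DAG diamonds) appear once.
#'
#' @param graph an [ontology_graph].
#' @param term a term identifier present in the graph.
#' @param direction `"ancestors"` or `"descendants"`.
#' @return Character vector of term identifiers (possibly empty).
#' @export
closure <- function(graph, term, direction = c("ancestors", "descendants")) {
  direction <- match.arg(direction)
  if (!term %in% graph$terms) stop_input("unknown term: %s", term)
  key <- paste0(direction, "\r", term)
  hit <- graph$.cache[[key]]
  if (!is.null(hit)) return(hit)
  mode <- if (direction == "ancestors") "out" else "in"
  res <- igraph::subcomponent(graph$.igraph, term, mode = mode)
  res <- setdiff(names(res), term)
  assign(key, res, envir = graph$.cache)
  res
}
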