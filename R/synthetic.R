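#' Specification of a synthetic ontology + corpus
#'
#' Defines the study conditions for the simulated data: a random rooted
#' DAG of `n_terms` terms, and a corpus of `n_genes` genes partitioned
#' into `n_blocks` latent functional modules. Each module owns a subtree
#' of the ontology; a module gene carries each owned leaf term with
#' probability `block_density` (curated evidence), plus uniformly random
#' off-module annotations at rate `noise_rate` (electronic evidence).
#' A fraction `holdout_fraction` of the curated module annotations is
#' withheld from the "old" corpus version and present only in the
#' "updated" version, giving a recoverable ground truth that emulates
#' the growth of real annotation databases between releases.
#'
#' @param n_terms number of ontology terms (default 60).
#' @param branching mean children per term, controls level sizes
#'   (default 3).
#' @param depth DAG depth below the root (default 3).
#' @param n_genes corpus size (default 200).
#' @param n_blocks latent gene modules (default 5).
#' @param block_density probability a module gene carries an owned leaf
#'   term (default 0.8).
#' @param noise_rate per-(gene, term) probability of an off-module
#'   electronic annotation (default 0.02).
#' @param holdout_fraction fraction of curated module annotations moved
#'   to the updated-only set (default 0.1).
#' @param seed RNG seed; generators are pure functions of (spec, seed).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_terms = 60L, branching = 3, depth = 3L,
                           n_genes = 200L, n_blocks = 5L,
                           block_density = 0.8, noise_rate = 0.02,
                           holdout_fraction = 0.1, seed = 1L) {
  stopifnot(n_terms >= 1, depth >= 1, n_genes >= 1,
            n_blocks >= 1, n_blocks <= n_genes,
            block_density >= 0, block_density <= 1,
            noise_rate >= 0, noise_rate <= 1,
            holdout_fraction >= 0, holdout_fraction < 1)
  structure(list(n_terms = as.integer(n_terms), branching = branching,
                 depth = as.integer(depth), n_genes = as.integer(n_genes),
                 n_blocks = as.integer(n_blocks),
                 block_density = block_density, noise_rate = noise_rate,
                 holdout_fraction = holdout_fraction, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a random rooted ontology DAG
#'
#' Terms are placed level by level below a single root; level sizes grow
#' roughly geometrically with `branching`. Every non-root term gets one
#' parent drawn uniformly from the previous level and, with probability
#' 0.2, a second distinct parent from the same level, creating the
#' diamond motifs typical of real ontologies. All edges are `is_a`,
#' single namespace.
#'
#' @param spec a [synthetic_spec].
#' @return An [ontology_graph].
#' @export
make_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_terms
  terms <- sprintf("ST:%04d", seq_len(n))
  if (n == 1L)
    return(ontology_graph(terms, data.frame(child = character(),
                                            parent = character(),
                                            relation = character()),
                          "synthetic"))
  # geometric level sizes, scaled to n - 1 non-root terms
  w <- spec$branching^seq_len(spec$depth)
  sizes <- pmax(1L, round(w / sum(w) * (n - 1L)))
  while (sum(sizes) > n - 1L) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n - 1L) sizes[length(sizes)] <- sizes[length(sizes)] + 1L
  levels <- split(terms[-1L], rep(seq_along(sizes), sizes))
  levels <- c(list(terms[1L]), levels)

  with_seed(spec$seed, {
    edges <- list()
    for (lv in seq_along(levels)[-1L]) {
      prev <- levels[[lv - 1L]]
      for (tm in levels[[lv]]) {
        parents <- prev[sample.int(length(prev), 1L)]
        if (length(prev) > 1L && stats::runif(1) < 0.2)
          parents <- c(parents, sample(setdiff(prev, parents), 1L))
        edges[[length(edges) + 1L]] <-
          data.frame(child = tm, parent = parents, relation = "is_a",
                     stringsAsFactors = FALSE)
      }
    }
    g <- ontology_graph(terms, do.call(rbind, edges), "synthetic")
    g$levels <- levels
    g
  })
}

#' Generate paired old/updated annotation corpora with planted blocks
#'
#' Assigns each gene to one of `n_blocks` modules; each module owns the
#' subtree under a distinct depth-1 term of the DAG. Module genes carry
#' each owned leaf term with probability `block_density` (evidence drawn
#' from IDA/IMP/ISS), plus noise annotations to arbitrary terms at rate
#' `noise_rate` (evidence IEA). A fraction `holdout_fraction` of the
#' curated module annotations is withheld from the old corpus and placed
#' only in the updated corpus: these `masked` pairs are the recoverable
#' ground truth for hold-out validation. Otherwise updated contains old.
#'
#' @param graph an [ontology_graph] from [make_ontology()] (or any DAG).
#' @param spec a [synthetic_spec].
#' @return A list with `old` and `updated` [annotation_corpus] objects,
#'   `masked` (data.frame of withheld (gene, term) pairs), `blocks`
#'   (named vector: gene -> module index) and `block_terms` (list of the
#'   owned leaf terms per module).
#' @export
make_corpus <- function(graph, spec) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(spec, "synthetic_spec"))
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  terms <- graph$terms
  is_leaf <- !(terms %in% graph$edges$parent)

  root <- unlist(graph$roots, use.names = FALSE)[1]
  top <- graph$edges$child[graph$edges$parent == root]
  if (length(top) == 0L) top <- terms

  with_seed(spec$seed + 1L, {
    block_roots <- if (length(top) >= spec$n_blocks)
      sample(top, spec$n_blocks)
    else sample(top, spec$n_blocks, replace = TRUE)
    block_terms <- lapply(block_roots, function(b) {
      sub <- c(b, closure(graph, b, "descendants"))
      leaves <- sub[sub %in% terms[is_leaf]]
      if (length(leaves) == 0L) sub else leaves
    })
    block_of <- sample(rep_len(seq_len(spec$n_blocks), spec$n_genes))

    rec <- list()
    for (gi in seq_along(genes)) {
      owned <- block_terms[[block_of[gi]]]
      hit <- owned[stats::runif(length(owned)) < spec$block_density]
      if (length(hit))
        rec[[length(rec) + 1L]] <- data.frame(
          gene = genes[gi], term = hit,
          evidence = sample(c("IDA", "IMP", "ISS"), length(hit), replace = TRUE),
          namespace = "synthetic", curated = TRUE, stringsAsFactors = FALSE)
      noise <- terms[stats::runif(length(terms)) < spec$noise_rate]
      noise <- setdiff(noise, hit)
      if (length(noise))
        rec[[length(rec) + 1L]] <- data.frame(
          gene = genes[gi], term = noise, evidence = "IEA",
          namespace = "synthetic", curated = FALSE, stringsAsFactors = FALSE)
    }
    all_rec <- do.call(rbind, rec)

    curated_idx <- which(all_rec$curated)
    n_mask <- floor(spec$holdout_fraction * length(curated_idx))
    mask_idx <- if (n_mask > 0) sample(curated_idx, n_mask) else integer(0)
    old <- all_rec[setdiff(seq_len(nrow(all_rec)), mask_idx), , drop = FALSE]
    masked <- all_rec[mask_idx, c("gene", "term"), drop = FALSE]
    rownames(masked) <- NULL
    list(old = annotation_corpus(old[names(old) != "curated"]),
         updated = annotation_corpus(all_rec[names(all_rec) != "curated"]),
         masked = masked,
         blocks = stats::setNames(block_of, genes),
         block_terms = block_terms)
  })
}

#' Mask leaf-most annotations from a matrix, preserving closure
#'
#' Removes `floor(fraction * nnz)` randomly chosen annotations among the
#' removable ones: an entry (g, f) is removable only when g has no
#' annotated descendant of f among the columns, so the masked matrix
#' stays ancestor-closed (a valid unfolded matrix). If fewer entries are
#' removable than requested, the maximal removable set is masked with a
#' warning.
#'
#' @param A an [annotation_matrix] (ancestor-closed).
#' @param graph the [ontology_graph].
#' @param fraction fraction of nonzeros to mask, in [0, 1).
#' @param seed RNG seed.
#' @return A list with `masked` (the reduced [annotation_matrix]) and
#'   `held`, a data.frame of removed (gene, term) pairs.
#' @export
mask_holdout <- function(A, graph, fraction, seed = 1L) {
  stopifnot(inherits(A, "annotation_matrix"), fraction >= 0, fraction < 1)
  if (fraction == 0)
    return(list(masked = A, held = data.frame(gene = character(),
                                              term = character())))
  tf <- term_frequency(A, graph)
  Tt <- methods::as(tf, "TsparseMatrix")
  removable <- which(Tt@x == 1)   # TF == 1: no annotated descendant
  target <- floor(fraction * Matrix::nnzero(A$A))
  if (length(removable) < target) {
    warning(sprintf("only %d of %d requested entries are removable",
                    length(removable), target))
    target <- length(removable)
  }
  pick <- with_seed(seed, sample(removable, target))
  ri <- Tt@i[pick] + 1L
  ci <- Tt@j[pick] + 1L
  M <- A$A
  M[cbind(ri, ci)] <- 0
  M <- Matrix::drop0(M)
  list(masked = annotation_matrix(M, A$L),
       held = data.frame(gene = A$genes[ri], term = A$terms[ci],
                         stringsAsFactors = FALSE))
}

#' Write an ontology as an OBO flat file
#'
#' @param graph an [ontology_graph].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (tm in graph$terms) {
    writeLines(c("", "[Term]", paste0("id: ", tm),
                 paste0("namespace: ", graph$namespace[[tm]])), con)
    e <- graph$edges[graph$edges$child == tm, , drop = FALSE]
    for (r in seq_len(nrow(e))) {
      if (e$relation[r] == "is_a")
        writeLines(paste0("is_a: ", e$parent[r]), con)
      else
        writeLines(paste0("relationship: part_of ", e$parent[r]), con)
    }
  }
  invisible(path)
}

#' Write a corpus as a GAF 2.2 file
#'
#' @param corpus an [annotation_corpus].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_gaf <- function(corpus, path) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  r <- corpus$records
  rows <- if (nrow(r) == 0L) character(0) else
    apply(cbind("SYN", r$gene, r$gene, "", r$term, "SYN:0000001",
                r$evidence, "", r$namespace, "", "", "gene", "taxon:0",
                "20260101", "SYN", "", ""),
          1, paste, collapse = "\t")
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}
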