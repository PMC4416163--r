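# Shared fixtures and independent oracles, all built in code.

# --- tiny hand-written OBO/GAF text -----------------------------------------

obo_chain <- function() c(
  "format-version: 1.2",
  "", "[Term]", "id: r", "namespace: bp",
  "", "[Term]", "id: a", "namespace: bp", "is_a: r",
  "", "[Term]", "id: b", "namespace: bp", "is_a: a"
)

# diamond: r <- a, r <- b, a <- c, b <- c
obo_diamond <- function() c(
  "format-version: 1.2",
  "", "[Term]", "id: r", "namespace: bp",
  "", "[Term]", "id: a", "namespace: bp", "is_a: r",
  "", "[Term]", "id: b", "namespace: bp", "is_a: r",
  "", "[Term]", "id: c", "namespace: bp", "is_a: a", "is_a: b"
)

gaf_row <- function(gene, term, evidence = "IDA", qualifier = "",
                    aspect = "P") {
  paste(c("DB", gene, gene, qualifier, term, "REF:1", evidence, "", aspect,
          "", "", "gene", "taxon:1", "20200101", "DB", "", ""),
        collapse = "\t")
}

# --- random DAGs with a brute-force closure oracle --------------------------

# Random DAG over n terms: term i (>= 2) gets 1-2 parents among 1..i-1.
random_dag <- function(n, seed) {
  withr::local_seed(seed)
  terms <- sprintf("t%03d", seq_len(n))
  edges <- NULL
  for (i in seq_len(n)[-1]) {
    np <- if (i > 2 && runif(1) < 0.3) 2L else 1L
    parents <- terms[sample.int(i - 1L, min(np, i - 1L))]
    edges <- rbind(edges, data.frame(child = terms[i], parent = parents,
                                     relation = "is_a"))
  }
  if (is.null(edges))
    edges <- data.frame(child = character(), parent = character(),
                        relation = character())
  list(graph = ontology_graph(terms, edges, "ns"), terms = terms,
       edges = edges)
}

# BFS closure oracle over the raw edge list, independent of the package DAG.
bfs_closure <- function(edges, term, direction) {
  from <- if (direction == "ancestors") "child" else "parent"
  to <- if (direction == "ancestors") "parent" else "child"
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- unique(edges[[to]][edges[[from]] %in% frontier])
    nxt <- setdiff(nxt, c(seen, term))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# Random corpus on a DAG (direct annotations only, mixed evidence).
random_corpus <- function(dag, n_genes, seed, density = 0.15) {
  withr::local_seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  hits <- which(matrix(runif(n_genes * length(dag$terms)), n_genes) < density,
                arr.ind = TRUE)
  if (nrow(hits) == 0) hits <- cbind(1L, 1L)
  annotation_corpus(data.frame(
    gene = genes[hits[, 1]], term = dag$terms[hits[, 2]],
    evidence = sample(c("IDA", "IEA", "IMP"), nrow(hits), replace = TRUE),
    namespace = "ns"))
}

# --- triple-nested-loop weighting oracle ------------------------------------

# Reference TF/IGF/schema computation by explicit loops over the dense
# matrix and the BFS descendant closure; deliberately naive.
oracle_weights <- function(A_dense, terms, edges, schema_name) {
  nG <- nrow(A_dense); nF <- ncol(A_dense)
  desc <- lapply(terms, function(tm) bfs_closure(edges, tm, "descendants"))
  TF <- matrix(0, nG, nF)
  for (g in seq_len(nG)) for (f in seq_len(nF)) {
    if (A_dense[g, f] == 1) {
      cnt <- 0
      for (d in desc[[f]]) {
        j <- match(d, terms)
        if (!is.na(j) && A_dense[g, j] == 1) cnt <- cnt + 1
      }
      TF[g, f] <- 1 + cnt
    }
  }
  IGF <- numeric(nF)
  for (f in seq_len(nF)) IGF[f] <- log(nG / sum(A_dense[, f] == 1))
  if (schema_name == "none") return(A_dense)
  loc <- substr(schema_name, 1, 1)
  glob <- substr(schema_name, 2, 2)
  norm <- substr(schema_name, 3, 3)
  W <- matrix(0, nG, nF)
  for (g in seq_len(nG)) {
    mx <- max(TF[g, ])
    for (f in seq_len(nF)) {
      if (A_dense[g, f] == 0) next
      wl <- if (loc == "N") TF[g, f] else 0.5 + 0.5 * TF[g, f] / mx
      wg <- if (glob == "T") IGF[f] else 1
      W[g, f] <- wl * wg
    }
  }
  if (norm == "M") for (g in seq_len(nG)) {
    mx <- max(W[g, ])
    if (mx > 0) W[g, ] <- W[g, ] / mx
  }
  W
}

# Build an annotation_matrix + graph pair from a random DAG/corpus,
# unfolded and unpruned (L = 1), for weighting tests.
random_instance <- function(n_terms, n_genes, seed) {
  dag <- random_dag(n_terms, seed)
  corpus <- random_corpus(dag, n_genes, seed + 1000)
  A <- build_matrix(corpus, dag$graph, L = 1L)
  list(dag = dag, A = A)
}
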