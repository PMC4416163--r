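#' Annotation corpus container
#'
#' A multiset of (gene, term, evidence, namespace) annotation records,
#' stored as a data.frame with an `unfolded` flag. Unfolding adds, for
#' every annotation of a gene to a term, annotations of the same gene to
#' all ancestors of that term (the ontology's true-path semantics).
#'
#' @param records data.frame with character columns `gene`, `term`,
#'   `evidence`, `namespace`.
#' @param unfolded logical; whether the corpus is already ancestor-closed.
#' @return An object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(records, unfolded = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("gene", "term", "evidence", "namespace")
  missing_cols <- setdiff(need, names(records))
  for (cl in missing_cols) records[[cl]] <- character(nrow(records))
  records <- records[need]
  if (nrow(records) > 0L) {
    if (any(records$gene == "") || any(records$term == ""))
      stop_input("gene and term identifiers must be non-empty")
    records$evidence <- toupper(records$evidence)
  }
  structure(list(records = records, unfolded = isTRUE(unfolded)),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("annotation_corpus: %d records, %d genes, %d terms%s\n",
              nrow(x$records), length(unique(x$records$gene)),
              length(unique(x$records$term)),
              if (x$unfolded) " (unfolded)" else ""))
  invisible(x)
}

#' Read a GAF 2.x annotation file
#'
#' Tab-separated, 17 columns, comment lines starting with `!`. Each data
#' row becomes one annotation record with `DB_Object_ID` as the gene,
#' `GO_ID` as the term, the evidence code, and the aspect column as the
#' namespace label. Rows whose qualifier contains `NOT` are dropped.
#' Duplicate (gene, term) rows are kept as distinct records, since they
#' may carry different evidence codes.
#'
#' @param x path to a GAF file, or a character vector of GAF lines.
#' @return An [annotation_corpus] (not unfolded).
#' @export
read_gaf <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else unlist(strsplit(x, "\n", fixed = TRUE))

  keep <- !startsWith(lines, "!") & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(annotation_corpus(data.frame(gene = character(), term = character(),
                                        evidence = character(),
                                        namespace = character())))
  # sentinel keeps strsplit from dropping trailing empty fields
  fields <- strsplit(paste0(lines[idx], "\tEOL"), "\t", fixed = TRUE)
  nf <- lengths(fields) - 1L
  if (any(nf != 17L))
    stop_parse("GAF line %d has %d columns, expected 17",
               idx[which(nf != 17L)[1]], nf[nf != 17L][1])
  m <- matrix(unlist(fields), ncol = 18L, byrow = TRUE)
  not_rows <- grepl("\\bNOT\\b", m[, 4])
  m <- m[!not_rows, , drop = FALSE]
  annotation_corpus(data.frame(
    gene = m[, 2], term = m[, 5], evidence = toupper(m[, 7]),
    namespace = m[, 9], stringsAsFactors = FALSE
  ))
}

#' Filter a corpus by evidence code
#'
#' Removes records whose evidence code is in `excluded`. The default
#' excludes the computationally inferred codes IEA (Inferred from
#' Electronic Annotation) and ND (No biological Data available), leaving
#' the curated annotations used for model training.
#'
#' @param corpus an [annotation_corpus].
#' @param excluded character vector of evidence codes to drop.
#' @return A filtered [annotation_corpus] (same `unfolded` flag).
#' @export
filter_evidence <- function(corpus, excluded = c("IEA", "ND")) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  keep <- !(corpus$records$evidence %in% toupper(excluded))
  annotation_corpus(corpus$records[keep, , drop = FALSE], corpus$unfolded)
}

#' Unfold a corpus against the ontology
#'
#' For each annotation (g, f), adds (g, f'') for every ancestor f'' of f,
#' carrying the original record's evidence code. Records are deduplicated
#' at the (gene, term, evidence) level. Records whose term is absent from
#' the graph are dropped with a warning.
#'
#' @param corpus an [annotation_corpus]; unfolding is idempotent, so an
#'   already-unfolded corpus is returned unchanged.
#' @param graph an [ontology_graph].
#' @return The unfolded [annotation_corpus].
#' @export
unfold_corpus <- function(corpus, graph) {
  stopifnot(inherits(corpus, "annotation_corpus"),
            inherits(graph, "ontology_graph"))
  if (corpus$unfolded) return(corpus)
  rec <- corpus$records
  known <- rec$term %in% graph$terms
  if (!all(known)) {
    warning(sprintf("dropping %d record(s) with terms absent from the ontology",
                    sum(!known)))
    rec <- rec[known, , drop = FALSE]
  }
  if (nrow(rec) == 0L) return(annotation_corpus(rec, unfolded = TRUE))

  anc <- lapply(unique(rec$term), function(tm) closure(graph, tm, "ancestors"))
  names(anc) <- unique(rec$term)
  n_anc <- lengths(anc)[rec$term]
  extra <- data.frame(
    gene = rep(rec$gene, n_anc),
    term = unlist(anc[rec$term], use.names = FALSE),
    evidence = rep(rec$evidence, n_anc),
    namespace = rep(rec$namespace, n_anc),
    stringsAsFactors = FALSE
  )
  out <- rbind(rec, extra)
  out <- out[!duplicated(out[c("gene", "term", "evidence")]), , drop = FALSE]
  rownames(out) <- NULL
  annotation_corpus(out, unfolded = TRUE)
}

#' Binary annotation matrix
#'
#' The pruned, unfolded gene-by-term 0/1 matrix A. Rows are genes, columns
#' are terms, both sorted lexicographically. Invariants: entries are 0/1;
#' the matrix is ancestor-closed (A(g,f)=1 implies A(g,f'')=1 for every
#' ancestor f'' of f still present among the columns); every column has at
#' least `L` nonzeros.
#'
#' @param A a sparse 0/1 Matrix with gene/term dimnames.
#' @param L the pruning threshold used to build it.
#' @return An object of class `annotation_matrix` with fields `A`,
#'   `genes`, `terms`, `L`.
#' @export
annotation_matrix <- function(A, L = 0L) {
  A <- methods::as(methods::as(A, "dMatrix"), "CsparseMatrix")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop_input("annotation matrix requires gene and term dimnames")
  structure(list(A = A, genes = rownames(A), terms = colnames(A),
                 L = as.integer(L)),
            class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("annotation_matrix: %d genes x %d terms, %d annotations (L=%d)\n",
              length(x$genes), length(x$terms), Matrix::nnzero(x$A), x$L))
  invisible(x)
}

#' Build the pruned binary annotation matrix
#'
#' Unfolds the corpus if needed, builds the binary gene-by-term matrix over
#' all distinct genes and terms of the unfolded corpus, then prunes: every
#' column annotated to fewer than `L` distinct genes is removed (a single
#' pass, not iterated), and genes left with no annotations afterwards are
#' dropped. Pruning removes very rare terms that carry little co-occurrence
#' information. Row and column orders are lexicographic.
#'
#' @param corpus an [annotation_corpus].
#' @param graph an [ontology_graph].
#' @param L integer pruning threshold (default 3): columns with `< L`
#'   annotated genes are deleted.
#' @return An [annotation_matrix].
#' @export
build_matrix <- function(corpus, graph, L = 3L) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (!corpus$unfolded) corpus <- unfold_corpus(corpus, graph)
  rec <- unique(corpus$records[c("gene", "term")])
  if (nrow(rec) == 0L) stop_input("cannot build a matrix from an empty corpus")

  genes <- sort(unique(rec$gene), method = "radix")
  terms <- sort(unique(rec$term), method = "radix")
  A <- Matrix::sparseMatrix(
    i = match(rec$gene, genes), j = match(rec$term, terms), x = 1,
    dims = c(length(genes), length(terms)), dimnames = list(genes, terms)
  )
  keep_col <- Matrix::colSums(A) >= L
  if (!any(keep_col))
    stop_input("pruning with L=%d removed every term column", L)
  A <- A[, keep_col, drop = FALSE]
  keep_row <- Matrix::rowSums(A) > 0
  A <- A[keep_row, , drop = FALSE]
  annotation_matrix(A, L)
}

#' Export an annotation or weighted matrix as MatrixMarket plus index files
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format), `genes.txt` and
#' `terms.txt` (one identifier per line, in row/column order) into `dir`.
#'
#' @param x an [annotation_matrix], [weighted_matrix], or a matrix with
#'   dimnames.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_matrix_dir <- function(x, dir) {
  M <- if (inherits(x, "annotation_matrix")) x$A
       else if (inherits(x, "weighted_matrix")) x$W
       else x
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.txt", "terms.txt"))
  Matrix::writeMM(methods::as(Matrix::Matrix(M, sparse = TRUE), "generalMatrix"),
                  paths[1])
  writeLines(rownames(M), paths[2])
  writeLines(colnames(M), paths[3])
  invisible(paths)
}

#' Read a matrix written by [write_matrix_dir()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.txt`, `terms.txt`.
#' @return A sparse Matrix with gene/term dimnames.
#' @export
read_matrix_dir <- function(dir) {
  M <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  M <- methods::as(methods::as(M, "dMatrix"), "CsparseMatrix")
  dimnames(M) <- list(readLines(file.path(dir, "genes.txt")),
                      readLines(file.path(dir, "terms.txt")))
  M
}
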