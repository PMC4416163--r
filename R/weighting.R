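#' Weighting schema codes
#'
#' A schema is a three-letter code: local weight (`N` = term frequency as
#' is, `A` = augmented, 0.5 + 0.5 TF/maxTF over the gene's annotations),
#' global weight (`T` = inverse gene frequency, `N` = none) and row
#' normalization (`N` = none, `M` = divide each row by its maximum). The
#' schema `"none"` is the binary passthrough W = A. The combinations the
#' field reports as useful are NTN, NTM and ATN; all eight component
#' combinations are accepted.
#'
#' @param name `"none"` or a three-letter code such as `"NTN"`.
#' @return A list with fields `local`, `global`, `norm`, `name`.
#' @export
weighting_schema <- function(name) {
  name <- toupper(as.character(name)[1])
  if (name %in% c("NONE", "")) {
    return(structure(list(local = "none", global = "none", norm = "none",
                          name = "none"), class = "weighting_schema"))
  }
  parts <- strsplit(name, "")[[1]]
  if (length(parts) != 3L || !parts[1] %in% c("N", "A") ||
      !parts[2] %in% c("T", "N") || !parts[3] %in% c("N", "M"))
    stop_config("unknown weighting schema: %s", name)
  structure(list(local = parts[1], global = parts[2], norm = parts[3],
                 name = name), class = "weighting_schema")
}

#' Term frequency statistic
#'
#' For each annotated pair (g, f), TF(g, f) = 1 + the number of
#' descendants of f (among the matrix columns) that are annotated to g.
#' A direct annotation to a leaf term gets TF = 1; a general term whose
#' unfolded annotation is supported by many annotated descendants gets a
#' proportionally larger TF. Where A(g, f) = 0, TF = 0. Descendants are
#' counted only among terms that survived pruning (the columns of A).
#'
#' @param A an [annotation_matrix].
#' @param graph the [ontology_graph] the matrix was built against.
#' @return A sparse Matrix of TF values, same shape and dimnames as `A$A`.
#' @export
term_frequency <- function(A, graph) {
  stopifnot(inherits(A, "annotation_matrix"))
  missing_terms <- setdiff(A$terms, graph$terms)
  if (length(missing_terms) > 0L)
    stop_input("matrix term absent from ontology: %s", missing_terms[1])
  M <- A$A
  ii <- jj <- xx <- vector("list", length(A$terms))
  for (j in seq_along(A$terms)) {
    rows <- which(M[, j] != 0)
    if (length(rows) == 0L) next
    desc <- intersect(closure(graph, A$terms[j], "descendants"), A$terms)
    tf <- if (length(desc) == 0L) rep(1, length(rows))
          else 1 + Matrix::rowSums(M[rows, desc, drop = FALSE])
    ii[[j]] <- rows; jj[[j]] <- rep(j, length(rows)); xx[[j]] <- tf
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = dim(M), dimnames = dimnames(M))
}

#' Inverse gene frequency statistic
#'
#' IGF(f) = ln(|G| / n_f), where n_f is the number of genes annotated to
#' term f. A term annotated to every gene gets IGF = ln 1 = 0 (it does not
#' discriminate among genes); a term annotated to a single gene gets the
#' maximum, ln |G|.
#'
#' @param A an [annotation_matrix].
#' @return Named numeric vector of IGF values over the matrix columns.
#' @export
inverse_gene_frequency <- function(A) {
  stopifnot(inherits(A, "annotation_matrix"))
  n_f <- Matrix::colSums(A$A != 0)
  if (any(n_f == 0))
    stop_input("column with no annotated genes: %s", A$terms[which(n_f == 0)[1]])
  stats::setNames(log(length(A$genes) / n_f), A$terms)
}

#' Weighted annotation matrix
#'
#' Result of applying a weighting schema to the binary matrix:
#' W(g, f) = A(g, f) * w_loc(g, f) * w_glob(f), optionally followed by
#' dividing each row by its own maximum. The nonzero pattern of W is a
#' subset of that of A (weighting never creates support), entries are
#' non-negative, and under `M` normalization every nonzero row has
#' maximum exactly 1.
#'
#' @param W real sparse Matrix.
#' @param schema the [weighting_schema] applied.
#' @param tf the TF matrix used (or NULL for schema "none").
#' @param igf the IGF vector used (or NULL).
#' @return An object of class `weighted_matrix`.
#' @export
weighted_matrix <- function(W, schema, tf = NULL, igf = NULL) {
  structure(list(W = W, schema = schema, tf = tf, igf = igf,
                 genes = rownames(W), terms = colnames(W)),
            class = "weighted_matrix")
}

#' @export
print.weighted_matrix <- function(x, ...) {
  cat(sprintf("weighted_matrix (%s): %d genes x %d terms\n",
              x$schema$name, nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Apply a weighting schema to the annotation matrix
#'
#' @param A an [annotation_matrix].
#' @param graph the [ontology_graph] (needed for the TF statistic).
#' @param schema a schema name accepted by [weighting_schema()], or a
#'   `weighting_schema` object. Default `"NTN"`.
#' @return A [weighted_matrix]. With schema `"none"`, W equals A.
#' @export
apply_schema <- function(A, graph, schema = "NTN") {
  stopifnot(inherits(A, "annotation_matrix"))
  if (!inherits(schema, "weighting_schema")) schema <- weighting_schema(schema)
  if (schema$name == "none")
    return(weighted_matrix(A$A, schema))

  tf <- term_frequency(A, graph)
  igf <- inverse_gene_frequency(A)

  W <- tf
  if (schema$local == "A") {
    # augmented: 0.5 + 0.5 * TF / max TF over the gene's annotated terms
    row_max <- apply_row_max(tf)
    W <- map_nonzeros(tf, function(i, j, x) 0.5 + 0.5 * x / row_max[i])
  }
  if (schema$global == "T")
    W <- W %*% Matrix::Diagonal(x = igf[colnames(W)])
  if (schema$norm == "M") {
    rm <- apply_row_max(W)
    rm[rm == 0] <- 1  # zero rows untouched
    # true division so each row's maximum is exactly 1
    W <- map_nonzeros(W, function(i, j, x) x / rm[i])
  }
  W <- methods::as(W, "CsparseMatrix")
  dimnames(W) <- dimnames(A$A)
  weighted_matrix(Matrix::drop0(W), schema, tf = tf, igf = igf)
}

# Row maxima of a sparse non-negative matrix (0 for empty rows).
apply_row_max <- function(M) {
  M <- methods::as(M, "TsparseMatrix")
  out <- numeric(nrow(M))
  if (length(M@x) > 0) {
    agg <- tapply(M@x, M@i, max)
    out[as.integer(names(agg)) + 1L] <- agg
  }
  out
}

# Apply f(i, j, x) over the nonzeros of a sparse matrix, keeping pattern.
map_nonzeros <- function(M, f) {
  M <- methods::as(M, "TsparseMatrix")
  M@x <- f(M@i + 1L, M@j + 1L, M@x)
  methods::as(M, "CsparseMatrix")
}
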