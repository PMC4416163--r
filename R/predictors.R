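#' Truncated-SVD (LSI) model
#'
#' Factorizes the (weighted) annotation matrix W = U S V' and keeps the
#' top-k right singular vectors. The truncation discards directions with
#' small singular values, which mostly capture noise from missing or
#' erroneous annotations; reconstruction projects each gene's annotation
#' profile onto the span of the retained directions.
#'
#' @param W a real matrix (dense or sparse Matrix) with dimnames.
#' @param k truncation level; clamped to min(nrow, ncol) with a warning.
#' @return An object of class `tsvd_model` with fields `k`, `Vk`
#'   (|F| x k, orthonormal columns), `singular_values`, `p`.
#' @export
fit_tsvd <- function(W, k = 500L) {
  W <- as_dense(W)
  if (all(W == 0)) stop_numeric("cannot factorize an all-zero matrix")
  p <- min(dim(W))
  if (k < 1L) stop_config("truncation level k must be >= 1")
  if (k > p) {
    warning(sprintf("k=%d exceeds min(|G|,|F|)=%d; clamped", k, p))
    k <- p
  }
  s <- svd(W, nu = 0, nv = p)
  V <- fix_signs(s$v)
  structure(list(k = as.integer(k), Vk = V[, seq_len(k), drop = FALSE],
                 singular_values = s$d[seq_len(k)], all_singular_values = s$d,
                 p = p, terms = colnames(W)),
            class = "tsvd_model")
}

# Resolve SVD/eigen sign indeterminacy: force the largest-magnitude entry
# of each column positive (ties broken by the first such entry).
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

as_dense <- function(W) {
  if (inherits(W, "weighted_matrix")) W <- W$W
  if (inherits(W, "annotation_matrix")) W <- W$A
  as.matrix(W)
}

#' Reconstruct annotation scores with a tSVD model
#'
#' Scores = W Vk Vk': each gene profile is projected onto the retained
#' latent directions. Entries that were 0 in the input but receive a high
#' reconstructed score are the predicted annotations.
#'
#' @param model a `tsvd_model`.
#' @param W the matrix to reconstruct (columns must match the model's).
#' @param A optional [annotation_matrix] defining which pairs are
#'   unobserved; defaults to the nonzero pattern of `W`.
#' @return A [prediction_result].
#' @export
reconstruct_tsvd <- function(model, W, A = NULL) {
  Wd <- as_dense(W)
  if (ncol(Wd) != nrow(model$Vk))
    stop_input("matrix has %d columns but model expects %d",
               ncol(Wd), nrow(model$Vk))
  scores <- (Wd %*% model$Vk) %*% t(model$Vk)
  dimnames(scores) <- dimnames(Wd)
  prediction_result(scores, A %||% binary_pattern(W), method = "tsvd")
}

binary_pattern <- function(W) {
  Wd <- as_dense(W)
  annotation_matrix(Matrix::Matrix((Wd != 0) * 1, sparse = TRUE,
                                   dimnames = dimnames(Wd)), L = 0L)
}

#' Semantically improved tSVD (SIM) model
#'
#' tSVD reconstruction is linear, so genes with few annotations tend to
#' receive systematically lower reconstructed scores than heavily
#' annotated genes. SIM mitigates this bias with a soft gene-clustering
#' step: each of the first C left singular vectors u_c of W defines a
#' cluster membership; a per-cluster term correlation matrix
#' T_c = W' C_c W is built with C_c = diag(u_c), its eigenvectors (sorted
#' by non-increasing eigenvalue) are truncated to k columns, and each gene
#' is finally scored by whichever cluster model (including the global
#' c = 0 tSVD model) reconstructs its profile with the smallest L2 error.
#' With C = 0, SIM is exactly tSVD.
#'
#' @param W real matrix with dimnames.
#' @param k truncation level (shared by all cluster models).
#' @param C number of clusters (0 to min(|G|,|F|)); default 3.
#' @param sort_by_magnitude sort T_c eigenvectors by |eigenvalue| instead
#'   of signed eigenvalue (default FALSE: signed, non-increasing).
#' @return An object of class `sim_model` with fields `C`, `k`,
#'   `cluster_weights` (list of u_c vectors) and `Vck` (list of C+1
#'   truncated eigenvector matrices; element 1 is the plain tSVD Vk).
#' @export
fit_sim <- function(W, k = 500L, C = 3L, sort_by_magnitude = FALSE) {
  Wd <- as_dense(W)
  p <- min(dim(Wd))
  if (C < 0L || C > p) stop_config("C must be between 0 and min(|G|,|F|)=%d", p)
  base <- fit_tsvd(Wd, k)
  k <- base$k
  sv <- svd(Wd, nu = min(C, p), nv = p)
  U <- if (C > 0L) fix_signs_like(sv$u, sv$v) else
    matrix(0, nrow(Wd), 0)
  Vck <- vector("list", C + 1L)
  Vck[[1L]] <- base$Vk
  cluster_weights <- vector("list", C)
  for (cc in seq_len(C)) {
    u_c <- U[, cc]
    cluster_weights[[cc]] <- u_c
    Tc <- crossprod(Wd, u_c * Wd)          # W' C_c W, symmetric
    eg <- eigen(Tc, symmetric = TRUE)      # eigenvalues non-increasing (signed)
    ord <- if (sort_by_magnitude) order(abs(eg$values), decreasing = TRUE)
           else seq_along(eg$values)
    Vc <- fix_signs(eg$vectors[, ord, drop = FALSE])
    Vck[[cc + 1L]] <- Vc[, seq_len(k), drop = FALSE]
  }
  structure(list(C = as.integer(C), k = k, cluster_weights = cluster_weights,
                 Vck = Vck, terms = colnames(Wd)),
            class = "sim_model")
}

# Sign-fix U consistently with the sign fix applied to V so that
# W = U S V' is preserved: flip u_j whenever v_j was flipped.
fix_signs_like <- function(U, V) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Reconstruct annotation scores with a SIM model
#'
#' For each gene profile a, computes the C+1 candidate reconstructions
#' a Vck Vck' and keeps the one closest to a in L2 norm; ties are broken
#' in favor of the smallest cluster index (the global model first).
#'
#' @param model a `sim_model`.
#' @param W matrix to reconstruct.
#' @param A optional [annotation_matrix] for the candidate ranking.
#' @return A [prediction_result] whose `cluster` attribute records the
#'   chosen cluster per gene (0 = global). With `C = 0` the result is
#'   labeled `"tsvd"`, since the two models coincide there.
#' @export
reconstruct_sim <- function(model, W, A = NULL) {
  Wd <- as_dense(W)
  if (ncol(Wd) != nrow(model$Vck[[1]]))
    stop_input("matrix has %d columns but model expects %d",
               ncol(Wd), nrow(model$Vck[[1]]))
  n_mod <- model$C + 1L
  recon <- lapply(model$Vck, function(V) (Wd %*% V) %*% t(V))
  dist2 <- vapply(recon, function(R) rowSums((R - Wd)^2), numeric(nrow(Wd)))
  dist2 <- matrix(dist2, nrow = nrow(Wd))
  # smallest c wins ties; tiny absolute slack so exact-arithmetic ties
  # (e.g. every model reconstructing perfectly) are not broken by
  # floating-point noise
  dmin <- apply(dist2, 1, min)
  tied <- dist2 <= dmin + 1e-18 + 1e-9 * dmin
  best <- apply(tied, 1, which.max)
  scores <- recon[[1]]
  for (cc in seq_len(n_mod)[-1]) {
    rows <- which(best == cc)
    if (length(rows)) scores[rows, ] <- recon[[cc]][rows, , drop = FALSE]
  }
  dimnames(scores) <- dimnames(Wd)
  out <- prediction_result(scores, A %||% binary_pattern(W),
                           method = if (model$C == 0L) "tsvd" else "sim")
  out$cluster <- stats::setNames(best - 1L, rownames(Wd))
  out
}

#' Fit the pLSA aspect model by EM
#'
#' Models the probability that gene g is annotated to term f through
#' latent topics t: P(f|g) = sum_t P(f|t) P(t|g). Rows of `theta` are the
#' per-gene topic distributions P(t|g); rows of `phi` are the per-topic
#' term distributions P(f|t). Fitting maximizes the log-likelihood
#' l = sum_{g,f} W(g,f) log sum_t P(f|t) P(t|g) by expectation-
#' maximization from a seeded random initialization; the likelihood trace
#' is non-decreasing and EM stops at a local optimum.
#'
#' @param W non-negative matrix with at least one positive entry and no
#'   all-zero rows.
#' @param n_topics number of latent topics; clamped to min(|G|,|F|).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood improvement below which EM stops
#'   (default 1e-6).
#' @param seed RNG seed for the initialization.
#' @return An object of class `plsa_model` with fields `n_topics`,
#'   `theta`, `phi`, `loglik_trace`, `seed`.
#' @export
fit_plsa <- function(W, n_topics = 500L, max_iter = 200L, tol = 1e-6,
                     seed = 1L) {
  Wd <- as_dense(W)
  if (any(Wd < 0)) stop_input("pLSA requires a non-negative matrix")
  if (all(Wd == 0)) stop_numeric("pLSA requires at least one positive entry")
  zero_rows <- rowSums(Wd) == 0
  if (any(zero_rows))
    stop_numeric("gene with no weight mass: %s",
                 (rownames(Wd) %||% as.character(seq_len(nrow(Wd))))[which(zero_rows)[1]])
  p <- min(dim(Wd))
  if (n_topics < 1L) stop_config("n_topics must be >= 1")
  if (n_topics > p) {
    warning(sprintf("n_topics=%d exceeds min(|G|,|F|)=%d; clamped", n_topics, p))
    n_topics <- p
  }
  nG <- nrow(Wd); nF <- ncol(Wd)
  init <- with_seed(seed, list(
    theta = matrix(stats::runif(nG * n_topics, 0.1, 1), nG, n_topics),
    phi = matrix(stats::runif(n_topics * nF, 0.1, 1), n_topics, nF)
  ))
  theta <- init$theta / rowSums(init$theta)
  phi <- init$phi / rowSums(init$phi)

  row_mass <- rowSums(Wd)
  pos <- Wd > 0
  trace <- numeric(0)
  ll_of <- function(theta, phi) {
    P <- theta %*% phi
    sum(Wd[pos] * log(P[pos]))
  }
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    P <- theta %*% phi
    Z <- matrix(0, nG, nF)
    Z[pos] <- Wd[pos] / P[pos]
    # M-step folded through the E-step responsibilities
    phi_new <- phi * crossprod(theta, Z)        # P(f|t) before normalization
    phi_new <- phi_new / pmax(rowSums(phi_new), .Machine$double.xmin)
    theta_new <- theta * (Z %*% t(phi))
    theta_new <- theta_new / row_mass
    theta <- theta_new; phi <- phi_new
    ll <- ll_of(theta, phi)
    if (!is.finite(ll)) stop_numeric("non-finite log-likelihood at iteration %d", it)
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) < tol * abs(prev)) break
    prev <- ll
  }
  dimnames(theta) <- list(rownames(Wd), NULL)
  dimnames(phi) <- list(NULL, colnames(Wd))
  structure(list(n_topics = as.integer(n_topics), theta = theta, phi = phi,
                 loglik_trace = trace, seed = seed),
            class = "plsa_model")
}

#' Log-likelihood of a weighted matrix under a pLSA model
#'
#' l = sum_{g,f} W(g,f) log sum_t P(f|t) P(t|g). Entries with W(g,f) = 0
#' contribute 0 regardless of the model probability; a zero probability at
#' a positive-weight entry yields -Inf with a warning.
#'
#' @param model a `plsa_model`.
#' @param W the weighted matrix.
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(model, W) {
  Wd <- as_dense(W)
  if (!all(dim(Wd) == c(nrow(model$theta), ncol(model$phi))))
    stop_input("matrix shape does not match the model")
  P <- model$theta %*% model$phi
  pos <- Wd > 0
  if (any(P[pos] == 0)) {
    warning("zero model probability at a positive-weight entry; -Inf returned")
    return(-Inf)
  }
  sum(Wd[pos] * log(P[pos]))
}

#' Normalized pLSA predictions (pLSAnorm)
#'
#' Computes P(f|g) = theta phi (each row a probability distribution over
#' terms), then rescales each gene row by its own maximum so the top term
#' of every gene scores exactly 1. Without this step, genes with many
#' plausible terms would spread their probability mass thin and rank
#' systematically below sparsely annotated genes in a global candidate
#' list; the per-row rescaling restores comparability across genes.
#'
#' @param model a fitted `plsa_model`.
#' @param A optional [annotation_matrix] defining the unobserved pairs to
#'   rank; if NULL, no ranking is built.
#' @return A [prediction_result] on the normalized scores.
#' @export
plsa_predict <- function(model, A = NULL) {
  P <- model$theta %*% model$phi
  M <- apply(P, 1, max)
  if (any(M <= 0)) stop_numeric("gene row with no probability mass")
  scores <- P / M
  prediction_result(scores, A, method = "plsa")
}

#' Prediction result: score matrix plus global candidate ranking
#'
#' @param scores real score matrix with dimnames (genes x terms).
#' @param A optional [annotation_matrix]; candidates are the pairs with
#'   A(g, f) = 0, ranked by descending score.
#' @param method label of the producing method.
#' @return An object of class `prediction_result` with fields `scores`,
#'   `ranking` (data.frame gene/term/score), `method`.
#' @export
prediction_result <- function(scores, A = NULL, method = "model") {
  scores <- as.matrix(scores)
  ranking <- if (is.null(A)) NULL else rank_candidates(scores, A)
  structure(list(scores = scores, ranking = ranking, method = method),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result (%s): %d x %d scores, %s candidates\n",
              x$method, nrow(x$scores), ncol(x$scores),
              if (is.null(x$ranking)) "no" else nrow(x$ranking)))
  invisible(x)
}

#' Rank unobserved gene-term pairs by score
#'
#' Lists every pair with A(g, f) = 0 sorted by descending score; ties are
#' broken lexicographically by gene then term identifier so rankings are
#' deterministic.
#'
#' @param scores score matrix (genes x terms, dimnames required).
#' @param A an [annotation_matrix] with matching dimnames.
#' @param top_n optional truncation of the returned list.
#' @return data.frame with columns `gene`, `term`, `score`, `rank`.
#' @export
rank_candidates <- function(scores, A, top_n = NULL) {
  stopifnot(inherits(A, "annotation_matrix"))
  scores <- as.matrix(scores)
  if (!all(dim(scores) == dim(A$A)))
    stop_input("score matrix shape does not match the annotation matrix")
  Adense <- as.matrix(A$A)
  zero <- which(Adense == 0, arr.ind = TRUE)
  df <- data.frame(gene = A$genes[zero[, 1]], term = A$terms[zero[, 2]],
                   score = scores[zero], stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene, df$term, method = "radix"), , drop = FALSE]
  if (!is.null(top_n)) df <- utils::head(df, top_n)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Write a candidate ranking as TSV
#'
#' Columns: gene, term, score, method, rank.
#'
#' @param result a [prediction_result] with a ranking.
#' @param path output file.
#' @param top_n optional truncation.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(result, path, top_n = NULL) {
  stopifnot(inherits(result, "prediction_result"), !is.null(result$ranking))
  df <- result$ranking
  if (!is.null(top_n)) df <- utils::head(df, top_n)
  out <- data.frame(gene = df$gene, term = df$term, score = df$score,
                    method = result$method, rank = df$rank)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
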