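rand_mat <- function(n, m, seed) {
  withr::local_seed(seed)
  matrix(runif(n * m), n, m,
         dimnames = list(sprintf("g%02d", 1:n), sprintf("t%02d", 1:m)))
}

test_that("fit_tsvd recovers singular structure with fixed signs", {
  I3 <- diag(3); dimnames(I3) <- list(letters[1:3], LETTERS[1:3])
  m <- fit_tsvd(I3, 3)
  expect_equal(m$singular_values, c(1, 1, 1))

  u <- c(1, 2, 3); v <- c(2, 1)
  W1 <- outer(u, v); dimnames(W1) <- list(paste0("g", 1:3), paste0("t", 1:2))
  m1 <- fit_tsvd(W1, 1)
  expect_equal(m1$singular_values[1], sqrt(sum(u^2)) * sqrt(sum(v^2)))

  W <- rand_mat(20, 15, 1)
  m <- fit_tsvd(W, 15)
  expect_lt(max(abs(crossprod(m$Vk) - diag(15))), 1e-8)
  expect_true(all(diff(m$singular_values) <= 1e-12))
  # sign convention: largest-magnitude entry of each right vector positive
  for (j in 1:15) expect_gt(m$Vk[which.max(abs(m$Vk[, j])), j], 0)
  expect_warning(fit_tsvd(W, 99), "clamped")
  expect_error(fit_tsvd(matrix(0, 2, 2)), "zero")
})

test_that("tSVD reconstruction obeys the Eckart-Young error formula", {
  W <- rand_mat(20, 15, 2)
  s_oracle <- svd(W)$d  # full-decomposition oracle
  m_full <- fit_tsvd(W, 15)
  r_full <- reconstruct_tsvd(m_full, W)
  expect_lt(norm(r_full$scores - W, "F"), 1e-8)
  for (k in c(1, 5, 10)) {
    r <- reconstruct_tsvd(fit_tsvd(W, k), W)
    expect_equal(norm(r$scores - W, "F"),
                 sqrt(sum(s_oracle[(k + 1):15]^2)), tolerance = 1e-8)
  }
  # reconstruction error is non-increasing in k
  errs <- vapply(1:15, function(k)
    norm(reconstruct_tsvd(fit_tsvd(W, k), W)$scores - W, "F"), numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("a profile inside the retained subspace is reproduced exactly", {
  W <- rand_mat(12, 8, 3)
  m <- fit_tsvd(W, 4)
  a <- matrix(2.5 * m$Vk[, 2], 1, dimnames = list("g", colnames(W)))
  r <- reconstruct_tsvd(m, a)
  expect_equal(as.vector(r$scores), as.vector(a), tolerance = 1e-10)
})

test_that("SIM with C = 0 is exactly tSVD", {
  W <- rand_mat(30, 20, 4)
  sim <- fit_sim(W, k = 6, C = 0)
  r_sim <- reconstruct_sim(sim, W)
  r_tsvd <- reconstruct_tsvd(fit_tsvd(W, 6), W)
  expect_lt(max(abs(r_sim$scores - r_tsvd$scores)), 1e-10)
  expect_true(all(r_sim$cluster == 0))
})

test_that("per-cluster correlation matrices are symmetric with the SVD
           eigenstructure at c = 0", {
  W <- rand_mat(15, 10, 5)
  sim <- fit_sim(W, k = 10, C = 3)
  for (cc in 1:3) {
    u_c <- sim$cluster_weights[[cc]]
    Tc <- crossprod(W, u_c * W)
    expect_lt(max(abs(Tc - t(Tc))), 1e-10)
  }
  # T0 = W'W: eigenvectors are right singular vectors, eigenvalues s^2
  sv <- svd(W)
  eg <- eigen(crossprod(W), symmetric = TRUE)
  expect_equal(eg$values[1:10], sv$d^2, tolerance = 1e-8)
  expect_lt(max(abs(abs(eg$vectors) - abs(sv$v))), 1e-6)
})

test_that("SIM picks the cluster model closest in L2, ties to global", {
  W <- rand_mat(10, 6, 6)
  # full-rank truncation: every model reconstructs exactly, tie -> c = 0
  sim <- fit_sim(W, k = 6, C = 2)
  r <- reconstruct_sim(sim, W)
  expect_true(all(r$cluster == 0))

  # brute-force argmin check at k < rank
  sim2 <- fit_sim(W, k = 3, C = 2)
  r2 <- reconstruct_sim(sim2, W)
  d2 <- sapply(sim2$Vck, function(V) rowSums((W %*% V %*% t(V) - W)^2))
  expect_equal(unname(r2$cluster), unname(apply(d2, 1, which.min) - 1L))
})

test_that("pLSA single-topic fit matches the closed form and a grid oracle", {
  W <- matrix(c(4, 1, 0, 2, 2, 1, 0, 1, 3), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("t", 1:3)))
  m <- fit_plsa(W, n_topics = 1, seed = 11)
  closed <- colSums(W) / sum(W)
  expect_equal(as.vector(m$phi), unname(closed), tolerance = 1e-10)
  expect_true(all(abs(m$theta - 1) < 1e-12))

  # grid-search oracle over the 2-simplex
  grid <- seq(0.01, 0.98, by = 0.01)
  best <- c(NA, NA, NA); best_ll <- -Inf
  cs <- colSums(W)
  for (p1 in grid) for (p2 in grid) {
    p3 <- 1 - p1 - p2
    if (p3 <= 0) next
    ll <- sum(cs * log(c(p1, p2, p3)))
    if (ll > best_ll) { best_ll <- ll; best <- c(p1, p2, p3) }
  }
  expect_equal(as.vector(m$phi), best, tolerance = 0.02)
})

test_that("pLSA respects probability contracts and EM monotonicity", {
  withr::local_seed(99)
  for (i in 1:5) {
    W <- matrix(rpois(12 * 8, 1.5), 12, 8,
                dimnames = list(sprintf("g%02d", 1:12), sprintf("t%02d", 1:8)))
    W <- W + (rowSums(W) == 0)  # guard against empty genes
    m <- fit_plsa(W, n_topics = 3, seed = i, max_iter = 80)
    expect_lt(max(abs(rowSums(m$theta) - 1)), 1e-10)
    expect_lt(max(abs(rowSums(m$phi) - 1)), 1e-10)
    expect_true(all(diff(m$loglik_trace) >= -1e-9))
  }
})

test_that("pLSA is deterministic for a fixed seed and rejects zero rows", {
  W <- rand_mat(8, 6, 12)
  m1 <- fit_plsa(W, 2, seed = 5)
  m2 <- fit_plsa(W, 2, seed = 5)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$phi, m2$phi)

  Wz <- W; Wz[3, ] <- 0
  expect_error(fit_plsa(Wz, 2), "g03")
})

test_that("pLSAnorm scales every gene row to max 1 from a stochastic P(f|g)", {
  W <- rand_mat(10, 7, 13)
  m <- fit_plsa(W, 3, seed = 2)
  P <- m$theta %*% m$phi
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  r <- plsa_predict(m)
  expect_true(all(apply(r$scores, 1, max) == 1))

  m1 <- fit_plsa(W, 1, seed = 2)
  r1 <- plsa_predict(m1)
  expect_lt(max(abs(sweep(r1$scores, 2, r1$scores[1, ]))), 1e-12)
})

test_that("log_likelihood matches explicit enumeration", {
  m <- list(theta = matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2, byrow = TRUE),
            phi = matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE))
  class(m) <- "plsa_model"
  W <- matrix(c(2, 0, 1, 3), 2, 2)
  P <- function(g, f) sum(m$theta[g, ] * m$phi[, f])
  byhand <- 2 * log(P(1, 1)) + 1 * log(P(1, 2)) + 3 * log(P(2, 2))
  expect_equal(log_likelihood(m, W), byhand, tolerance = 1e-12)
  expect_equal(log_likelihood(m, matrix(0, 2, 2)), 0)

  m1 <- list(theta = matrix(1, 1, 1), phi = matrix(1, 1, 1))
  class(m1) <- "plsa_model"
  expect_equal(log_likelihood(m1, matrix(5, 1, 1)), 0)
})

test_that("rank_candidates lists A = 0 pairs with deterministic tie-breaks", {
  A <- annotation_matrix(Matrix::Matrix(
    matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("t1", "t2"))),
    sparse = TRUE))
  expect_equal(nrow(rank_candidates(matrix(1, 2, 2), A)), 0)

  A2 <- annotation_matrix(Matrix::Matrix(
    matrix(c(1, 1, 0, 1), 2, 2, dimnames = list(c("g1", "g2"),
                                                c("t1", "t2"))),
    sparse = TRUE))
  r <- rank_candidates(matrix(c(0, 0, 0.7, 0), 2, 2), A2)
  expect_equal(nrow(r), 1)
  expect_equal(r$score, 0.7)

  A3 <- annotation_matrix(Matrix::Matrix(
    matrix(c(0, 0, 0, 1, 1, 1), 3, 2,
           dimnames = list(c("g1", "g2", "g3"), c("t1", "t2"))),
    sparse = TRUE))
  s3 <- matrix(c(0.9, 0.9, 0.1, 0, 0, 0), 3, 2)
  r3 <- rank_candidates(s3, A3)
  expect_equal(r3$gene, c("g1", "g2", "g3"))
  expect_equal(r3$score, c(0.9, 0.9, 0.1))
})

test_that("tSVD score bias toward heavily annotated genes exceeds SIM's", {
  cors_tsvd <- numeric(0); cors_sim <- numeric(0)
  for (seed in 1:20) {
    spec <- synthetic_spec(n_genes = 60, n_terms = 40, n_blocks = 4,
                           noise_rate = 0.05, seed = seed)
    g <- make_ontology(spec)
    corp <- make_corpus(g, spec)
    A <- build_matrix(corp$old, g, L = 3)
    W <- as.matrix(A$A)
    nann <- rowSums(W)
    r_t <- reconstruct_tsvd(fit_tsvd(W, 4), W, A)
    r_s <- reconstruct_sim(fit_sim(W, 4, 3), W, A)
    cors_tsvd <- c(cors_tsvd, cor(nann, rowMeans(r_t$scores)))
    cors_sim <- c(cors_sim, cor(nann, rowMeans(r_s$scores)))
  }
  expect_gt(mean(cors_tsvd), 0)
  expect_lte(mean(abs(cors_sim)), mean(abs(cors_tsvd)) + 1e-8)
})
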