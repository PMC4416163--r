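am <- function(M) {
  if (is.null(dimnames(M)))
    dimnames(M) <- list(sprintf("g%02d", seq_len(nrow(M))),
                        sprintf("t%02d", seq_len(ncol(M))))
  annotation_matrix(Matrix::Matrix(M, sparse = TRUE))
}

test_that("classify counts the four annotation classes with strict >", {
  A <- am(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  s <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2, byrow = TRUE)
  cc <- classify(A, s, 0.5)
  expect_equal(cc[c("AC", "AP", "AR", "NAC")],
               list(AC = 2L, AP = 0L, AR = 0L, NAC = 2L))

  hi <- classify(A, s, 1)   # tau >= max score: nothing predicted
  expect_equal(hi$AC + hi$AP, 0)
  expect_equal(hi$AR, 2); expect_equal(hi$NAC, 2)

  lo <- classify(A, s, -1)  # tau < min score: everything predicted
  expect_equal(lo$AC, 2); expect_equal(lo$AP, 2)
  expect_equal(lo$AR + lo$NAC, 0)

  # ties at tau are negatives (strict inequality)
  tie <- classify(A, s, 0.9)
  expect_equal(tie$AC, 0)
})

test_that("the four classes always partition the matrix", {
  withr::local_seed(21)
  for (i in 1:100) {
    n <- sample(3:10, 1); m <- sample(3:10, 1)
    A <- am(matrix(rbinom(n * m, 1, 0.4), n, m))
    s <- matrix(runif(n * m), n, m)
    for (tau in c(-1, runif(3), 2)) {
      cc <- classify(A, s, tau)
      expect_equal(cc$AC + cc$AP + cc$AR + cc$NAC, n * m)
    }
  }
})

test_that("perfect reconstruction gives windowed AUC 100, anti-perfect 0", {
  withr::local_seed(8)
  M <- matrix(rbinom(400, 1, 0.3), 20, 20)
  M[1, 1] <- 1; M[2, 2] <- 0
  A <- am(M)
  expect_equal(roc_curve(A, M)$auc_percent, 100)
  expect_equal(roc_curve(A, 1 - M)$auc_percent, 0)
})

test_that("ROC rates are monotone along the threshold sweep", {
  withr::local_seed(31)
  A <- am(matrix(rbinom(900, 1, 0.2), 30, 30))
  s <- matrix(runif(900), 30, 30)
  roc <- roc_curve(A, s)
  expect_true(all(diff(roc$points$APrate) >= 0))  # tau decreasing
  expect_true(all(diff(roc$points$ACrate) >= 0))
  expect_true(all(roc$points$APrate >= 0 & roc$points$APrate <= 1))
  expect_true(all(roc$points$ACrate >= 0 & roc$points$ACrate <= 1))
  expect_gte(roc$auc_percent, 0)
  expect_lte(roc$auc_percent, 100)
  expect_error(roc_curve(am(matrix(1, 2, 2)), matrix(0.5, 2, 2)),
               "degenerate")
})

test_that("scores independent of A give a near-diagonal windowed curve", {
  aucs <- numeric(10)
  for (i in 1:10) {
    withr::local_seed(100 + i)
    A <- am(matrix(rbinom(200 * 200, 1, 0.3), 200, 200))
    s <- matrix(runif(200 * 200), 200, 200)
    aucs[i] <- roc_curve(A, s)$auc_percent
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.3)
})

test_that("version comparison counts cmp / Uany / Ucur as defined", {
  g <- parse_obo(obo_chain())
  ranking <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                        term = c("a", "a", "a", "a"),
                        stringsAsFactors = FALSE)
  old_full <- annotation_corpus(data.frame(
    gene = c("g1", "g9"), term = c("a", "r"),
    evidence = c("IEA", "IDA"), namespace = "bp"))
  updated <- annotation_corpus(data.frame(
    gene = c("g2", "g3", "g4", "g4"), term = c("a", "a", "a", "a"),
    evidence = c("IDA", "IDA", "IEA", "IDA"), namespace = "bp"))
  expect_warning(
    rep4 <- version_compare(ranking, old_full, updated, g, n_top = 5),
    "only 4")
  # g1/a exists in old with IEA only -> cmp
  expect_equal(rep4$counts[["cmp"]], 1)
  # g2, g3, g4 in updated -> Uany 3; all carry curated evidence -> Ucur 3
  expect_equal(rep4$counts[["uany"]], 3)
  expect_equal(rep4$counts[["ucur"]], 3)
  expect_equal(rep4$pct_ucur, 75)
  expect_lte(rep4$pct_ucur, rep4$pct_uany)
})

test_that("unfolded matching credits predictions of general terms", {
  g <- parse_obo(obo_chain())
  ranking <- data.frame(gene = "g1", term = "a", stringsAsFactors = FALSE)
  old_full <- annotation_corpus(data.frame(gene = "g9", term = "r",
                                           evidence = "IDA",
                                           namespace = "bp"))
  # updated annotates the descendant b; unfolding implies a
  updated <- annotation_corpus(data.frame(gene = "g1", term = "b",
                                          evidence = "IDA",
                                          namespace = "bp"))
  expect_warning(r1 <- version_compare(ranking, old_full, updated, g))
  expect_equal(r1$counts[["uany"]], 1)
  expect_warning(
    r2 <- version_compare(ranking, old_full, updated, g,
                          unfold_updated = FALSE))
  expect_equal(r2$counts[["uany"]], 0)
})

test_that("dataset growth statistics reproduce published arithmetic", {
  expect_equal(annotation_delta(32232, 144358),
               list(delta = 112126, delta_percent = 347.87))
  expect_equal(annotation_delta(335063, 232945),
               list(delta = -102118, delta_percent = -30.47))
  expect_true(is.na(annotation_delta(0, 10)$delta_percent))

  corpus <- annotation_corpus(data.frame(
    gene = c("g1", "g1", "g2"), term = c("a", "b", "a"),
    evidence = "IDA", namespace = "bp"))
  st <- dataset_stats(corpus, corpus)
  expect_equal(st$delta, 0)
  expect_equal(st$delta_percent, 0)
  expect_equal(st$old$n_genes, 2)
  expect_equal(st$old$n_annotations, 3)
})
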