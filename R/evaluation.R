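#' Confusion counts between input annotations and reconstructed scores
#'
#' Given a threshold tau, a pair is predicted annotated when its score is
#' strictly greater than tau. Crossed with the binary input matrix this
#' yields four classes: AC (annotation confirmed, A=1 and score > tau,
#' akin to a true positive), AP (annotation predicted, A=0 and score >
#' tau, the novel candidate annotations), AR (annotation to be reviewed,
#' A=1 and score <= tau, akin to a false negative) and NAC (not existing
#' annotation confirmed, A=0 and score <= tau). The four counts always
#' partition the |G| x |F| matrix.
#'
#' @param A an [annotation_matrix].
#' @param scores score matrix of the same shape.
#' @param tau the decision threshold.
#' @return A list with fields `tau`, `AC`, `AP`, `AR`, `NAC`.
#' @export
classify <- function(A, scores, tau) {
  stopifnot(inherits(A, "annotation_matrix"))
  scores <- as.matrix(scores)
  if (!all(dim(scores) == dim(A$A)))
    stop_input("score matrix shape does not match the annotation matrix")
  a <- as.vector(as.matrix(A$A)) != 0
  s <- as.vector(scores)
  pred <- s > tau
  list(tau = tau,
       AC = sum(a & pred), AP = sum(!a & pred),
       AR = sum(a & !pred), NAC = sum(!a & !pred))
}

#' Windowed ROC curve over the reconstruction threshold
#'
#' Sweeps tau over all distinct score values (plus sentinels above the
#' maximum and below the minimum) and records, for each tau,
#' APrate = AP / (AP + NAC) (the fraction of input zeros promoted to
#' predictions; 1 - specificity) and ACrate = AC / (AC + AR) (the
#' fraction of input annotations confirmed; sensitivity). Because only
#' the very best-scoring candidates matter in practice, the curve is
#' evaluated on the narrow window APrate in [0, `window`] and the AUC is
#' normalized by the window width: `auc_percent` = area / window * 100,
#' so a reconstruction that exactly reproduces the input (predicting
#' nothing new) scores 100.
#'
#' @param A an [annotation_matrix] with at least one 1 and one 0.
#' @param scores score matrix of the same shape.
#' @param window upper APrate bound of the evaluation window
#'   (default 0.010).
#' @return A list of class `roc_curve` with `points` (data.frame tau /
#'   APrate / ACrate), `window`, `auc_percent`.
#' @export
roc_curve <- function(A, scores, window = 0.010) {
  stopifnot(inherits(A, "annotation_matrix"))
  scores <- as.matrix(scores)
  if (!all(dim(scores) == dim(A$A)))
    stop_input("score matrix shape does not match the annotation matrix")
  a <- as.vector(as.matrix(A$A)) != 0
  s <- as.vector(scores)
  n_one <- sum(a); n_zero <- sum(!a)
  if (n_one == 0L || n_zero == 0L)
    stop_input("degenerate annotation matrix: needs both ones and zeros")

  ord <- order(s, decreasing = TRUE)
  s_sorted <- s[ord]
  a_sorted <- a[ord]
  # counts with score strictly greater than each distinct value
  last_of_run <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  cum_one <- cumsum(a_sorted)
  cum_zero <- cumsum(!a_sorted)
  taus <- s_sorted[last_of_run]
  gt_one <- c(0, cum_one[last_of_run])[seq_along(taus)]   # AC at tau = value
  gt_zero <- c(0, cum_zero[last_of_run])[seq_along(taus)]
  tau_all <- c(taus[1] + 1, taus, taus[length(taus)] - 1)
  AC <- c(0, gt_one, n_one)
  AP <- c(0, gt_zero, n_zero)
  pts <- data.frame(tau = tau_all, APrate = AP / n_zero, ACrate = AC / n_one)

  auc <- windowed_auc(pts$APrate, pts$ACrate, window)
  structure(list(points = pts, window = window, auc_percent = auc),
            class = "roc_curve")
}

# Trapezoidal area under the piecewise-linear path (x, y) over [0, window],
# divided by the window width, as a percentage. The path is traversed in
# decreasing-tau order, so x is non-decreasing; vertical jumps (repeated x)
# contribute no area, which makes the anti-perfect predictor score 0.
windowed_auc <- function(x, y, window) {
  stopifnot(!is.unsorted(x))
  if (x[1] > 0) { x <- c(0, x); y <- c(0, y) }
  i <- which(x >= window)[1]
  if (is.na(i)) {
    x <- c(x, window); y <- c(y, y[length(y)]); i <- length(x)
  }
  if (x[i] > window) {
    x0 <- x[i - 1L]; y0 <- y[i - 1L]
    yw <- y0 + (window - x0) * (y[i] - y0) / (x[i] - x0)
    xs <- c(x[seq_len(i - 1L)], window); ys <- c(y[seq_len(i - 1L)], yw)
  } else {
    xs <- x[seq_len(i)]; ys <- y[seq_len(i)]
  }
  area <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  area / window * 100
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, window [0, %g], AUC %.2f%%\n",
              nrow(x$points), x$window, x$auc_percent))
  invisible(x)
}

#' Write ROC points as TSV (tau, APrate, ACrate)
#'
#' @param roc a [roc_curve].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate top predictions against an updated corpus version
#'
#' Takes the top `n_top` ranked candidate annotations produced by a model
#' trained on the curated part of `old_full`, and counts how many are
#' confirmed by (a) `cmp`: the pair is present in the old corpus but with
#' exclusively computational (IEA/ND) evidence, so it was invisible to the
#' model; (b) `Uany`: the pair is present in the updated corpus with any
#' evidence; (c) `Ucur`: the pair is present in the updated corpus with at
#' least one curated (non-IEA/ND) evidence code. Ucur is the most reliable
#' confirmation and is always a subset of Uany. Both corpora are unfolded
#' before matching (a predicted general term counts as confirmed when the
#' updated corpus annotates any of its descendants); `unfold_updated =
#' FALSE` restricts matching to the updated corpus as given.
#'
#' @param ranking data.frame with `gene` and `term` columns (e.g. the
#'   `ranking` of a [prediction_result]), already sorted.
#' @param old_full the complete old corpus (all evidence codes).
#' @param updated the updated corpus version.
#' @param graph the shared [ontology_graph].
#' @param n_top number of top candidates to check (default 500); if the
#'   ranking is shorter, its full length is used with a warning.
#' @param computational evidence codes considered computational.
#' @param unfold_updated unfold the corpora before matching (default TRUE).
#' @return A list of class `comparison_report`: `n_top`, `counts` and
#'   percentages `pct_cmp`, `pct_uany`, `pct_ucur`.
#' @export
version_compare <- function(ranking, old_full, updated, graph, n_top = 500L,
                            computational = c("IEA", "ND"),
                            unfold_updated = TRUE) {
  stopifnot(is.data.frame(ranking),
            all(c("gene", "term") %in% names(ranking)))
  if (nrow(ranking) < n_top) {
    warning(sprintf("ranking has only %d candidates; using all of them",
                    nrow(ranking)))
    n_top <- nrow(ranking)
  }
  top <- ranking[seq_len(n_top), , drop = FALSE]
  key <- function(g, f) paste(g, f, sep = "\r")
  top_key <- key(top$gene, top$term)

  if (unfold_updated) {
    if (!old_full$unfolded) old_full <- unfold_corpus(old_full, graph)
    if (!updated$unfolded) updated <- unfold_corpus(updated, graph)
  }
  oldr <- old_full$records
  updr <- updated$records
  old_key <- key(oldr$gene, oldr$term)
  old_curated <- unique(old_key[!(oldr$evidence %in% computational)])
  old_any <- unique(old_key)
  cmp_keys <- setdiff(old_any, old_curated)  # present with ONLY computational evidence

  upd_key <- key(updr$gene, updr$term)
  uany_keys <- unique(upd_key)
  ucur_keys <- unique(upd_key[!(updr$evidence %in% computational)])

  counts <- c(cmp = sum(top_key %in% cmp_keys),
              uany = sum(top_key %in% uany_keys),
              ucur = sum(top_key %in% ucur_keys))
  structure(list(n_top = n_top, counts = counts,
                 pct_cmp = counts[["cmp"]] / n_top * 100,
                 pct_uany = counts[["uany"]] / n_top * 100,
                 pct_ucur = counts[["ucur"]] / n_top * 100),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(paste0("comparison_report (top %d): cmp %.1f%%, ",
                     "Uany %.1f%%, Ucur %.1f%%\n"),
              x$n_top, x$pct_cmp, x$pct_uany, x$pct_ucur))
  invisible(x)
}

#' Quantitative comparison of two corpus versions
#'
#' Counts distinct genes, distinct terms and distinct (gene, term)
#' annotations in each corpus version and reports the annotation growth
#' Delta = a_new - a_old and Delta% = Delta / a_old * 100. Displayed
#' Delta% values are truncated toward zero at 2 decimals, matching the
#' convention of published GO dataset summary tables.
#'
#' @param old,new two [annotation_corpus] objects.
#' @return A list of class `dataset_stats` with per-version counts,
#'   `delta` and `delta_percent`.
#' @export
dataset_stats <- function(old, new) {
  count1 <- corpus_counts(old)
  count2 <- corpus_counts(new)
  structure(c(list(old = count1, new = count2),
              annotation_delta(count1$n_annotations, count2$n_annotations)),
            class = "dataset_stats")
}

corpus_counts <- function(corpus) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  r <- corpus$records
  list(n_genes = length(unique(r$gene)),
       n_terms = length(unique(r$term)),
       n_annotations = nrow(unique(r[c("gene", "term")])))
}

#' Annotation-count growth between two corpus versions
#'
#' @param a_old,a_new distinct-annotation counts of the old and new
#'   corpus versions.
#' @return list with `delta` (a_new - a_old) and `delta_percent`
#'   (Delta / a_old * 100, truncated toward zero at 2 decimals; `NA` when
#'   `a_old` is 0).
#' @export
annotation_delta <- function(a_old, a_new) {
  delta <- a_new - a_old
  pct <- if (a_old == 0) NA_real_ else trunc(delta / a_old * 100 * 100) / 100
  list(delta = delta, delta_percent = pct)
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf("dataset_stats: #a %d -> %d, Delta %d (%.2f%%)\n",
              x$old$n_annotations, x$new$n_annotations, x$delta,
              x$delta_percent))
  invisible(x)
}
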