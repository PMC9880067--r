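# Verification of a selected gene subset with a radial-kernel SVM, plus the
# summary metrics: test accuracy, misjudgment count, redundancy-removal
# rate.

#' Train/test SVM verification of a gene subset
#'
#' Trains a C-classification SVM with an RBF kernel (via \pkg{e1071}) on the
#' training samples restricted to `genes`, predicts the test samples and
#' reports the accuracy (percent) and the number of misjudged test samples.
#' Unless given, `gamma` defaults to `1 / (n_features * var(train))` with
#' `var(train)` the overall variance of the training feature matrix; the
#' features are used unscaled (expression values are already on a common
#' intensity scale). The run is deterministic given (seed, params, split).
#'
#' @param x genes-by-samples expression matrix.
#' @param labels named two-level factor.
#' @param split an `"fgx_split"` from [split_train_test()].
#' @param genes nonempty character vector of gene ids to use as features.
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width; `NULL` for the default above.
#' @param seed RNG seed (recorded; libsvm training here is deterministic).
#' @return an `"fgx_eval"` list: `n_features`, `genes`, `accuracy` (percent),
#'   `misjudgments`, per-sample `predictions`, `cost`, `gamma`, `seed`, and
#'   the fitted `model`.
#' @export
evaluate_classifier <- function(x, labels, split, genes, cost = 1,
                                gamma = NULL, seed = 1L) {
  labels <- match_labels(x, labels)
  genes <- as.character(genes)
  if (!length(genes)) stopf("an empty gene list cannot be evaluated")
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stopf("gene(s) absent from the matrix: %s", toString(head(missing, 5L)))
  if (!inherits(split, "fgx_split")) stopf("'split' must be an fgx_split")
  bad <- setdiff(c(split$train_ids, split$test_ids), colnames(x))
  if (length(bad))
    stopf("split refers to unknown sample(s): %s", toString(head(bad, 5L)))
  xt <- t(x[genes, , drop = FALSE])
  tr <- xt[split$train_ids, , drop = FALSE]
  te <- xt[split$test_ids, , drop = FALSE]
  ytr <- droplevels(labels[split$train_ids])
  yte <- labels[split$test_ids]
  if (nlevels(ytr) < 2L) stopf("training set contains a single class")
  if (is.null(gamma)) {
    v <- var(as.vector(tr))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(tr) * v) else 1 / ncol(tr)
  }
  model <- with_seed(seed,
    e1071::svm(x = tr, y = ytr, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE))
  pred <- predict(model, te)
  acc <- 100 * mean(as.character(pred) == as.character(yte))
  structure(list(n_features = length(genes), genes = genes,
                 accuracy = acc,
                 misjudgments = sum(as.character(pred) != as.character(yte)),
                 predictions = setNames(as.character(pred), rownames(te)),
                 cost = cost, gamma = gamma, seed = as.integer(seed),
                 model = model),
            class = "fgx_eval")
}

#' @export
print.fgx_eval <- function(x, ...) {
  cat(sprintf("SVM (RBF) verification: %d feature gene(s)\n", x$n_features))
  cat(sprintf("  test accuracy %.2f%%, %d misjudgment(s) of %d test samples\n",
              x$accuracy, x$misjudgments, length(x$predictions)))
  cat(sprintf("  C = %g, gamma = %g\n", x$cost, x$gamma))
  invisible(x)
}

#' Accuracy as a function of the number of feature genes
#'
#' Evaluates the classifier for each requested gene count, taking the
#' top-count genes by contribution rate each time.
#'
#' @param x genes-by-samples expression matrix.
#' @param labels named two-level factor.
#' @param split an `"fgx_split"`.
#' @param contributions named gene-contribution vector
#'   ([gene_contribution()]).
#' @param counts integer vector of feature-gene counts to try.
#' @param cost,gamma,seed passed to [evaluate_classifier()].
#' @return data frame with columns `n_genes`, `accuracy_pct`,
#'   `misjudgments`; the full reports are attached as attribute `reports`.
#' @export
sweep_feature_counts <- function(x, labels, split, contributions, counts,
                                 cost = 1, gamma = NULL, seed = 1L) {
  counts <- as.integer(counts)
  if (any(counts < 1L) || any(counts > length(contributions)))
    stopf("all counts must lie in [1, %d]", length(contributions))
  reports <- lapply(counts, function(k) {
    genes <- names(select_feature_genes(contributions, k))
    evaluate_classifier(x, labels, split, genes, cost = cost, gamma = gamma,
                        seed = seed)
  })
  out <- data.frame(n_genes = counts,
                    accuracy_pct = vapply(reports, `[[`, 0, "accuracy"),
                    misjudgments = vapply(reports, `[[`, 0L, "misjudgments"))
  attr(out, "reports") <- reports
  out
}

#' Redundancy-removal rate
#'
#' The percentage of input genes not retained as feature genes,
#' `100 * (total - kept) / total`, computed in exact double arithmetic from
#' the two integer counts (keeping 5 of 2000 genes gives exactly 99.75).
#'
#' @param total total number of input genes (> 0).
#' @param kept number of genes kept, 0 <= kept <= total.
#' @return a `"removal_report"`: list with `total_genes`, `kept_genes`,
#'   `removal_rate` (percent).
#' @export
removal_rate <- function(total, kept) {
  if (!is.numeric(total) || length(total) != 1L || total <= 0 ||
      total != trunc(total))
    stopf("'total' must be a single positive integer")
  if (!is.numeric(kept) || length(kept) != 1L || kept < 0 ||
      kept != trunc(kept))
    stopf("'kept' must be a single nonnegative integer")
  if (kept > total)
    stopf("'kept' (%d) exceeds 'total' (%d)", kept, total)
  structure(list(total_genes = as.integer(total), kept_genes = as.integer(kept),
                 removal_rate = 100 * (total - kept) / total),
            class = "removal_report")
}

#' @export
print.removal_report <- function(x, ...) {
  cat(sprintf("redundancy removal: kept %d of %d genes, removal rate %.2f%%\n",
              x$kept_genes, x$total_genes, x$removal_rate))
  invisible(x)
}
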