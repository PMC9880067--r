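# The main fitting function: the full hybrid feature-gene extraction path,
# returning a classed object with the usual modelling methods.

#' Hybrid feature-gene extraction
#'
#' Runs the complete extraction path on a two-class expression matrix:
#' per-gene class statistics; Bhattacharyya-distance and Gini-index scoring;
#' top-k selection under each criterion; intersection into the common-gene
#' set; PCA of the common genes' correlation matrix; component retention by
#' eigenvalue threshold; gene contribution rates over the retained
#' components; selection of the final feature genes; and (when a split is
#' available) SVM verification with the redundancy-removal rate.
#'
#' An SVM model for [predict.fgx()] is always fitted on the feature genes --
#' on the training samples when a split is given, otherwise on all samples.
#'
#' @param x genes-by-samples expression matrix, or a `"synth_dataset"` (its
#'   matrix and labels are used).
#' @param labels named two-level factor over the samples; ignored when `x`
#'   is a synthetic dataset.
#' @param top_k genes kept per criterion before intersecting (default 200).
#' @param n_features final number of feature genes (default 5).
#' @param retain_rule,eigen_threshold component retention rule and threshold
#'   (default: eigenvalue > 2), see [retain_components()].
#' @param contribution_weight loading magnitude used in the gene
#'   contribution rate, `"abs"` (default) or `"squared"`.
#' @param literal_bottom keep the least informative k per criterion instead
#'   of the most informative (see [select_top_k()]).
#' @param train_counts optional named per-class training-set sizes; when
#'   given, a stratified split is drawn with `seed` and the feature genes
#'   are verified on the held-out test samples.
#' @param split optional precomputed `"fgx_split"` (overrides
#'   `train_counts`).
#' @param svm_cost,svm_gamma SVM parameters, see [evaluate_classifier()].
#' @param seed RNG seed for the split and classifier; the whole fit is
#'   deterministic given `(x, labels, arguments, seed)`.
#' @return an object of class `"fgx"` with components `feature_genes` (named
#'   contribution rates), `contributions` (all common genes), `selection`,
#'   `scores`, `pca`, `evaluation` (`NULL` without a split), `removal`,
#'   `split`, `model`, and bookkeeping fields. Methods: [print.fgx()],
#'   [summary.fgx()], [coef.fgx()], [predict.fgx()], [plot.fgx()].
#' @examples
#' d <- synth_data(synth_config(n_genes = 300, n_informative = 10,
#'                              n_pos = 14, n_neg = 11, seed = 5))
#' fit <- fgx(d, top_k = 60, n_features = 5,
#'            train_counts = c(lesion = 10, normal = 5), seed = 5)
#' fit
#' coef(fit)[1:5]
#' @export
fgx <- function(x, labels = NULL, top_k = 200L, n_features = 5L,
                retain_rule = c("eigenvalue", "cumulative"),
                eigen_threshold = NULL,
                contribution_weight = c("abs", "squared"),
                literal_bottom = FALSE,
                train_counts = NULL, split = NULL,
                svm_cost = 1, svm_gamma = NULL, seed = 1L) {
  cl <- match.call()
  if (inherits(x, "synth_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$matrix
  }
  retain_rule <- match.arg(retain_rule)
  contribution_weight <- match.arg(contribution_weight)
  labels <- match_labels(x, labels)

  st <- class_stats(x, labels)
  b_scores <- bhattacharyya_score(st)
  g_scores <- gini_score(x, labels)
  b_sel <- select_top_k(rank_genes(b_scores), top_k, literal_bottom)
  g_sel <- select_top_k(rank_genes(g_scores), top_k, literal_bottom)
  common <- suppressWarnings(intersect_selections(b_sel, g_sel))
  if (length(common) < 2L)
    stopf(paste0("only %d gene(s) survive both filters; increase 'top_k' ",
                 "(currently %d) so the two top lists overlap"),
          length(common), top_k)
  if (n_features > length(common))
    stopf("n_features = %d exceeds the %d common genes; lower 'n_features' or raise 'top_k'",
          n_features, length(common))

  std <- standardize_genes(x[common, , drop = FALSE])
  eig <- eigendecompose(correlation_matrix(std))
  ctab <- contribution_rates(eig)
  t_ret <- retain_components(eig, rule = retain_rule, threshold = eigen_threshold)
  contrib <- gene_contribution(eig, t_ret, weight = contribution_weight)
  features <- select_feature_genes(contrib, n_features)

  if (is.null(split) && !is.null(train_counts))
    split <- split_train_test(labels, train_counts, seed = seed)
  evaluation <- NULL
  if (!is.null(split)) {
    evaluation <- evaluate_classifier(x, labels, split, names(features),
                                      cost = svm_cost, gamma = svm_gamma,
                                      seed = seed)
    model <- evaluation$model
  } else {
    all_split <- structure(list(train_ids = colnames(x), test_ids = colnames(x)),
                           class = "fgx_split")
    model <- evaluate_classifier(x, labels, all_split, names(features),
                                 cost = svm_cost, gamma = svm_gamma,
                                 seed = seed)$model
  }

  structure(list(
    call = cl,
    feature_genes = features,
    contributions = contrib,
    selection = list(bhattacharyya = b_sel, gini = g_sel, common = common,
                     top_k = as.integer(top_k),
                     eliminated = c(bhattacharyya = attr(b_sel, "eliminated"),
                                    gini = attr(g_sel, "eliminated"))),
    scores = list(bhattacharyya = b_scores, gini = g_scores),
    pca = list(eigen = eig, components = ctab, n_retained = t_ret,
               rule = retain_rule,
               threshold = if (is.null(eigen_threshold)) {
                 if (retain_rule == "eigenvalue") 2 else 0.85
               } else eigen_threshold,
               weight = contribution_weight),
    evaluation = evaluation,
    removal = removal_rate(nrow(x), length(features)),
    split = split,
    model = model,
    labels = labels,
    class_counts = table(labels),
    n_genes = nrow(x), n_samples = ncol(x),
    seed = as.integer(seed)
  ), class = "fgx")
}

#' @describeIn fgx compact view of the fitted extraction.
#' @param ... unused.
#' @export
print.fgx <- function(x, ...) {
  cc <- x$class_counts
  cat("Hybrid feature-gene extraction (Bhattacharyya + Gini filter, PCA)\n")
  cat(sprintf("  data: %d genes x %d samples (%s)\n", x$n_genes, x$n_samples,
              paste(sprintf("%s=%d", names(cc), cc), collapse = ", ")))
  cat(sprintf("  filter: top-%d per criterion -> %d common genes\n",
              x$selection$top_k, length(x$selection$common)))
  cat(sprintf("  PCA: %d component(s) retained (%s %s %g), weight = %s\n",
              x$pca$n_retained, x$pca$rule,
              if (x$pca$rule == "eigenvalue") ">" else ">=", x$pca$threshold,
              x$pca$weight))
  fg <- x$feature_genes
  cat(sprintf("  feature genes (%d): %s\n", length(fg),
              paste(sprintf("%s (%.4f)", names(fg), fg), collapse = ", ")))
  print(x$removal)
  if (!is.null(x$evaluation))
    cat(sprintf("  test accuracy %.2f%% (%d misjudgment(s) of %d)\n",
                x$evaluation$accuracy, x$evaluation$misjudgments,
                length(x$evaluation$predictions)))
  invisible(x)
}

#' @describeIn fgx detailed summary (component table, contributions,
#'   verification).
#' @param object an `"fgx"` fit.
#' @export
summary.fgx <- function(object, ...) {
  structure(list(fit = object,
                 components = object$pca$components,
                 contributions = sort(object$contributions, decreasing = TRUE)),
            class = "summary.fgx")
}

#' @export
print.summary.fgx <- function(x, ...) {
  print(x$fit)
  t_ret <- x$fit$pca$n_retained
  cat("\nPrincipal components (retained block above the line):\n")
  tab <- x$fit$pca$components
  tab$contribution <- sprintf("%.3f%%", 100 * tab$contribution)
  tab$cumulative <- sprintf("%.3f%%", 100 * tab$cumulative)
  tab$eigenvalue <- sprintf("%.3f", tab$eigenvalue)
  print(head(tab, max(t_ret + 3L, 8L)), row.names = FALSE)
  cat(sprintf("\nTop gene contributions (of %d common genes):\n",
              length(x$contributions)))
  print(signif(head(x$contributions, 10L), 4))
  invisible(x)
}

#' @describeIn fgx gene contribution rates of all common genes, largest
#'   first.
#' @export
coef.fgx <- function(object, ...) {
  sort(object$contributions, decreasing = TRUE)
}

#' Classify new samples with a fitted extraction
#'
#' Applies the stored RBF-SVM (trained on the fit's feature genes) to new
#' samples.
#'
#' @param object an `"fgx"` fit.
#' @param newdata genes-by-samples matrix containing at least the fit's
#'   feature genes; defaults to predicting the fit's own test samples when a
#'   split was used.
#' @param ... unused.
#' @return named factor of predicted class labels.
#' @export
predict.fgx <- function(object, newdata = NULL, ...) {
  genes <- names(object$feature_genes)
  if (is.null(newdata)) {
    if (is.null(object$evaluation))
      stopf("no 'newdata' given and the fit has no test split to re-predict")
    return(factor(object$evaluation$predictions,
                  levels = levels(object$labels)))
  }
  if (!is.matrix(newdata) || !is.numeric(newdata))
    stopf("'newdata' must be a numeric genes-by-samples matrix")
  missing <- setdiff(genes, rownames(newdata))
  if (length(missing))
    stopf("'newdata' lacks feature gene(s): %s", toString(head(missing, 5L)))
  pred <- predict(object$model, t(newdata[genes, , drop = FALSE]))
  setNames(factor(as.character(pred), levels = levels(object$labels)),
           colnames(newdata))
}

#' Scree and gene-contribution plot of a fitted extraction
#'
#' Left panel: eigenvalues with the retention threshold; right panel: the
#' largest gene contribution rates, feature genes highlighted.
#'
#' @param x an `"fgx"` fit.
#' @param n_bars how many genes to show in the contribution panel.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.fgx <- function(x, n_bars = 20L, ...) {
  op <- par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(par(op))
  ev <- x$pca$components$eigenvalue
  barplot(ev, names.arg = x$pca$components$component, las = 2,
          ylab = "eigenvalue", main = "Correlation-matrix spectrum",
          border = NA)
  if (x$pca$rule == "eigenvalue") abline(h = x$pca$threshold, lty = 2)
  g <- sort(x$contributions, decreasing = TRUE)
  g <- head(g, n_bars)
  cols <- ifelse(names(g) %in% names(x$feature_genes), "grey25", "grey75")
  barplot(g, names.arg = names(g), las = 2, col = cols, border = NA,
          ylab = "gene contribution rate",
          main = sprintf("Gene contributions (t = %d)", x$pca$n_retained))
  legend("topright", bty = "n", fill = c("grey25", "grey75"),
         legend = c("feature gene", "other common gene"))
  invisible(x)
}

#' Write the stage artifacts of a fitted extraction
#'
#' Writes every intermediate table as TSV plus one machine-readable
#' `summary.json`. Output is a deterministic function of the fit, so two
#' identical runs produce byte-identical files.
#'
#' @param fit an `"fgx"` fit.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fgx_report <- function(fit, dir) {
  if (!inherits(fit, "fgx")) stopf("'fit' must be an fgx object")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.12g", v))
  for (crit in names(fit$scores)) {
    s <- fit$scores[[crit]]
    wtsv(data.frame(gene_id = s$gene_id, score = fmt(s$score),
                    degenerate = s$degenerate),
         sprintf("scores_%s.tsv", crit))
  }
  all_genes <- fit$scores$bhattacharyya$gene_id
  wtsv(data.frame(gene_id = all_genes,
                  in_bhattacharyya = all_genes %in% fit$selection$bhattacharyya,
                  in_gini = all_genes %in% fit$selection$gini,
                  in_common = all_genes %in% fit$selection$common),
       "selection.tsv")
  ctab <- fit$pca$components
  wtsv(data.frame(component = ctab$component,
                  eigenvalue = fmt(ctab$eigenvalue),
                  contribution_pct = fmt(100 * ctab$contribution),
                  cumulative_pct = fmt(100 * ctab$cumulative)),
       "pca_components.tsv")
  wtsv(data.frame(gene_id = names(fit$contributions),
                  contribution = fmt(as.numeric(fit$contributions)),
                  feature_gene = names(fit$contributions) %in%
                    names(fit$feature_genes)),
       "gene_contributions.tsv")
  if (!is.null(fit$split))
    wtsv(data.frame(sample_id = c(fit$split$train_ids, fit$split$test_ids),
                    role = rep(c("train", "test"),
                               c(length(fit$split$train_ids),
                                 length(fit$split$test_ids)))),
         "split.tsv")
  if (!is.null(fit$evaluation))
    wtsv(data.frame(n_genes = fit$evaluation$n_features,
                    accuracy_pct = fmt(fit$evaluation$accuracy),
                    misjudgments = fit$evaluation$misjudgments),
         "evaluation.tsv")
  summary_list <- fgx_summary_list(fit)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary_list, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["summary.json"]] <- p
  invisible(unlist(paths))
}

# machine-readable run summary; every default the method leaves open
# (variants, thresholds, seed) is recorded so a run is auditable
fgx_summary_list <- function(fit) {
  cc <- fit$class_counts
  out <- list(
    n_genes = fit$n_genes,
    n_samples = fit$n_samples,
    class_counts = as.list(setNames(as.integer(cc), names(cc))),
    top_k = fit$selection$top_k,
    n_selected = list(bhattacharyya = length(fit$selection$bhattacharyya),
                      gini = length(fit$selection$gini)),
    n_eliminated = as.list(fit$selection$eliminated),
    n_common = length(fit$selection$common),
    pca = list(rule = fit$pca$rule, threshold = fit$pca$threshold,
               n_retained = fit$pca$n_retained, weight = fit$pca$weight,
               eigenvalues = round(fit$pca$components$eigenvalue, 10)),
    feature_genes = as.list(setNames(as.numeric(fit$feature_genes),
                                     names(fit$feature_genes))),
    removal_rate_pct = fit$removal$removal_rate,
    seed = fit$seed
  )
  if (!is.null(fit$evaluation))
    out$evaluation <- list(accuracy_pct = fit$evaluation$accuracy,
                           misjudgments = fit$evaluation$misjudgments,
                           n_test = length(fit$evaluation$predictions),
                           cost = fit$evaluation$cost,
                           gamma = fit$evaluation$gamma)
  out
}
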