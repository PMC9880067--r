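# Per-gene filter scores for two-class expression data.
#
# Every criterion returns a "gene_scores" data frame (gene_id, score,
# degenerate) carrying the criterion name, its ranking direction, and
# whether ranking uses |score|. Degenerate genes (zero range or a singular
# denominator) are flagged and excluded from ranking, never fatal: real
# matrices contain constant probes.

new_gene_scores <- function(gene_id, score, criterion, direction,
                            use_abs = FALSE, degenerate = NULL) {
  if (is.null(degenerate)) degenerate <- !is.finite(score)
  out <- data.frame(gene_id = as.character(gene_id), score = as.numeric(score),
                    degenerate = as.logical(degenerate), stringsAsFactors = FALSE)
  attr(out, "criterion") <- criterion
  attr(out, "direction") <- direction
  attr(out, "use_abs") <- use_abs
  class(out) <- c("gene_scores", "data.frame")
  if (any(out$degenerate))
    warnf("%d gene(s) have a degenerate '%s' score and are excluded from ranking",
          sum(out$degenerate), criterion)
  out
}

#' @export
print.gene_scores <- function(x, ...) {
  cat(sprintf("gene scores: criterion '%s' (%s%s), %d genes, %d degenerate\n",
              attr(x, "criterion"), attr(x, "direction"),
              if (isTRUE(attr(x, "use_abs"))) ", ranked by |score|" else "",
              nrow(x), sum(x$degenerate)))
  print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Per-gene class-conditional statistics
#'
#' Means, standard deviations and variances of each gene within each of the
#' two classes, with the sample (n-1) variance convention. The first factor
#' level is the positive class.
#'
#' @param x genes-by-samples expression matrix.
#' @param labels named two-level factor over the matrix samples.
#' @return a `"class_stats"` data frame with columns `gene_id`, `mean_pos`,
#'   `mean_neg`, `sd_pos`, `sd_neg`, `var_pos`, `var_neg`, `n_pos`, `n_neg`.
#' @export
class_stats <- function(x, labels) {
  labels <- match_labels(x, labels)
  lev <- levels(labels)
  xp <- x[, labels == lev[1L], drop = FALSE]
  xn <- x[, labels == lev[2L], drop = FALSE]
  if (ncol(xp) < 2L || ncol(xn) < 2L)
    stopf("both classes need at least 2 samples (got %d and %d)", ncol(xp), ncol(xn))
  vp <- row_var(xp)
  vn <- row_var(xn)
  out <- data.frame(gene_id = rownames(x),
                    mean_pos = rowMeans(xp), mean_neg = rowMeans(xn),
                    sd_pos = sqrt(vp), sd_neg = sqrt(vn),
                    var_pos = vp, var_neg = vn,
                    n_pos = ncol(xp), n_neg = ncol(xn),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "positive_class") <- lev[1L]
  attr(out, "negative_class") <- lev[2L]
  class(out) <- c("class_stats", "data.frame")
  out
}

#' Bhattacharyya distance score
#'
#' Gaussian two-class Bhattacharyya distance per gene,
#' \deqn{Bd = \frac{(\eta_1-\eta_2)^2}{8(\omega_1^2+\omega_2^2)} +
#'   \frac{1}{2}\ln\frac{\omega_1^2+\omega_2^2}{2\omega_1\omega_2},}
#' combining mean separation and variance disparity; larger is more
#' informative. Note the 1/8 coefficient on the mean term: the classical
#' Gaussian Bhattacharyya distance carries 1/4 there, but the 1/8 form is
#' kept deliberately -- the two differ by a monotone reweighting of the mean
#' term and induce very similar rankings. Genes with a zero class variance
#' are flagged degenerate.
#'
#' @param stats a [class_stats()] table.
#' @return a `"gene_scores"` table, direction higher-is-informative.
#' @export
bhattacharyya_score <- function(stats) {
  v1 <- stats$var_pos; v2 <- stats$var_neg
  dm <- stats$mean_pos - stats$mean_neg
  deg <- !(v1 > 0 & v2 > 0)
  bd <- rep(NA_real_, length(dm))
  ok <- !deg
  bd[ok] <- dm[ok]^2 / (8 * (v1[ok] + v2[ok])) +
    0.5 * log((v1[ok] + v2[ok]) / (2 * sqrt(v1[ok] * v2[ok])))
  new_gene_scores(stats$gene_id, bd, "bhattacharyya", "higher_is_informative",
                  degenerate = deg)
}

#' Discretize one gene's expression onto integer levels 0..20
#'
#' Min-max scales the values to \[0, 20\] and rounds half up
#' (`trunc(20*(x-min)/(max-min) + 0.5)`), so the minimum maps to level 0 and
#' the maximum to level 20 exactly. Positive affine transforms of the input
#' leave the levels unchanged.
#'
#' @param values numeric vector of one gene's expression across samples;
#'   must not be constant.
#' @return integer vector of levels in \[0, 20\].
#' @export
discretize_gene <- function(values) {
  if (!is.numeric(values) || !all(is.finite(values)))
    stopf("'values' must be finite numeric")
  r <- range(values)
  if (r[1L] == r[2L])
    stopf("cannot discretize a constant gene (max == min)")
  lv <- as.integer(trunc(20 * (values - r[1L]) / (r[2L] - r[1L]) + 0.5))
  names(lv) <- names(values)
  lv
}

#' Gini impurity of a level histogram
#'
#' `1 - sum(p^2)` over the relative frequencies of the discretized levels
#' within one class; 0 for a pure class, at most 20/21 over 21 levels.
#'
#' @param level_counts nonnegative integer counts per level (any length).
#' @return the Gini impurity, in \[0, 1 - 1/length(level_counts)\].
#' @export
gini_level <- function(level_counts) {
  if (!is.numeric(level_counts) || any(level_counts < 0))
    stopf("'level_counts' must be nonnegative counts")
  n <- sum(level_counts)
  if (n < 1) stopf("empty class: no samples to compute a Gini index from")
  p <- level_counts / n
  1 - sum(p^2)
}

#' Gini index score per gene
#'
#' Each gene is discretized onto levels 0..20 across all samples
#' ([discretize_gene()]); within each class the Gini impurity of the level
#' distribution is computed and the two are combined with class-proportion
#' weights n_k/n. Smaller values mean more class-pure expression levels,
#' i.e. more taxonomic information, so the ranking direction is
#' lower-is-informative. Constant genes are flagged degenerate.
#'
#' @param x genes-by-samples expression matrix.
#' @param labels named two-level factor.
#' @return a `"gene_scores"` table, direction lower-is-informative.
#' @export
gini_score <- function(x, labels) {
  labels <- match_labels(x, labels)
  lev <- levels(labels)
  idx <- lapply(lev, function(l) which(labels == l))
  n <- length(labels)
  w <- vapply(idx, length, 1L) / n
  G <- nrow(x)
  sc <- rep(NA_real_, G)
  deg <- logical(G)
  for (i in seq_len(G)) {
    v <- x[i, ]
    r <- range(v)
    if (r[1L] == r[2L]) { deg[i] <- TRUE; next }
    s <- trunc(20 * (v - r[1L]) / (r[2L] - r[1L]) + 0.5)
    g <- 0
    for (k in 1:2) {
      p <- tabulate(s[idx[[k]]] + 1, nbins = 21L) / length(idx[[k]])
      g <- g + w[k] * (1 - sum(p * p))
    }
    sc[i] <- g
  }
  new_gene_scores(rownames(x), sc, "gini", "lower_is_informative",
                  degenerate = deg)
}

# shared body of the FSC and signal-to-noise criteria, which have the same
# printed form: mean difference over a combination of the class sds
mean_over_sd_score <- function(stats, variant, criterion) {
  dm <- stats$mean_pos - stats$mean_neg
  den <- if (variant == "as_printed") stats$sd_pos - stats$sd_neg
         else stats$sd_pos + stats$sd_neg
  deg <- den == 0
  sc <- rep(NA_real_, length(dm))
  sc[!deg] <- dm[!deg] / den[!deg]
  new_gene_scores(stats$gene_id, sc, criterion, "higher_is_informative",
                  use_abs = TRUE, degenerate = deg)
}

#' Signal-to-noise ratio score
#'
#' Mean difference over a combination of the class standard deviations.
#' `variant = "standard_sum"` (default) uses the classical sum denominator
#' `sd_pos + sd_neg`; `variant = "as_printed"` uses the difference
#' `sd_pos - sd_neg`, which is singular when the sds are equal and is
#' provided for fidelity only. Ranking uses `|score|`.
#'
#' @param stats a [class_stats()] table.
#' @param variant denominator convention, see Details.
#' @return a `"gene_scores"` table.
#' @export
snr_score <- function(stats, variant = c("standard_sum", "as_printed")) {
  mean_over_sd_score(stats, match.arg(variant), "snr")
}

#' Feature score criterion (FSC)
#'
#' Identical in form to [snr_score()] (the two criteria share the same
#' printed formula); kept as a separately named criterion.
#'
#' @inheritParams snr_score
#' @return a `"gene_scores"` table.
#' @export
fsc_score <- function(stats, variant = c("standard_sum", "as_printed")) {
  mean_over_sd_score(stats, match.arg(variant), "fsc")
}

#' Fisher discriminant ratio score
#'
#' Squared mean difference over a combination of the class variances:
#' `standard_sum` (default) divides by `var_pos + var_neg` (the classical
#' Fisher ratio), `as_printed` by `var_pos - var_neg` (singular and
#' sign-unstable; fidelity only).
#'
#' @inheritParams snr_score
#' @return a `"gene_scores"` table, direction higher-is-informative.
#' @export
fisher_score <- function(stats, variant = c("standard_sum", "as_printed")) {
  variant <- match.arg(variant)
  dm <- stats$mean_pos - stats$mean_neg
  den <- if (variant == "as_printed") stats$var_pos - stats$var_neg
         else stats$var_pos + stats$var_neg
  deg <- den == 0
  sc <- rep(NA_real_, length(dm))
  sc[!deg] <- dm[!deg]^2 / den[!deg]
  new_gene_scores(stats$gene_id, sc, "fisher", "higher_is_informative",
                  degenerate = deg)
}

#' Welch t-statistic score
#'
#' `t = (mean_pos - mean_neg) / sqrt(var_pos/n_pos + var_neg/n_neg)`; used
#' purely as a ranking score (|t|, higher is more informative), no p-values.
#' Two constant classes with equal means give t = 0; with unequal means the
#' gene is flagged degenerate.
#'
#' @param x genes-by-samples expression matrix.
#' @param labels named two-level factor.
#' @return a `"gene_scores"` table.
#' @export
t_statistic_score <- function(x, labels) {
  st <- class_stats(x, labels)
  dm <- st$mean_pos - st$mean_neg
  se2 <- st$var_pos / st$n_pos + st$var_neg / st$n_neg
  deg <- se2 == 0 & dm != 0
  t <- rep(NA_real_, length(dm))
  zero <- se2 == 0 & dm == 0
  t[zero] <- 0
  ok <- se2 > 0
  t[ok] <- dm[ok] / sqrt(se2[ok])
  new_gene_scores(st$gene_id, t, "t_statistic", "higher_is_informative",
                  use_abs = TRUE, degenerate = deg)
}

#' Compute one or more filter criteria at once
#'
#' Convenience wrapper used by the CLI `score` subcommand.
#'
#' @param x genes-by-samples expression matrix.
#' @param labels named two-level factor.
#' @param criteria criteria to compute.
#' @param variant denominator variant for snr/fsc/fisher.
#' @return named list of `"gene_scores"` tables.
#' @export
score_genes <- function(x, labels,
                        criteria = c("bhattacharyya", "gini", "snr", "fsc",
                                     "fisher", "t_statistic"),
                        variant = c("standard_sum", "as_printed")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  variant <- match.arg(variant)
  st <- class_stats(x, labels)
  setNames(lapply(criteria, function(cr) {
    switch(cr,
           bhattacharyya = bhattacharyya_score(st),
           gini = gini_score(x, labels),
           snr = snr_score(st, variant),
           fsc = fsc_score(st, variant),
           fisher = fisher_score(st, variant),
           t_statistic = t_statistic_score(x, labels))
  }), criteria)
}
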