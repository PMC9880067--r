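# PCA-based feature-gene extraction: standardize the common-gene submatrix
# (samples as observations, genes as variables), eigendecompose the
# gene-gene correlation matrix, retain components by eigenvalue threshold,
# and score genes by their normalized share of absolute loadings on the
# retained components.

#' Standardize a gene submatrix for PCA
#'
#' Transposes a genes-by-samples matrix into the samples-by-genes
#' orientation (observations = samples, variables = genes) and scales each
#' gene column to mean 0 and sample standard deviation 1 (n-1 denominator).
#'
#' @param x genes-by-samples expression matrix with no constant gene.
#' @return numeric matrix, samples x genes, standardized columns.
#' @export
standardize_genes <- function(x) {
  check_expression(x)
  v <- row_var(x)
  const <- rownames(x)[v == 0]
  if (length(const))
    stopf("constant gene(s) cannot be standardized: %s", toString(head(const, 5L)))
  z <- scale(t(x), center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Gene-gene Pearson correlation matrix
#'
#' @param std samples-by-genes matrix (typically from [standardize_genes()]).
#' @return symmetric correlation matrix with unit diagonal, entries clipped
#'   to \[-1, 1\].
#' @export
correlation_matrix <- function(std) {
  if (!is.matrix(std) || !is.numeric(std))
    stopf("'std' must be a numeric samples-by-genes matrix")
  r <- cor(std)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Eigendecompose a correlation matrix
#'
#' Eigenvalues sorted descending; tiny negative eigenvalues (within -1e-10)
#' are floored at 0. Each eigenvector's sign is fixed so that its
#' largest-magnitude entry is nonnegative, making the decomposition
#' deterministic across linear-algebra backends.
#'
#' @param corr symmetric (correlation) matrix.
#' @return an `"eigen_system"`: list with `values` and the orthonormal
#'   `vectors` matrix (genes in rows, components PC1.. in columns).
#' @export
eigendecompose <- function(corr) {
  if (!is.matrix(corr) || !isSymmetric(unname(corr), tol = 1e-8))
    stopf("a symmetric (correlation) matrix is required")
  es <- eigen(corr, symmetric = TRUE)
  vals <- es$values
  vals[vals < 0 & vals >= -1e-10] <- 0
  vecs <- es$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(corr), paste0("PC", seq_len(ncol(vecs))))
  structure(list(values = vals, vectors = vecs), class = "eigen_system")
}

#' @export
print.eigen_system <- function(x, ...) {
  cat(sprintf("eigensystem of a %d x %d correlation matrix\n",
              nrow(x$vectors), nrow(x$vectors)))
  cat("  eigenvalues:", toString(signif(head(x$values, 8L), 4)),
      if (length(x$values) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Component contribution rates
#'
#' Each component's eigenvalue as a fraction of the eigenvalue total, plus
#' the running (cumulative) contribution.
#'
#' @param eig an `"eigen_system"`.
#' @return data frame with columns `component`, `eigenvalue`,
#'   `contribution`, `cumulative`; contributions sum to 1.
#' @export
contribution_rates <- function(eig) {
  lam <- eig$values / sum(eig$values)
  data.frame(component = paste0("PC", seq_along(lam)),
             eigenvalue = eig$values,
             contribution = lam,
             cumulative = cumsum(lam),
             stringsAsFactors = FALSE)
}

#' Number of principal components to retain
#'
#' `rule = "eigenvalue"` (default) keeps components whose eigenvalue exceeds
#' the threshold (default 2; the Kaiser rule corresponds to threshold 1);
#' `rule = "cumulative"` keeps the smallest t whose cumulative contribution
#' reaches the threshold (default 0.85). At least one component is always
#' retained.
#'
#' @param eig an `"eigen_system"`.
#' @param rule retention rule.
#' @param threshold rule threshold; default 2 (eigenvalue) or 0.85
#'   (cumulative).
#' @return integer t, the number of retained components (>= 1).
#' @export
retain_components <- function(eig, rule = c("eigenvalue", "cumulative"),
                              threshold = NULL) {
  rule <- match.arg(rule)
  if (is.null(threshold)) threshold <- if (rule == "eigenvalue") 2 else 0.85
  t <- if (rule == "eigenvalue") {
    sum(eig$values > threshold)
  } else {
    cum <- cumsum(eig$values / sum(eig$values))
    idx <- match(TRUE, cum >= threshold)
    if (is.na(idx)) length(cum) else idx
  }
  max(as.integer(t), 1L)
}

#' Gene contribution rates over the retained components
#'
#' Each gene's share of loading magnitude on the first t components:
#' with d_ij the magnitude of gene j's loading on component i (absolute
#' value by default, squared loading as a variant),
#' `g_j = sum_i d_ij / sum_i sum_k d_ik`, so the rates sum to exactly 1.
#'
#' @param eig an `"eigen_system"`.
#' @param t number of retained components, 1 <= t <= m.
#' @param weight `"abs"` (default) or `"squared"` loading magnitudes.
#' @return named numeric vector of per-gene contribution rates (sum 1), with
#'   `t` and `weight` attached as attributes.
#' @export
gene_contribution <- function(eig, t, weight = c("abs", "squared")) {
  weight <- match.arg(weight)
  m <- ncol(eig$vectors)
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t > m)
    stopf("'t' must be a single integer in [1, %d]", m)
  d <- eig$vectors[, seq_len(as.integer(t)), drop = FALSE]
  d <- if (weight == "abs") abs(d) else d^2
  g <- rowSums(d) / sum(d)
  names(g) <- rownames(eig$vectors)
  attr(g, "t") <- as.integer(t)
  attr(g, "weight") <- weight
  g
}

#' Pick the final feature genes by contribution rate
#'
#' @param g named gene-contribution vector from [gene_contribution()].
#' @param n_features how many genes to keep; must not exceed `length(g)`.
#' @return the selected genes' contribution rates, named, largest first
#'   (ties broken lexicographically by gene id).
#' @export
select_feature_genes <- function(g, n_features) {
  m <- length(g)
  if (!is.numeric(n_features) || length(n_features) != 1L ||
      n_features < 1 || n_features > m)
    stopf("'n_features' must be a single integer in [1, %d]", m)
  ord <- order(-g, names(g))
  out <- g[ord][seq_len(as.integer(n_features))]
  attributes(out) <- c(attributes(out)[c("names")],
                       attributes(g)[c("t", "weight")])
  out
}
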