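# Expression data model and tabular I/O.
#
# An expression matrix is a plain numeric matrix, genes in rows and samples
# in columns, with unique identifiers as dimnames -- the convention of the
# classic microarray toolkits. Class labels are a named factor with exactly
# two levels, ordered by first appearance (the first level is the
# "positive" class wherever a positive/negative convention is needed).

#' Validate a genes-by-samples expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix with unique gene rownames, unique sample colnames, at least two
#' of each, and no missing or non-finite entries.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
check_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("gene identifiers (rownames) and sample identifiers (colnames) are required")
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup))
    stopf("duplicated gene identifier(s): %s", toString(head(dup, 5L)))
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup))
    stopf("duplicated sample identifier(s): %s", toString(head(dup, 5L)))
  if (nrow(x) < 2L || ncol(x) < 2L)
    stopf("need at least 2 genes and 2 samples, got %d x %d", nrow(x), ncol(x))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stopf("non-finite value at gene '%s', sample '%s'",
          rownames(x)[bad[1L]], colnames(x)[bad[2L]])
  }
  invisible(x)
}

#' Read an expression matrix from a TSV/CSV file
#'
#' The on-disk layout is a header row of sample identifiers and a first
#' column of gene identifiers (or the transpose, see `orientation`); the
#' delimiter (tab or comma) is sniffed from the header line. The returned
#' matrix is always genes x samples.
#'
#' @param path path to the delimited file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`
#'   when the file stores samples as rows.
#' @return a validated numeric matrix, genes in rows.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("expression file not found: '%s'", path)
  sep <- sniff_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "\"", comment.char = "")
  if (ncol(df) < 2L)
    stopf("'%s': expected an identifier column plus at least one data column", path)
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  dup <- unique(row_ids[duplicated(row_ids)])
  if (length(dup))
    stopf("duplicated identifier(s) in '%s': %s", path, toString(head(dup, 5L)))
  body <- as.matrix(df[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stopf("non-numeric value '%s' at row '%s', column '%s' of '%s'",
          body[bad[1L], bad[2L]], row_ids[bad[1L]], col_ids[bad[2L]], path)
  }
  dimnames(values) <- list(row_ids, col_ids)
  if (orientation == "samples_in_rows") values <- t(values)
  check_expression(values)
  values
}

#' Write an expression matrix as TSV
#'
#' Values are serialized at 12 significant digits so that a write/read
#' round trip preserves them to at least that precision.
#'
#' @param x validated expression matrix (see [check_expression()]).
#' @param path output path.
#' @param sep field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, sep = "\t") {
  check_expression(x)
  fm <- matrix(sprintf("%.12g", x), nrow = nrow(x))
  lines <- c(paste(c("gene_id", colnames(x)), collapse = sep),
             paste(rownames(x), apply(fm, 1L, paste, collapse = sep), sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Construct two-class sample labels
#'
#' @param classes character vector of class tags, exactly two distinct
#'   values; level order follows first appearance, and the first level is
#'   treated as the positive class.
#' @param sample_ids unique sample identifiers, same length as `classes`.
#' @return a named factor with two levels.
#' @export
class_labels <- function(classes, sample_ids) {
  classes <- as.character(classes)
  sample_ids <- as.character(sample_ids)
  if (length(classes) != length(sample_ids))
    stopf("'classes' and 'sample_ids' differ in length (%d vs %d)",
          length(classes), length(sample_ids))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stopf("duplicated sample identifier(s): %s", toString(head(dup, 5L)))
  tags <- unique(classes)
  if (length(tags) != 2L)
    stopf("exactly two class tags are required, got %d (%s)",
          length(tags), toString(head(tags, 5L)))
  f <- factor(classes, levels = tags)
  names(f) <- sample_ids
  counts <- table(f)
  if (any(counts < 2L))
    stopf("class '%s' has %d sample(s); at least 2 per class are required",
          names(counts)[which.min(counts)], min(counts))
  f
}

check_labels <- function(labels) {
  if (!is.factor(labels) || is.null(names(labels)))
    stopf("labels must be a named factor (see class_labels())")
  class_labels(as.character(labels), names(labels))
}

# Pair labels with a matrix: every sample of the matrix must be labelled and
# every label must refer to a matrix sample; returns labels in column order.
match_labels <- function(x, labels) {
  check_expression(x)
  labels <- check_labels(labels)
  ids <- colnames(x)
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stopf("no class label for sample(s): %s", toString(head(missing, 5L)))
  extra <- setdiff(names(labels), ids)
  if (length(extra))
    stopf("label(s) for sample(s) absent from the matrix: %s",
          toString(head(extra, 5L)))
  labels[ids]
}

#' Read two-class sample labels from a two-column TSV/CSV
#'
#' Column 1 is the sample identifier, column 2 the class tag; a header line
#' `sample_id<sep>class` is tolerated and skipped.
#'
#' @param path path to the label file.
#' @return a named two-level factor; class counts via `table()`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("label file not found: '%s'", path)
  sep <- sniff_sep(path)
  df <- read.table(path, sep = sep, header = FALSE, colClasses = "character",
                   quote = "\"", comment.char = "")
  if (ncol(df) != 2L)
    stopf("'%s': expected exactly two columns (sample_id, class), got %d",
          path, ncol(df))
  if (df[1L, 1L] == "sample_id") df <- df[-1L, , drop = FALSE]
  class_labels(df[[2L]], df[[1L]])
}

#' Write two-class sample labels as a two-column TSV
#' @param labels named two-level factor.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  labels <- check_labels(labels)
  writeLines(paste(names(labels), as.character(labels), sep = "\t"), path)
  invisible(path)
}

#' Stratified train/test split
#'
#' Draws the requested number of training samples from each class (without
#' replacement, deterministically for a given seed); everything else is the
#' test set. Both sides must end up containing both classes.
#'
#' @param labels named two-level factor.
#' @param train_counts named integer vector, one entry per class tag, giving
#'   the training-set size for that class.
#' @param seed RNG seed; the split is bit-identical across runs for a fixed
#'   seed.
#' @return an object of class `"fgx_split"`: a list with `train_ids` and
#'   `test_ids`.
#' @examples
#' lab <- class_labels(rep(c("lesion", "normal"), c(28, 22)), sprintf("s%02d", 1:50))
#' sp <- split_train_test(lab, c(lesion = 20, normal = 10), seed = 1)
#' table(lab[sp$test_ids])  # 8 lesion, 12 normal
#' @export
split_train_test <- function(labels, train_counts, seed = 1L) {
  labels <- check_labels(labels)
  lev <- levels(labels)
  if (is.null(names(train_counts)) || !all(lev %in% names(train_counts)))
    stopf("'train_counts' must be named with both class tags: %s", toString(lev))
  train <- with_seed(seed, {
    unlist(lapply(lev, function(l) {
      ids <- names(labels)[labels == l]
      k <- as.integer(train_counts[[l]])
      if (k > length(ids))
        stopf("class '%s': requested %d training samples but only %d exist",
              l, k, length(ids))
      if (k < 1L || k > length(ids) - 1L)
        stopf("class '%s': training count %d leaves train or test without that class",
              l, k)
      sample(ids, k)
    }), use.names = FALSE)
  })
  test <- setdiff(names(labels), train)
  structure(list(train_ids = train, test_ids = test), class = "fgx_split")
}

#' @export
print.fgx_split <- function(x, ...) {
  cat(sprintf("train/test split: %d train, %d test samples\n",
              length(x$train_ids), length(x$test_ids)))
  invisible(x)
}
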