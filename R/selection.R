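# Ranking, top-k selection, and the common-gene intersection of two filters.

#' Rank genes by a score table
#'
#' Orders the non-degenerate genes from most to least informative according
#' to the table's criterion direction (applying `|score|` where the
#' criterion ranks by magnitude). Ties are broken lexicographically by gene
#' identifier, so the order is a deterministic function of the scores alone.
#'
#' @param scores a `"gene_scores"` table.
#' @return character vector of gene ids, most informative first, of class
#'   `"ranked_genes"` with the criterion attached as an attribute.
#' @export
rank_genes <- function(scores) {
  if (!inherits(scores, "gene_scores"))
    stopf("'scores' must be a gene_scores table")
  keep <- !scores$degenerate & is.finite(scores$score)
  if (!any(keep))
    stopf("no gene has a usable '%s' score: all are degenerate",
          attr(scores, "criterion"))
  s <- scores[keep, , drop = FALSE]
  val <- if (isTRUE(attr(scores, "use_abs"))) abs(s$score) else s$score
  if (attr(scores, "direction") == "higher_is_informative") val <- -val
  ord <- order(val, s$gene_id)
  structure(s$gene_id[ord],
            criterion = attr(scores, "criterion"), class = "ranked_genes")
}

#' @export
print.ranked_genes <- function(x, ...) {
  cat(sprintf("ranked genes ('%s', most informative first): %d genes\n",
              attr(x, "criterion"), length(x)))
  cat(" ", toString(head(unclass(x), 8L)), if (length(x) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Keep the k most informative genes of a ranking
#'
#' Returns the first `min(k, n)` genes and records how many were eliminated.
#' With `literal_bottom = TRUE` the k *least* informative genes are kept
#' instead -- a deliberately literal reading of "sort ascending and keep the
#' bottom of the list" that exists only to make that alternative
#' reproducible; the default keeps the informative end.
#'
#' @param ranked a `"ranked_genes"` vector from [rank_genes()].
#' @param k number of genes to keep (k = 0 eliminates everything; k > n
#'   keeps all with a warning).
#' @param literal_bottom keep the least informative k instead.
#' @return character vector of selected gene ids with attributes
#'   `eliminated` (count) and `criterion`.
#' @export
select_top_k <- function(ranked, k, literal_bottom = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stopf("'k' must be a single nonnegative integer")
  k <- as.integer(k)
  n <- length(ranked)
  if (k > n) warnf("k = %d exceeds the %d ranked genes; selecting all", k, n)
  kk <- min(k, n)
  sel <- if (literal_bottom) ranked[seq.int(n - kk + 1L, length.out = kk)]
         else ranked[seq_len(kk)]
  sel <- as.character(sel)
  attr(sel, "eliminated") <- n - kk
  attr(sel, "criterion") <- attr(ranked, "criterion")
  sel
}

#' Intersect two gene selections
#'
#' The common-gene set of a dual filter: genes kept by both criteria.
#' Returned sorted for determinism. An empty intersection is a warning, not
#' an error -- the caller decides whether downstream stages can proceed.
#'
#' @param a,b character vectors of gene ids.
#' @return sorted character vector of the common genes, with the parent set
#'   sizes as attributes `n_a` and `n_b`.
#' @export
intersect_selections <- function(a, b) {
  common <- sort(intersect(as.character(a), as.character(b)))
  if (!length(common))
    warnf("the two selections share no genes")
  attr(common, "n_a") <- length(a)
  attr(common, "n_b") <- length(b)
  common
}
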