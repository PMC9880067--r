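# small in-code fixtures shared across test files

# a deterministic 2-class toy matrix with named genes/samples
toy_matrix <- function(G = 6, n_pos = 4, n_neg = 4, seed = 42) {
  fgx:::with_seed(seed, {
    m <- matrix(rnorm(G * (n_pos + n_neg), 8, 1), G, n_pos + n_neg)
  })
  dimnames(m) <- list(sprintf("g%02d", seq_len(G)),
                      sprintf("s%02d", seq_len(n_pos + n_neg)))
  m
}

toy_labels <- function(n_pos = 4, n_neg = 4, tags = c("lesion", "normal")) {
  class_labels(rep(tags, c(n_pos, n_neg)),
               sprintf("s%02d", seq_len(n_pos + n_neg)))
}

# class_stats table built directly from given per-gene parameters
fake_stats <- function(mean_pos, mean_neg, sd_pos, sd_neg,
                       n_pos = 10L, n_neg = 10L) {
  out <- data.frame(gene_id = sprintf("g%02d", seq_along(mean_pos)),
                    mean_pos = mean_pos, mean_neg = mean_neg,
                    sd_pos = sd_pos, sd_neg = sd_neg,
                    var_pos = sd_pos^2, var_neg = sd_neg^2,
                    n_pos = n_pos, n_neg = n_neg,
                    stringsAsFactors = FALSE)
  class(out) <- c("class_stats", "data.frame")
  out
}

# gene_scores table built directly (bypasses scoring)
fake_scores <- function(ids, scores, direction = "higher_is_informative",
                        use_abs = FALSE) {
  fgx:::new_gene_scores(ids, scores, "test", direction, use_abs = use_abs,
                        degenerate = rep(FALSE, length(ids)))
}

# the benchmark design: 2000 genes, 28+22 samples, 30 planted informative
bench_config <- function(seed = 101L, n_informative = 30L) {
  synth_config(seed = seed, n_informative = n_informative)
}
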