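# filter criteria: hand-computed values, independent scalar oracles,
# degenerate handling, and invariance properties

# --- independent scalar oracles: literal transcriptions of each formula ---
oracle_bd <- function(m1, m2, s1, s2)
  (m1 - m2)^2 / (8 * (s1^2 + s2^2)) +
    0.5 * log((s1^2 + s2^2) / (2 * s1 * s2))
oracle_snr <- function(m1, m2, s1, s2, printed)
  (m1 - m2) / (if (printed) s1 - s2 else s1 + s2)
oracle_fisher <- function(m1, m2, s1, s2, printed)
  (m1 - m2)^2 / (if (printed) s1^2 - s2^2 else s1^2 + s2^2)
oracle_t <- function(m1, m2, v1, v2, n1, n2)
  (m1 - m2) / sqrt(v1 / n1 + v2 / n2)

test_that("class statistics use the n-1 convention and swap with the tags", {
  m <- rbind(g1 = c(0, 2, 1, 3), g2 = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  lab <- class_labels(c("A", "A", "B", "B"), paste0("s", 1:4))
  st <- class_stats(m, lab)
  expect_equal(st$mean_pos[1], 1)
  expect_equal(st$mean_neg[1], 2)
  expect_equal(st$sd_pos[1], sqrt(2))
  expect_equal(st$sd_neg[1], sqrt(2))
  expect_equal(st$mean_pos[2], 5)
  expect_equal(st$sd_pos[2], 0)
  expect_equal(st$var_pos, st$sd_pos^2)

  # same partition, but the other class is listed (hence positive) first
  lab2 <- class_labels(c("B", "B", "A", "A"), c("s3", "s4", "s1", "s2"))
  st2 <- class_stats(m, lab2)
  expect_equal(st2$mean_pos, st$mean_neg)
  expect_equal(st2$sd_neg, st$sd_pos)
})

test_that("Bhattacharyya score matches hand-derived values", {
  st <- fake_stats(mean_pos = c(1, 0, 2), mean_neg = c(1, 1, 2),
                   sd_pos = c(1, 1, 1), sd_neg = c(1, 1, 2))
  sc <- bhattacharyya_score(st)
  expect_equal(sc$score[1], 0)                       # identical distributions
  expect_equal(sc$score[2], 0.0625)                  # mean shift only
  expect_equal(sc$score[3], 0.5 * log(5 / 4))        # variance disparity only
  expect_identical(attr(sc, "direction"), "higher_is_informative")
})

test_that("zero-variance genes are flagged degenerate with a warning", {
  st <- fake_stats(mean_pos = c(0, 1), mean_neg = c(1, 0),
                   sd_pos = c(0, 1), sd_neg = c(1, 1))
  expect_warning(sc <- bhattacharyya_score(st), "degenerate")
  expect_true(sc$degenerate[1])
  expect_false(sc$degenerate[2])
  expect_true(is.na(sc$score[1]))
})

test_that("discretization maps the range onto levels 0..20 with half-up rounding", {
  expect_identical(discretize_gene(c(0, 5, 10)), c(0L, 10L, 20L))
  expect_error(discretize_gene(rep(3, 5)), "constant")

  for (seed in 1:10) {
    v <- fgx:::with_seed(seed, rnorm(25))
    lv <- discretize_gene(v)
    expect_true(all(lv >= 0L & lv <= 20L))
    expect_identical(lv[which.min(v)], 0L)
    expect_identical(lv[which.max(v)], 20L)
    # positive affine transforms are absorbed by the min-max scaling
    expect_identical(discretize_gene(2.5 * v + 7), lv)
  }
})

test_that("gini_level matches closed-form impurities and stays in range", {
  expect_equal(gini_level(c(0, 7, 0)), 0)                  # pure
  expect_equal(gini_level(c(3, 3)), 0.5)                   # two equal levels
  expect_equal(gini_level(rep(1, 21)), 20 / 21)            # uniform, 21 levels
  expect_error(gini_level(integer(0)), "empty class")
  for (seed in 1:20) {
    counts <- fgx:::with_seed(seed, rpois(21, 2))
    if (sum(counts) == 0) counts[1] <- 1
    g <- gini_level(counts)
    expect_gte(g, 0)
    expect_lte(g, 20 / 21)
  }
})

test_that("gene-level Gini is the class-size-weighted impurity", {
  # class A constant at the minimum (pure); class B split min/max (0.5)
  m <- rbind(g1 = c(0, 0, 0, 0, 0, 0, 10, 10),
             g2 = c(0, 0, 0, 0, 10, 10, 10, 10))
  colnames(m) <- paste0("s", 1:8)
  lab <- class_labels(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  sc <- gini_score(m, lab)
  expect_equal(sc$score[1], 0.5 * 0 + 0.5 * 0.5)   # weighted 0.25
  expect_equal(sc$score[2], 0)                     # class-pure levels
  expect_identical(attr(sc, "direction"), "lower_is_informative")

  # independent oracle on random genes: per-class gini_level of the levels
  d <- synth_data(synth_config(n_genes = 40, n_informative = 10, n_pos = 9,
                               n_neg = 7, seed = 12))
  sc <- gini_score(d$matrix, d$labels)
  n <- ncol(d$matrix)
  for (i in seq_len(nrow(d$matrix))) {
    lv <- discretize_gene(d$matrix[i, ])
    exp_g <- 0
    for (k in levels(d$labels)) {
      lk <- lv[d$labels == k]
      exp_g <- exp_g + length(lk) / n * gini_level(tabulate(lk + 1L, 21L))
    }
    expect_equal(sc$score[i], exp_g, tolerance = 1e-12)
  }
})

test_that("constant genes are excluded from the Gini ranking", {
  m <- toy_matrix(G = 5)
  m[3, ] <- 4
  lab <- toy_labels()
  expect_warning(sc <- gini_score(m, lab), "degenerate")
  expect_true(sc$degenerate[3])
  expect_false(any(sc$degenerate[-3]))
})

test_that("SNR and FSC give the documented values under both variants", {
  st <- fake_stats(mean_pos = c(1, 2, 3, 3), mean_neg = c(0, 0, 3, 1),
                   sd_pos = c(2, 3, 1, 1), sd_neg = c(1, 1, 2, 1))
  snr_p <- suppressWarnings(snr_score(st, "as_printed"))
  snr_s <- snr_score(st, "standard_sum")
  expect_equal(snr_p$score[1], 1.0)
  expect_equal(snr_s$score[1], 1 / 3)
  expect_equal(snr_s$score[3], 0)                 # no mean separation
  expect_true(snr_p$degenerate[4])                # equal sds: singular
  expect_false(snr_s$degenerate[4])

  fsc_p <- suppressWarnings(fsc_score(st, "as_printed"))
  fsc_s <- fsc_score(st, "standard_sum")
  expect_equal(fsc_p$score[2], 1.0)
  expect_equal(fsc_s$score[2], 0.5)
  expect_true(isTRUE(attr(fsc_s, "use_abs")))
})

test_that("Fisher ratio matches hand values; printed variant flags equal variances", {
  st <- fake_stats(mean_pos = c(1, 1, 2), mean_neg = c(0, 0, 2),
                   sd_pos = c(sqrt(2), 1, 1), sd_neg = c(1, 1, 3))
  f_p <- suppressWarnings(fisher_score(st, "as_printed"))
  f_s <- fisher_score(st, "standard_sum")
  expect_equal(f_p$score[1], 1.0)
  expect_equal(f_s$score[1], 1 / 3)
  expect_true(f_p$degenerate[2])
  expect_equal(f_s$score[3], 0)
})

test_that("t statistic has the Welch form and is antisymmetric in the classes", {
  m <- rbind(g1 = c(1.5, 0.5, 1.5, 0.5, 1, 0, -1, 0),
             g2 = c(1, 2, 3, 4, 1, 2, 3, 4))
  colnames(m) <- paste0("s", 1:8)
  lab <- class_labels(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  sc <- t_statistic_score(m, lab)
  st <- class_stats(m, lab)
  expect_equal(sc$score,
               oracle_t(st$mean_pos, st$mean_neg, st$var_pos, st$var_neg, 4, 4))
  expect_equal(sc$score[2], 0)  # identical class distributions

  # same partition with class B listed (hence positive) first
  lab2 <- class_labels(rep(c("B", "A"), each = 4), paste0("s", c(5:8, 1:4)))
  sc2 <- t_statistic_score(m, lab2)
  expect_equal(sc2$score, -sc$score)

  # x = 1 vs 0 with unit variances and n = 4 gives 1/sqrt(0.5)
  st2 <- fake_stats(1, 0, 1, 1, n_pos = 4L, n_neg = 4L)
  expect_equal(oracle_t(1, 0, 1, 1, 4, 4), sqrt(2))
})

test_that("vectorized scores equal the scalar oracles on 100 random tuples", {
  tup <- fgx:::with_seed(77, data.frame(m1 = rnorm(100), m2 = rnorm(100),
                                        s1 = runif(100, 0.2, 3),
                                        s2 = runif(100, 0.2, 3)))
  st <- fake_stats(tup$m1, tup$m2, tup$s1, tup$s2, n_pos = 12L, n_neg = 9L)
  bd <- bhattacharyya_score(st)$score
  snr_s <- snr_score(st, "standard_sum")$score
  snr_p <- snr_score(st, "as_printed")$score
  fsc_s <- fsc_score(st, "standard_sum")$score
  fis_s <- fisher_score(st, "standard_sum")$score
  fis_p <- fisher_score(st, "as_printed")$score
  for (i in seq_len(100)) {
    expect_equal(bd[i], oracle_bd(tup$m1[i], tup$m2[i], tup$s1[i], tup$s2[i]),
                 tolerance = 1e-12)
    expect_equal(snr_s[i],
                 oracle_snr(tup$m1[i], tup$m2[i], tup$s1[i], tup$s2[i], FALSE),
                 tolerance = 1e-12)
    expect_equal(snr_p[i],
                 oracle_snr(tup$m1[i], tup$m2[i], tup$s1[i], tup$s2[i], TRUE),
                 tolerance = 1e-12)
    expect_equal(fsc_s[i],
                 oracle_snr(tup$m1[i], tup$m2[i], tup$s1[i], tup$s2[i], FALSE),
                 tolerance = 1e-12)
    expect_equal(fis_s[i],
                 oracle_fisher(tup$m1[i], tup$m2[i], tup$s1[i], tup$s2[i], FALSE),
                 tolerance = 1e-12)
    expect_equal(fis_p[i],
                 oracle_fisher(tup$m1[i], tup$m2[i], tup$s1[i], tup$s2[i], TRUE),
                 tolerance = 1e-12)
  }
})

test_that("Bhattacharyya score is invariant under common affine transforms", {
  d <- synth_data(synth_config(n_genes = 20, n_informative = 8, n_pos = 10,
                               n_neg = 8, seed = 4))
  base <- bhattacharyya_score(class_stats(d$matrix, d$labels))$score
  for (ab in list(c(2, 0), c(0.5, 3), c(-1.5, 10))) {
    tr <- bhattacharyya_score(class_stats(ab[1] * d$matrix + ab[2],
                                          d$labels))$score
    expect_equal(tr, base, tolerance = 1e-10)
  }
})

test_that("planted genes outscore null genes in mean Bhattacharyya distance", {
  hits <- 0L
  for (seed in 1:10) {
    d <- synth_data(synth_config(n_genes = 300, n_informative = 30,
                                 n_pos = 14, n_neg = 11, mean_shift = 2,
                                 seed = seed))
    sc <- bhattacharyya_score(class_stats(d$matrix, d$labels))
    planted <- sc$score[sc$gene_id %in% d$truth]
    null <- sc$score[!sc$gene_id %in% d$truth]
    hits <- hits + (mean(planted) > mean(null))
  }
  expect_identical(hits, 10L)
})
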