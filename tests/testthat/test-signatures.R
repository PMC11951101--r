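make_expr <- function(n_cells = 400, n_genes = 100, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_cells * n_genes, 1, 0.5), n_cells, n_genes,
         dimnames = list(sprintf("cell%04d", seq_len(n_cells)),
                         sprintf("GENE%03d", seq_len(n_genes))))
}

test_that("signature scores centre on zero under label exchangeability", {
  expr <- make_expr(2000, 100)
  set.seed(2)
  gs <- sample(colnames(expr), 15)  # an arbitrary label assignment
  sc <- score_signature(expr, gs, n_bins = 10, n_ctrl_per_gene = 50,
                        seed = 11)
  expect_lt(abs(mean(sc$score)), 0.02)
})

test_that("a constructed expression shift is recovered in the shifted cells", {
  expr <- make_expr(600, 100)
  gs <- paste0("GENE", sprintf("%03d", 1:10))
  shifted <- 1:300
  expr[shifted, gs] <- expr[shifted, gs] + 1
  sc <- score_signature(expr, gs, n_bins = 10, n_ctrl_per_gene = 50,
                        seed = 3)
  expect_equal(mean(sc$score[shifted]), 1, tolerance = 0.15)
  expect_equal(mean(sc$score[-shifted]), 0, tolerance = 0.15)
})

test_that("signature scoring is seed-deterministic and gene-order invariant", {
  expr <- make_expr(100, 80)
  gs <- c("GENE010", "GENE020", "GENE030")
  a <- score_signature(expr, gs, seed = 7, n_bins = 8)
  b <- score_signature(expr, gs, seed = 7, n_bins = 8)
  expect_identical(a, b)
  perm <- expr[, sample(ncol(expr))]
  c <- score_signature(perm, rev(gs), seed = 7, n_bins = 8)
  expect_equal(a$score, c$score, tolerance = 1e-12)
  d <- score_signature(expr, gs, seed = 8, n_bins = 8)
  expect_false(identical(a$score, d$score))
})

test_that("signature scoring rejects absent gene sets and warns on poor overlap", {
  expr <- make_expr(50, 60)
  expect_error(score_signature(expr, c("NOPE1", "NOPE2"), name = "IFN_I"),
               "IFN_I")
  expect_warning(score_signature(expr, c("GENE001", "NOPE1", "NOPE2"),
                                 n_bins = 6), "only 1 of 3")
  expect_error(score_signature(expr[, 1:4], "GENE001", n_bins = 25),
               "at least")
})

test_that("subset proportions nest, partition and omit empty denominators", {
  cells <- data.frame(
    donor_id = rep("d1", 12),
    tissue = rep("TI", 12),
    cluster = rep(c("c1", "c2", "c3"), c(6, 3, 3)),
    cell_type = "MBC",
    stringsAsFactors = FALSE)
  den <- cells$cell_type == "MBC"
  p2 <- subset_proportions(cells, cells$cluster == "c2", den)
  expect_equal(p2$proportion, 0.25)
  sib <- vapply(c("c1", "c2", "c3"), function(cl) {
    subset_proportions(cells, cells$cluster == cl, den)$proportion
  }, numeric(1))
  expect_equal(sum(sib), 1)
  expect_error(subset_proportions(cells, rep(TRUE, 12), cells$cluster != "c1"),
               "nest")
})

test_that("disease-score association matches the closed-form Pearson formula", {
  expect_equal(correlate_with_disease(1:5, 2 * (1:5) + 3)$pearson_r, 1,
               tolerance = 1e-12)
  expect_error(correlate_with_disease(rep(0.3, 5), rnorm(5)), "zero variance")
  expect_error(correlate_with_disease(1:2, 1:2), "insufficient")

  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(9); y <- rnorm(9)
    res <- correlate_with_disease(x, y)
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$pearson_r, r_oracle, tolerance = 1e-12)
    t_stat <- r_oracle * sqrt(7 / (1 - r_oracle^2))
    expect_equal(res$p_value, 2 * pt(-abs(t_stat), 7), tolerance = 1e-9)
    expect_equal(res$slope,
                 sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2),
                 tolerance = 1e-12)
    expect_equal(res$intercept, mean(y) - res$slope * mean(x),
                 tolerance = 1e-12)
  }
})

test_that("p value decreases in |r| at fixed n", {
  x <- seq_len(8)
  p_of <- function(rho) {
    set.seed(1)
    y <- rho * scale(x)[, 1] + sqrt(1 - rho^2) * scale(rnorm(8))[, 1]
    correlate_with_disease(x, y)$p_value
  }
  expect_gt(p_of(0.3), p_of(0.9))
})

test_that("group comparisons cover t, paired t, Mann-Whitney and ANOVA/Tukey", {
  cmp <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  t_oracle <- (mean(1:3) - mean(4:6)) / sqrt(var(1:3) / 3 + var(4:6) / 3)
  expect_equal(cmp$statistic, t_oracle, tolerance = 1e-12)

  same <- compare_groups(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  flat <- compare_groups(rep(2, 9), rep(c("a", "b", "c"), each = 3),
                         test = "anova_tukey")
  expect_equal(flat$statistic, 0)

  expect_error(
    compare_groups(1:4, rep(c("a", "b"), 2), test = "paired_t",
                   pair_ids = c("d1", "d2", "d1", "d3")),
    "d2|d3")

  mw <- compare_groups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3),
                       test = "mann_whitney")
  expect_lt(mw$p_value, 0.1)
})

test_that("Tukey-adjusted p values are at least the unadjusted pairwise t p", {
  set.seed(3)
  vals <- c(rnorm(6, 0), rnorm(6, 1), rnorm(6, 2))
  grp <- rep(c("a", "b", "c"), each = 6)
  tk <- compare_groups(vals, grp, test = "anova_tukey")
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    raw <- t.test(vals[grp == pair[1]], vals[grp == pair[2]],
                  var.equal = TRUE)$p.value
    comp <- paste(pair[2], pair[1], sep = "-")
    expect_gte(tk$pairwise$p_adj[tk$pairwise$comparison == comp],
               raw - 1e-9)
  }
})

test_that("IFN-signature scores separate inflamed from non-inflamed cells", {
  coh <- simulate_cohort(small_scenario(seed = 23))
  sc <- score_signature(coh$expression, coh$gene_sets$IFN_I, name = "IFN_I",
                        n_bins = 10, n_ctrl_per_gene = 30, seed = 5)
  meta <- coh$metadata[match(sc$cell_id, coh$metadata$cell_id), ]
  hot <- meta$inflammation == "inflamed"
  expect_gt(mean(sc$score[hot]) - mean(sc$score[!hot]), 0.5)
})

test_that("compartment-wise correlations support a Benjamini-Hochberg switch", {
  set.seed(6)
  donors <- sprintf("d%d", 1:9)
  props <- rbind(
    data.frame(compartment = "PC_blood", donor_id = donors,
               proportion = seq(0.1, 0.5, length.out = 9)),
    data.frame(compartment = "MBC_TI", donor_id = donors,
               proportion = rnorm(9, 0.3, 0.05)),
    data.frame(compartment = "flat", donor_id = donors,
               proportion = rep(0.2, 9)))
  scores <- data.frame(donor_id = donors,
                       disease_score = seq(2, 18, length.out = 9) +
                         rnorm(9, 0, 0.5))
  res <- correlate_compartments(props, scores, adjust = "bh")
  pcb <- res[res$compartment == "PC_blood", ]
  expect_gt(pcb$pearson_r, 0.9)
  expect_true(is.na(res$pearson_r[res$compartment == "flat"]))
  expect_match(res$reason[res$compartment == "flat"], "zero variance")
  ok <- !is.na(res$p_value)
  expect_true(all(res$p_adjusted[ok] >= res$p_value[ok] - 1e-12))
})
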