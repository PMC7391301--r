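test_that("normalisation scales columns to the target and preserves proportions", {
  cm <- make_screen_fixture(
    cbind(c(1, 2, 7), c(2, 4, 14), c(10, 20, 70), c(5, 5, 90), c(3, 3, 94)),
    rep("g1", 3)
  )
  norm <- normalize_counts(cm, target_total = 100)
  expect_equal(unname(colSums(norm$counts)), rep(100, 5))
  # 3-shRNA toy column (1, 2, 7) with target 100 -> (10, 20, 70)
  expect_equal(unname(norm$counts[, 1]), c(10, 20, 70))
  # sample 2 is sample 1 with every raw count doubled -> identical column
  expect_equal(unname(norm$counts[, 2]), c(10, 20, 70))
  # already at the target -> unchanged
  again <- normalize_counts(norm, target_total = 100)
  expect_equal(again$counts, norm$counts)
  # rank order preserved in every column
  for (j in 1:5) {
    expect_identical(order(norm$counts[, j]), order(cm$counts[, j]))
  }
  zero <- make_screen_fixture(
    cbind(c(0, 0), c(1, 1), c(1, 1), c(1, 1), c(1, 1)), rep("g1", 2)
  )
  expect_error(normalize_counts(zero), "zero total.*L_T0")
})

test_that("log transform applies log10(x + pseudocount)", {
  cm <- make_screen_fixture(
    cbind(c(0, 9.9, 99.9), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)),
    rep("g1", 3)
  )
  lg <- log_transform(cm, pseudocount = 0.1)
  expect_equal(unname(lg$counts[, 1]), c(-1, 1, 2))
  # monotonicity preserved
  expect_identical(order(lg$counts[, 2]), order(cm$counts[, 2]))
})

test_that("robust-Z exclusion follows the median/MAD rule with a hard cap", {
  # six identical replicate values: MAD = 0, all equal -> no exclusions
  cm <- make_screen_fixture(cbind(5, 5, 5, 5, 5, 5, 5), "g1")
  ex <- robust_z_exclude(cm)
  expect_false(any(ex$L$excluded))
  expect_equal(unname(ex$L$robust_z[1, ]), rep(0, 6))

  # hand oracle: replicates (4,5,5,5,6,50), median 5, MAD 0.5
  cm2 <- make_screen_fixture(matrix(c(1, 4, 5, 5, 5, 6, 50), 1), "g1")
  ex2 <- robust_z_exclude(cm2)
  expect_equal(unname(ex2$L$robust_z[1, 6]), 45 / (1.4826 * 0.5),
               tolerance = 1e-12)
  expect_equal(unname(ex2$L$robust_z[1, 6]), 60.7, tolerance = 1e-3)
  expect_identical(unname(ex2$L$excluded[1, ]),
                   c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))

  # more candidates than the cap: only the two largest |Z| are excluded
  # (the MAD's 50% breakdown keeps a third value below |Z| = 5 at n = 6,
  # so the cap is exercised at a lower threshold)
  cm3 <- make_screen_fixture(matrix(c(1, 5, 5, 5, 40, 60, 80), 1), "g1")
  ex3 <- robust_z_exclude(cm3, threshold = 0.6)
  expect_identical(sum(ex3$L$excluded), 2L)
  expect_identical(unname(ex3$L$excluded[1, ]),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))

  # fewer than 4 tumour replicates is an error
  cm4 <- make_screen_fixture(cbind(1, 1, 1, 1), "g1")
  expect_error(robust_z_exclude(cm4), "at least 4")
})

test_that("robust-Z exclusion never removes more than 2 of 6 replicates", {
  for (s in 1:5) {
    sim <- sim_screen(n_genes = 40, shrnas_per_gene = 3, outlier_rate = 0.1,
                      outlier_factor = 100, seed = 300 + s)
    ex <- robust_z_exclude(log_transform(normalize_counts(sim$counts)))
    n_excl <- rowSums(ex$line1$excluded)
    expect_true(all(n_excl <= 2))
    expect_true(all(6 - n_excl >= 4))
  }
})

test_that("the omnibus skewness-kurtosis check matches its reference values", {
  # frozen cross-check computed with an independent implementation of the
  # D'Agostino-Pearson K2 test on this exact vector
  x <- c(0.1, 1.2, -0.5, 2.3, 0.7, -1.1, 0.4, 1.9, -0.2, 0.8,
         1.5, -0.9, 0.3, 2.1, -0.4, 0.6, 1.1, -1.3, 0.9, 0.2,
         3.5, 0.05, -2.2, 1.4, 0.75)
  r <- check_gaussian(x)
  expect_equal(r$statistic, 0.6262892367, tolerance = 1e-9)
  expect_equal(r$p, 0.7311441681, tolerance = 1e-9)
  expect_true(r$pass)

  set.seed(5)
  expect_true(check_gaussian(rnorm(1000))$pass)
  set.seed(5)
  expect_warning(bad <- check_gaussian(rexp(1000)), "Gaussian")
  expect_false(bad$pass)

  expect_error(check_gaussian(rep(1, 30)), "variance")
  expect_error(check_gaussian(rnorm(10)), "at least 20")
})

test_that("dropout Z-scores standardise log ratios within a cell line", {
  # 10 shRNAs, one 100-fold depleted; large counts so the pseudocount is
  # negligible
  t0 <- rep(1e4, 10)
  tum <- matrix(rep(c(rep(1e4, 9), 1e2), 6), 10, 6)
  cm <- make_screen_fixture(cbind(t0, tum), rep(paste0("g", 1:5), each = 2))
  sc <- dropout_z(cm)
  tab <- sc$table
  # hand-standardisation oracle
  lr <- log10((rowMeans(tum) + 0.1) / (t0 + 0.1))
  z_oracle <- (lr - mean(lr)) / sd(lr)
  expect_equal(tab$z, unname(z_oracle), tolerance = 1e-12)
  expect_identical(which(tab$dropout), 10L)
  # standardisation identities
  expect_equal(mean(tab$z), 0, tolerance = 1e-12)
  expect_equal(sd(tab$z), 1, tolerance = 1e-12)
  # the threshold is strict: dropout iff z < -1.96
  expect_identical(tab$dropout, tab$z < -1.96)

  flat <- make_screen_fixture(cbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1),
                                    c(1, 1), c(1, 1), c(1, 1)),
                              c("g1", "g2"))
  expect_error(dropout_z(flat), "zero variance")
})

test_that("null screen calibration: ~5% of shRNAs beyond |Z| = 1.96", {
  sim <- sim_screen(n_genes = 500, shrnas_per_gene = 4, seed = 77)
  norm <- normalize_counts(sim$counts)
  sc <- dropout_z(norm, robust_z_exclude(log_transform(norm)))
  frac <- mean(abs(sc$table$z) > 1.96)
  band <- 2.5758 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), band)
})

test_that("gene hits from Z calls require two scoring shRNAs per line", {
  tab <- data.frame(
    shrna = sprintf("sh%d", 1:6),
    gene = c("gA", "gA", "gB", "gB", "gC", "gC"),
    cell_line = "Y79", n_used = 6, log_ratio = 0,
    z = c(-2.5, -2.1, -2.3, -0.5, -1.0, 0.4),
    dropout = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  scores <- structure(list(table = tab, gene_of = NULL,
                           params = list(z_cut = -1.96)),
                      class = "screen_scores")
  hits <- gene_hits_screen1(scores)
  expect_true(hits$hit_Y79[hits$gene == "gA"])
  expect_false(hits$hit_Y79[hits$gene == "gB"])  # only 1 dropout shRNA
  expect_false(hits$hit_Y79[hits$gene == "gC"])

  # simulated truth recovery, including line-specific reporting
  sim <- sim_screen(n_genes = 80, shrnas_per_gene = 4, depleted_genes = 5,
                    depletion_factor = 0.1, seed = 19)
  norm <- normalize_counts(sim$counts)
  sc <- dropout_z(norm, robust_z_exclude(log_transform(norm)))
  hits2 <- gene_hits_screen1(sc)
  expect_setequal(hits2$gene[hits2$n_lines_hit > 0], sim$truth)
})

test_that("log-ratio gene hits use the fivefold cutoff and line tiers", {
  lr <- rbind(
    gA_sh1 = c(-0.70, -0.80, -0.75, -0.10),
    gA_sh2 = c(-0.70, -0.90, -0.69, -0.20),
    gB_sh1 = c(-0.68, -0.70, -0.10, 0.00),   # -0.68 does not score
    gB_sh2 = c(-0.60, -0.75, -0.20, 0.10),
    gC_sh1 = c(-0.80, -0.85, -0.90, -0.95),
    gC_sh2 = c(-0.10, -0.10, -0.10, -0.10)   # gene C: only 1 shRNA scores
  )
  colnames(lr) <- c("W", "Y", "R1", "R2")
  gene_of <- setNames(c("gA", "gA", "gB", "gB", "gC", "gC"), rownames(lr))
  hits <- gene_hits_screen2(lr, gene_of)
  get <- function(g, col) hits[hits$gene == g, col]
  # gA scores with 2 shRNAs in W and Y (the -0.69 boundary itself scores)
  expect_equal(get("gA", "n_lines_hit"), 3)
  expect_identical(get("gA", "tier"), "high")
  expect_equal(get("gB", "n_lines_hit"), 1)
  expect_identical(get("gB", "tier"), "low")
  expect_equal(get("gC", "n_lines_hit"), 0)
  expect_identical(get("gC", "tier"), "none")

  two <- lr
  two["gB_sh1", "W"] <- -0.69
  two["gB_sh2", "W"] <- -0.69
  hits2 <- gene_hits_screen2(two, gene_of)
  expect_equal(hits2[hits2$gene == "gB", "n_lines_hit"], 2)
  expect_identical(hits2[hits2$gene == "gB", "tier"], "medium")
})

test_that("Fisher exact p matches full hypergeometric enumeration", {
  # printed validation table: 15/18 hits validated vs 3/18 non-hits scoring
  p <- fisher_exact_2x2(15, 3, 3, 15)
  expect_equal(round(p, 4), 2e-04)
  expect_equal(p, oracle_fisher_p(15, 3, 3, 15), tolerance = 1e-7)

  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), oracle_fisher_p(3, 0, 0, 3),
               tolerance = 1e-12)

  # property: agreement with the enumeration oracle on random tables N <= 40
  set.seed(123)
  for (i in 1:25) {
    cells <- as.vector(stats::rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    if (any(rowSums(matrix(cells, 2)) == 0) ||
        any(colSums(matrix(cells, 2)) == 0)) next
    expect_equal(fisher_exact_2x2(cells[1], cells[3], cells[2], cells[4]),
                 oracle_fisher_p(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-7)
  }

  expect_warning(p0 <- fisher_exact_2x2(0, 0, 3, 5), "margin")
  expect_identical(p0, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})
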