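# Permutation test, logistic risk + AUC, panel selection, correlation.

test_that("permutation test: exact enumeration on the 2-vs-2 toy", {
  m <- matrix(c(1, 2, 5, 6), 1, 4,
              dimnames = list("g1", c("a1", "a2", "b1", "b2")))
  out <- permutation_test(m, c("a1", "a2"), c("b1", "b2"), n_perm = 100)
  expect_true(out$exact)
  expect_equal(out$obs_diff, -4)
  expect_identical(out$n_null, 6L)
  # observed regrouping is its own tie: (1 + 1) / (6 + 1)
  expect_equal(out$p, 2 / 7)
  expect_equal(out$p, oracle_perm_p(c(1, 2, 5, 6), 2))
  expect_equal(out$p_raw, 0)
})

test_that("permutation p equals full enumeration on random <=10-drug cases", {
  set.seed(17)
  for (i in 1:10) {
    na <- sample(2:4, 1); nb <- sample(2:6, 1)
    vals <- rnorm(na + nb)
    m <- matrix(vals, 1, na + nb,
                dimnames = list("g", paste0("d", seq_len(na + nb))))
    out <- permutation_test(m, paste0("d", 1:na),
                            paste0("d", na + 1:nb), n_perm = 1e4)
    expect_true(out$exact)
    expect_equal(out$p, oracle_perm_p(vals, na), tolerance = 1e-12)
  }
})

test_that("degenerate duplicated columns give p = 1 under tie counting", {
  m <- matrix(5, 1, 4, dimnames = list("g", c("a1", "a2", "b1", "b2")))
  # every regrouping reproduces the observed difference (all ties)
  out <- permutation_test(m, c("a1", "a2"), c("b1", "b2"), n_perm = 50)
  expect_equal(out$p, 1)
})

test_that("sampled and exact permutation p agree within Monte-Carlo error", {
  set.seed(18)
  vals <- rnorm(16)
  vals[1:8] <- vals[1:8] - 0.8
  m <- matrix(vals, 1, 16, dimnames = list("g", paste0("d", 1:16)))
  a <- paste0("d", 1:8); b <- paste0("d", 9:16)
  ex <- permutation_test(m, a, b, n_perm = 13000)      # C(16,8) = 12870
  expect_true(ex$exact)
  sa <- permutation_test(m, a, b, n_perm = 5000, seed = 5)
  expect_false(sa$exact)
  se <- sqrt(ex$p * (1 - ex$p) / 5000)
  expect_lt(abs(sa$p - ex$p), 3 * se + 1e-3)
})

test_that("permutation p is valid: P(p <= alpha) <= alpha under the null", {
  set.seed(19)
  m <- matrix(rnorm(500 * 12), 500, 12,
              dimnames = list(paste0("g", 1:500), paste0("d", 1:12)))
  out <- permutation_test(m, paste0("d", 1:5), paste0("d", 6:12),
                          n_perm = 400, seed = 7)
  for (alpha in c(0.05, 0.2)) {
    frac <- mean(out$p <= alpha)
    # binomial 99.9% upper bound around alpha (genes correlated only
    # through shared relabelings; bound padded accordingly)
    expect_lt(frac, alpha + 4 * sqrt(alpha * (1 - alpha) / 500) + 0.02)
  }
  expect_true(all(out$p > 0 & out$p <= 1))
})

test_that("group handling errors", {
  m <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), paste0("d", 1:4)))
  expect_error(permutation_test(m, c("d1", "d2"), c("d2", "d3")),
               class = "dignet_grouping_error")
  expect_error(permutation_test(m, "d1", c("d2", "d3")),
               class = "dignet_grouping_error")
  expect_error(permutation_test(m, c("d1", "d9"), c("d2", "d3")),
               class = "dignet_grouping_error")
})

test_that("AUC: hand-computed midrank cases and invariances", {
  expect_equal(auc_midrank(c(1, 1, 2, 2), c(0, 1, 0, 1)), 0.5)
  expect_equal(auc_midrank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc_midrank(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0.0)
  set.seed(20)
  x <- rnorm(30); y <- rbinom(30, 1, 0.4)
  expect_equal(auc_midrank(x, y) + auc_midrank(-x, y), 1)
  expect_equal(auc_midrank(exp(2 * x), y), auc_midrank(x, y))  # monotone map
  expect_error(auc_midrank(x, rep(1, 30)), class = "dignet_degenerate_error")
})

test_that("gene_risk: separation flag, folded statistics, degenerate labels", {
  m <- rbind(sep = c(1, 2, 3, 10, 11, 12),
             down = c(10, 11, 12, 1, 2, 3.5),
             flat = c(5, 5.1, 4.9, 5, 5.05, 4.95))
  colnames(m) <- paste0("p", 1:6)
  y <- c(0, 0, 0, 1, 1, 1)
  out <- gene_risk(m, y)
  expect_true(out$flagged[out$gene == "sep"])
  expect_equal(out$auc[out$gene == "sep"], 1.0)
  expect_identical(out$or[out$gene == "sep"], Inf)
  # down-regulated marker: folded AUC/or with negative direction
  expect_gt(out$auc[out$gene == "down"], 0.9)
  expect_identical(out$direction[out$gene == "down"], -1)
  expect_error(gene_risk(m, c(0, 0, 0, 0, 0, 0)),
               class = "dignet_degenerate_error")
})

test_that("logistic slope is recovered at n = 5000", {
  set.seed(22)
  x <- rnorm(5000)
  p <- 1 / (1 + exp(-(0 + 1 * x)))
  y <- rbinom(5000, 1, p)
  out <- gene_risk(matrix(x, 1, dimnames = list("g1", NULL)), y)
  expect_false(out$flagged)
  expect_gt(out$or, 2.45); expect_lt(out$or, 3.0)
})

test_that("logistic recovery across beta in {0, 0.5, 1} within 3 SE", {
  set.seed(23)
  for (b in c(0, 0.5, 1)) {
    x <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(b * x))
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    se <- summary(fit)$coefficients["x", "Std. Error"]
    out <- gene_risk(matrix(x, 1, dimnames = list("g", NULL)), y)
    expect_lt(abs(out$beta - b), 3 * se)
  }
})

test_that("select_panel: strict AND, ordering, planted recovery", {
  rec <- data.frame(gene = c("keep", "lowauc", "lowor", "inf"),
                    beta = c(2.27, 2.27, 1, 40),
                    or = c(9.7, 9.7, exp(1), Inf),
                    auc = c(0.75, 0.69, 0.8, 0.9),
                    direction = 1, flagged = c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(select_panel(rec), c("inf", "keep"))
  expect_identical(select_panel(rec, or_min = Inf), character(0))
  # planted recovery: 3 risk genes among 20 null genes
  set.seed(24)
  n <- 80
  y <- rep(c(1, 0), c(16, 64))
  m <- matrix(rnorm(23 * n), 23, n,
              dimnames = list(c(paste0("risk", 1:3), paste0("null", 1:20)),
                              NULL))
  m[1:3, y == 1] <- m[1:3, y == 1] - 2.5
  out <- gene_risk(m, y)
  expect_setequal(select_panel(out), paste0("risk", 1:3))
})

test_that("significance-strength correlation matches the covariance oracle", {
  set.seed(25)
  perm <- data.frame(gene = paste0("g", 1:50),
                     p = runif(50, 1e-6, 0.5))
  risk <- data.frame(gene = paste0("g", 1:50),
                     or = runif(50, 1, 12))
  out <- significance_strength_correlation(perm, risk)
  expect_lt(abs(out$r - oracle_cor(-log10(perm$p), risk$or)), 1e-10)
  expect_identical(out$n, 50L)
  # exact linear relation gives r = 1
  risk2 <- data.frame(gene = perm$gene, or = 3 - 2 * log10(perm$p))
  expect_equal(significance_strength_correlation(perm, risk2)$r, 1)
  # constant vector raises
  risk3 <- data.frame(gene = perm$gene, or = rep(2, 50))
  expect_error(significance_strength_correlation(perm, risk3),
               class = "dignet_degenerate_error")
  expect_error(significance_strength_correlation(perm[1:2, ], risk[1:2, ]),
               class = "dignet_insufficient_data")
})
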