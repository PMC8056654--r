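# The weighted co-expression core: adjacency, scale-free fit, TOM,
# clustering, eigengenes, merging, membership.

test_that("soft adjacency powers |correlation| and zeroes the diagonal", {
  set.seed(1)
  g1 <- rnorm(10)
  m <- rbind(g1 = g1, g2 = 2 * g1 + 1, g3 = rnorm(10))
  a <- soft_adjacency(m, beta = 5)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(diag(a), c(g1 = 0, g2 = 0, g3 = 0))
  expect_equal(a["g1", "g3"], abs(cor(g1, m["g3", ]))^5, tolerance = 1e-12)
  # beta = 5 on r = 0.5 gives 0.03125 (synthetic two-gene check)
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(1, 3, 2, 5, 4, 7, 6, 8)
  r <- cor(x, y)
  a2 <- soft_adjacency(rbind(gx = x, gy = y), beta = 5)
  expect_equal(a2["gx", "gy"], abs(r)^5, tolerance = 1e-12)
  expect_equal(0.5^5, 0.03125)
  expect_error(soft_adjacency(m[, 1:2], 5), class = "dignet_insufficient_data")
  expect_warning(soft_adjacency(rbind(m, g4 = rep(1, 10)), 5), "constant")
})

test_that("adjacency matches a brute-force correlation oracle", {
  set.seed(7)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  a <- soft_adjacency(m, beta = 3)
  for (i in c(1, 5, 19)) for (j in c(2, 11, 20)) {
    expect_lt(abs(a[i, j] - abs(oracle_cor(m[i, ], m[j, ]))^3), 1e-10)
  }
})

test_that("scale-free fit: two occupied bins give R2 = 1; oracle agreement", {
  set.seed(12)
  m <- matrix(rnorm(100), 10, 10)
  rownames(m) <- sprintf("g%02d", 1:10)
  a <- soft_adjacency(m, 2)
  expect_equal(scale_free_fit(a, n_bins = 2L), 1.0)
  # brute-force regression oracle on 100 genes
  m2 <- matrix(rnorm(100 * 12), 100, 12,
               dimnames = list(sprintf("g%03d", 1:100), NULL))
  a2 <- soft_adjacency(m2, 5)
  k <- rowSums(a2)
  bin <- cut(k, 10, include.lowest = TRUE)
  x <- log10(tapply(k, bin, mean)); y <- log10(tapply(k, bin, length) / 100)
  ok <- is.finite(x) & is.finite(y)
  r2 <- oracle_cor(x[ok], y[ok])^2
  expect_lt(abs(scale_free_fit(a2, 10) - r2), 1e-8)
  # degenerate: identical connectivities
  ident <- structure(matrix(0.5, 4, 4) - diag(0.5, 4), class = "matrix")
  expect_error(scale_free_fit(ident), class = "dignet_degenerate_error")
})

test_that("TOM formula on closed-form and random cases", {
  a1 <- matrix(1, 3, 3) - diag(3)
  t1 <- topological_overlap(a1)
  expect_equal(t1[upper.tri(t1)], rep(1, 3))    # (1+1)/(2+1-1)
  a0 <- matrix(0, 4, 4)
  expect_equal(topological_overlap(a0), diag(4))
  set.seed(3)
  m <- matrix(rnorm(15 * 8), 15, 8, dimnames = list(paste0("g", 1:15), NULL))
  a <- soft_adjacency(m, 4)
  expect_lt(max(abs(topological_overlap(a) - oracle_tom(unclass(a)))), 1e-10)
})

test_that("TOM is bounded in [0,1] with symmetric zero-diagonal dissimilarity", {
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(rnorm(12 * 10), 12, 10)
    rownames(m) <- paste0("g", 1:12)
    tom <- topological_overlap(soft_adjacency(m, sample(2:6, 1)))
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    d <- 1 - tom
    expect_equal(d, t(d))
    expect_equal(diag(d), rep(0, 12), ignore_attr = TRUE)
  }
})

test_that("detect_modules separates perfect blocks and handles ties", {
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0
  rownames(d) <- colnames(d) <- paste0("g", 1:6)
  ms <- detect_modules(d, min_module_size = 2)
  expect_identical(length(unique(ms$labels)), 2L)
  expect_identical(length(unique(ms$labels[1:3])), 1L)
  expect_identical(length(unique(ms$labels[4:6])), 1L)
  # all-equal dissimilarity: one module, deterministic
  de <- matrix(0.7, 6, 6) - diag(0.7, 6)
  rownames(de) <- colnames(de) <- paste0("g", 1:6)
  ms1 <- detect_modules(de, min_module_size = 2)
  ms2 <- detect_modules(de, min_module_size = 2)
  expect_identical(ms1$labels, ms2$labels)
  expect_identical(length(unique(ms1$labels)), 1L)
  # fewer genes than min size: all unassigned with warning
  expect_warning(ms0 <- detect_modules(de, min_module_size = 10),
                 "unassigned")
  expect_true(all(ms0$labels == 0L))
})

test_that("planted 4-module structure is recovered at ARI >= 0.9", {
  genes <- sprintf("M%dG%02d", rep(1:4, each = 50), rep(1:50, 4))
  truth <- expression_truth(
    module_assignment = stats::setNames(rep(1:4, each = 50), genes),
    group_A_drugs = paste0("a", 1:2), group_B_drugs = paste0("b", 1:2),
    noise_sd = 0.3, loading_range = c(0.7, 1))
  ps <- simulate_expression_profiles(truth, 200, n_profiles_per_drug = 15,
                                     seed = 7)
  tom <- topological_overlap(soft_adjacency(ps$matrix, 5))
  ms <- merge_modules(detect_modules(1 - tom, min_module_size = 30,
                                     cut_height_quantile = 0.95),
                      ps$matrix, 0.3)
  ari <- oracle_ari(ms$labels[genes], truth$module_assignment[genes])
  expect_gte(ari, 0.9)
  # factor-eigengene correlation^2 >= 0.9 for each planted factor
  fac <- attr(ps, "latent_factors")
  for (mod in 1:4) {
    planted <- names(which(truth$module_assignment == mod))
    lab <- as.integer(names(which.max(table(ms$labels[planted]))))
    r2 <- cor(ms$eigengenes[, paste0("ME", lab)], fac[mod, ])^2
    expect_gte(r2, 0.9)
  }
})

test_that("eigengenes: unit norm, orientation, degenerate modules", {
  set.seed(9)
  g <- rnorm(12)
  m <- rbind(g1 = g, g2 = g, g3 = rnorm(12), g4 = rnorm(12))
  labels <- c(g1 = 1L, g2 = 1L, g3 = 2L, g4 = 2L)
  me <- module_eigengenes(m, labels)
  expect_equal(sqrt(sum(me[, "ME1"]^2)), 1, tolerance = 1e-12)
  expect_equal(abs(cor(me[, "ME1"], g)), 1, tolerance = 1e-12)
  # global sign flip: orientation rule restores cor(ME, mean profile) >= 0
  me_flip <- module_eigengenes(-m, labels)
  z <- scale(t(-m[c("g1", "g2"), ]))
  expect_gte(cor(me_flip[, "ME1"], rowMeans(z)), 0)
  # zero-variance gene dropped with warning
  expect_warning(module_eigengenes(rbind(m, g5 = rep(2, 12)),
                                   c(labels, g5 = 1L)), "zero-variance")
})

test_that("planted factor is recovered by the module eigengene", {
  set.seed(10)
  fac <- rnorm(20)
  load <- runif(10, 0.7, 1)
  m <- outer(load, fac) + matrix(rnorm(200, 0, 0.3), 10, 20)
  rownames(m) <- paste0("g", 1:10)
  me <- module_eigengenes(m, stats::setNames(rep(1L, 10), rownames(m)))
  expect_gte(cor(me[, 1], fac)^2, 0.9)
})

test_that("merge_modules merges duplicates and respects the threshold", {
  set.seed(11)
  f1 <- rnorm(16); f2 <- rnorm(16); f3 <- rnorm(16)
  mk <- function(f, n, nm) {
    out <- outer(runif(n, 0.8, 1), f) + matrix(rnorm(n * 16, 0, 0.1), n, 16)
    rownames(out) <- nm
    out
  }
  # 6 modules from 3 duplicated factors
  m <- rbind(mk(f1, 6, paste0("a", 1:6)), mk(f1, 6, paste0("b", 1:6)),
             mk(f2, 6, paste0("c", 1:6)), mk(f2, 6, paste0("d", 1:6)),
             mk(f3, 6, paste0("e", 1:6)), mk(f3, 6, paste0("f", 1:6)))
  labels <- stats::setNames(rep(1:6, each = 6), rownames(m))
  ms <- merge_modules(module_set(labels), m, 0.3)
  expect_identical(length(setdiff(unique(ms$labels), 0L)), 3L)
  # threshold 0 is the identity on labels (up to renumbering by size)
  ms0 <- merge_modules(module_set(labels), m, 0)
  expect_identical(length(setdiff(unique(ms0$labels), 0L)), 6L)
  # two modules with identical eigengenes always merge
  m2 <- rbind(mk(f1, 4, paste0("x", 1:4)), mk(f1, 4, paste0("y", 1:4)))
  ms2 <- merge_modules(
    module_set(stats::setNames(rep(1:2, each = 4), rownames(m2))), m2, 0.3)
  expect_identical(length(setdiff(unique(ms2$labels), 0L)), 1L)
})

test_that("module count is non-increasing in the merge threshold", {
  set.seed(13)
  m <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(paste0("g", 1:40), NULL))
  labels <- stats::setNames(rep(1:8, each = 5), rownames(m))
  counts <- vapply(c(0, 0.2, 0.5, 0.9, 1.5), function(th) {
    ms <- merge_modules(module_set(labels), m, th)
    length(setdiff(unique(ms$labels), 0L))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("module membership and core-gene selection", {
  set.seed(14)
  fac <- rnorm(15)
  m <- rbind(hi = fac * 0.99 + rnorm(15, 0, 0.05),
             lo = fac * 0.5 + rnorm(15, 0, 1),
             me_like = fac)
  labels <- c(hi = 1L, lo = 1L, me_like = 1L)
  ms <- merge_modules(module_set(labels), m, 0)
  mm <- module_membership(m, ms)
  # brute-force correlation oracle
  for (g in rownames(m))
    expect_lt(abs(mm[g, "ME1"] - oracle_cor(m[g, ], ms$eigengenes[, 1])),
              1e-10)
  core <- select_core_genes(mm, 1, mm_min = 0.9)
  expect_true("hi" %in% core)
  expect_false("lo" %in% core)
  # strict threshold boundary: mm_min = 1 selects nothing
  expect_identical(select_core_genes(mm, 1, mm_min = 1), character(0))
  # a gene equal to its ME has membership 1
  expect_equal(unname(mm["me_like", "ME1"]),
               cor(m["me_like", ], ms$eigengenes[, 1]), tolerance = 1e-12)
})

test_that("adjacency/TOM/membership are invariant to positive affine transforms", {
  set.seed(15)
  m <- matrix(rnorm(10 * 12), 10, 12, dimnames = list(paste0("g", 1:10), NULL))
  shift <- runif(10, -3, 3); scale_ <- runif(10, 0.5, 4)
  m2 <- m * scale_ + shift
  expect_equal(soft_adjacency(m, 5), soft_adjacency(m2, 5), tolerance = 1e-10)
  expect_equal(topological_overlap(soft_adjacency(m, 5)),
               topological_overlap(soft_adjacency(m2, 5)), tolerance = 1e-10)
  labels <- stats::setNames(rep(1:2, each = 5), rownames(m))
  expect_equal(module_membership(m, merge_modules(module_set(labels), m, 0)),
               module_membership(m2, merge_modules(module_set(labels), m2, 0)),
               tolerance = 1e-8)
})

test_that("gene-order permutation permutes outputs identically", {
  set.seed(16)
  m <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(paste0("g", 1:20), NULL))
  perm <- sample(20)
  a1 <- soft_adjacency(m, 5)
  a2 <- soft_adjacency(m[perm, ], 5)
  expect_equal(unclass(a2), unclass(a1)[perm, perm],
               tolerance = 1e-12, ignore_attr = TRUE)
  t1 <- topological_overlap(a1)
  expect_equal(topological_overlap(a2), t1[perm, perm], tolerance = 1e-12)
})
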