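# filtering, normalization, NB testing, BH, calling, replicate QC

test_that("filter_expressed keeps features reaching the threshold anywhere", {
  m <- rbind(f1 = c(0, 0, 0, 0), f2 = c(1, 0, 0, 0), f3 = c(5, 2, 3, 1))
  cm <- tiny_count_matrix(m)
  out <- filter_expressed(cm)
  expect_equal(rownames(out$counts), c("f2", "f3"))
  # all pass -> identical
  out2 <- filter_expressed(tiny_count_matrix(m + 1))
  expect_equal(nrow(out2$counts), 3L)
})

test_that("estimate_size_factors is median-of-ratios", {
  m <- matrix(c(10, 30, 50, 10, 30, 50), ncol = 2)
  expect_equal(unname(estimate_size_factors(tiny_count_matrix(m, "rna"))),
               c(1, 1))
  m2 <- matrix(c(10, 30, 50, 20, 60, 100), ncol = 2)
  sf <- estimate_size_factors(tiny_count_matrix(m2))
  expect_equal(unname(round(sf, 4)), c(0.7071, 1.4142))
  # permutation invariance
  sf_perm <- estimate_size_factors(tiny_count_matrix(m2[c(3, 1, 2), ]))
  expect_equal(unname(sf), unname(sf_perm))
  # no all-positive row -> instructive error
  m3 <- matrix(c(0, 5, 5, 0), ncol = 2)
  expect_error(estimate_size_factors(tiny_count_matrix(m3)), "prefilter")
})

test_that("nb_wald_test handles identical groups and recovers planted folds", {
  m <- matrix(rep(c(100, 50, 20), 6), ncol = 6)
  res <- nb_wald_test(tiny_count_matrix(m),
                      setNames(rep(1, 6), colnames(tiny_count_matrix(m)$counts)))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  # power: 4-fold at mean 100, dispersion 0.05, 3 vs 3
  set.seed(21)
  nf <- 1000
  cp <- cbind(matrix(rnbinom(nf * 3, mu = 100, size = 20), nf),
              matrix(rnbinom(nf * 3, mu = 400, size = 20), nf))
  resp <- nb_wald_test(tiny_count_matrix(cp),
                       setNames(rep(1, 6), paste0(rep(c("WT", "mut"),
                                                      each = 3), "_r", 1:3)))
  expect_gte(mean(resp$p < 0.01), 0.9)
  expect_equal(median(resp$log2fc), 2, tolerance = 0.05)
  # genotype missing -> error
  cm <- tiny_count_matrix(m)
  cm$samples$genotype <- "WT"
  expect_error(nb_wald_test(cm), "both genotypes")
})

test_that("nb_wald_test per-feature dispersion mode works and flags zeros", {
  set.seed(22)
  cp <- matrix(rnbinom(600, mu = 50, size = 10), 100)
  cm <- tiny_count_matrix(cp)
  res <- nb_wald_test(cm, dispersion = "per-feature")
  expect_true(all(res$dispersion >= 1e-8))
  expect_true(length(unique(res$dispersion)) > 1L)
})

test_that("bh_adjust equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # monotone in ranks, permutation invariant up to reordering
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("call_differential applies the published thresholds", {
  res <- data.frame(feature = c("a", "b", "c"),
                    baseMean = 1,
                    log2fc = c(log2(1.25), log2(3), log2(1.1)),
                    p = c(0.001, 0.01, 0.0001))
  # engineer padj: single features through bh are the p themselves
  out <- call_differential(data.frame(feature = "a", baseMean = 1,
                                      log2fc = log2(1.25), p = 0.04))
  expect_equal(out$call, "up")
  out <- call_differential(data.frame(feature = "a", baseMean = 1,
                                      log2fc = log2(3), p = 0.06))
  expect_equal(out$call, "ns")
  out <- call_differential(data.frame(feature = "a", baseMean = 1,
                                      log2fc = log2(1.1), p = 0.01))
  expect_equal(out$call, "ns")
  out <- call_differential(data.frame(feature = "a", baseMean = 1,
                                      log2fc = -log2(1.3), p = 0.01))
  expect_equal(out$call, "down")
  expect_error(call_differential(res, fc_min = 1), "exceed 1")
  # conservation: up + down + ns = total
  set.seed(24)
  res2 <- data.frame(feature = paste0("f", 1:200), baseMean = 1,
                     log2fc = rnorm(200), p = runif(200))
  out2 <- call_differential(res2)
  expect_equal(sum(table(out2$call)), 200L)
  expect_true(all(out2$padj >= out2$p - 1e-12))
})

test_that("replicate_spearman matches rank-then-Pearson", {
  m <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4, 4, 3, 2, 1, 8, 6, 4, 2), ncol = 4)
  cm <- tiny_count_matrix(m)
  qc <- replicate_spearman(cm)
  expect_equal(qc$spearman_r[qc$genotype == "WT"], 1)
  expect_equal(qc$spearman_r[qc$genotype == "mutant"], 1)  # same ranks
  m2 <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1, 5, 5, 5, 5, 1, 2, 3, 4), ncol = 4)
  qc2 <- replicate_spearman(tiny_count_matrix(m2))
  expect_equal(qc2$spearman_r[1], -1)
  expect_true(is.na(qc2$spearman_r[2]))  # constant replicate
  set.seed(25)
  for (rep in 1:10) {
    a <- rpois(50, 20); b <- rpois(50, 20)
    cm3 <- tiny_count_matrix(cbind(a, b, a, b))
    r <- replicate_spearman(cm3)$spearman_r[1]
    expect_equal(r, cor(rank(a), rank(b)), tolerance = 1e-12)
  }
})

test_that("scaling by size factors is a fixed point", {
  # median-of-ratios is equivariant: rescaled counts give constant factors
  # (all 1 once the factors are normalized to geometric mean 1)
  set.seed(26)
  m <- matrix(rnbinom(400, mu = 60, size = 5) + 1, ncol = 4)
  cm <- tiny_count_matrix(m)
  sf <- estimate_size_factors(cm)
  scaled <- sweep(m, 2, sf, "/")
  cm2 <- tiny_count_matrix(scaled)
  sf2 <- unname(estimate_size_factors(cm2))
  gm <- exp(mean(log(sf)))
  expect_equal(sf2, rep(gm, 4), tolerance = 1e-12)
  expect_equal(sf2, rep(1, 4), tolerance = 0.05)
})

test_that("k9_relative_summary detects genotype shifts in K9/H3 ratio", {
  set.seed(27)
  n <- 2000
  base <- matrix(rpois(n * 4, 100), n)
  # identical genotypes -> degenerate all-zero differences -> p = 1
  same <- tiny_count_matrix(cbind(base[, 1:2], base[, 1:2]), "chip_k9")
  h3s <- tiny_count_matrix(cbind(base[, 3:4], base[, 3:4]), "chip_h3")
  rownames(h3s$counts) <- rownames(same$counts)
  expect_equal(k9_relative_summary(same, h3s)$p, 1)
  # a sparse subset of hyper-methylated features is identifiable after depth
  # normalization (a uniform genome-wide change is not, as in real CPM data)
  boosted <- base[, 1:2]
  boosted[1:30, ] <- boosted[1:30, ] * 8
  shifted <- tiny_count_matrix(cbind(base[, 1:2], boosted), "chip_k9")
  rownames(shifted$counts) <- rownames(h3s$counts)
  res <- k9_relative_summary(shifted, h3s)
  expect_lt(res$p, 1e-6)
  expect_error(k9_relative_summary(same, tiny_count_matrix(base[1:50, ])),
               "feature set")
})

test_that("signed-rank p is extreme under a constant shift and matches the
           exact enumeration at small n", {
  # constant +1 shift across 100 paired differences
  set.seed(28)
  d <- rnorm(100, mean = 0, sd = 0.01) + 1
  expect_lt(k9balance:::signed_rank_p(d), 1e-6)
  for (rep in 1:30) {
    d <- round(rnorm(12), 3)
    d <- d[d != 0]
    if (anyDuplicated(abs(d))) next
    got <- k9balance:::signed_rank_p(d)
    expect_equal(got, oracle_signed_rank_p(d), tolerance = 0.1 * got + 1e-12)
  }
})
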