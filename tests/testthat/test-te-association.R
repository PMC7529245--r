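# association curves, resampling nulls, nearest-TE contrast, enrichment

test_that("association_curve is zero without TEs and monotone in d", {
  genes <- data.frame(id = paste0("g", 1:6), chrom = "Chr1",
                      start = seq(100, 2100, 400),
                      end = seq(100, 2100, 400) + 200,
                      stringsAsFactors = FALSE)
  no_te <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  ac <- association_curve(genes[1:3, ], genes[4:6, ], no_te,
                          c(Chr1 = 5000), max_d = 400, step = 100)
  expect_true(all(ac$curve$mean_focal == 0))
  expect_true(all(ac$curve$mean_background == 0))
  set.seed(41)
  tes <- random_intervals(40, max_coord = 5000)
  ac2 <- association_curve(genes[1:3, ], genes[4:6, ], tes,
                           c(Chr1 = 5000), max_d = 1000, step = 100)
  expect_true(all(diff(ac2$curve$mean_focal) >= 0))
  expect_true(all(diff(ac2$curve$mean_background) >= 0))
  expect_error(association_curve(genes[1:3, ], genes[3:6, ], tes,
                                 c(Chr1 = 5000)), "disjoint")
  expect_error(association_curve(genes[0, ], genes[4:6, ], tes,
                                 c(Chr1 = 5000)), "non-empty")
})

test_that("resampled_anova is calibrated and powered", {
  set.seed(42)
  pool <- rgamma(1000, shape = 1.2, scale = 300)
  # null: averaging over independent focal draws concentrates near 0.5
  avg <- mean(vapply(1:10, function(i) {
    focal <- sample(pool, 165)
    resampled_anova(focal, pool, n_resample = 200, seed = i)
  }, numeric(1)))
  expect_gt(avg, 0.35); expect_lt(avg, 0.65)
  # 3-pooled-SD shift
  focal_shift <- sample(pool, 165) + 3 * sd(pool)
  p_shift <- resampled_anova(focal_shift, pool, n_resample = 200, seed = 1)
  expect_lt(p_shift, 1e-4)
  # determinism
  expect_identical(resampled_anova(focal_shift, pool, 100, seed = 7),
                   resampled_anova(focal_shift, pool, 100, seed = 7))
  expect_error(resampled_anova(1, pool), ">= 2")
  expect_error(resampled_anova(rep(1, 10), 1:5), "at least as large")
})

test_that("association_curve recovers a planted shift (construction)", {
  # two gene sets over the same TE field, one shifted into a TE-dense zone
  set.seed(43)
  tes <- data.frame(chrom = "Chr1", start = seq(0, 9900, 100),
                    end = seq(0, 9900, 100) + 50)
  g1 <- data.frame(id = paste0("a", 1:5), chrom = "Chr1",
                   start = seq(100, 900, 200), end = seq(100, 900, 200) + 100)
  ac <- association_curve(g1, transform(g1, id = paste0("b", 1:5)),
                          tes, c(Chr1 = 1e4), max_d = 200, step = 100)
  expect_equal(ac$curve$mean_focal, ac$curve$mean_background)
})

test_that("nearest_distance_ttest compares group means with Welch t", {
  genes <- data.frame(id = paste0("g", 1:8), chrom = "Chr1",
                      start = seq(0, 7000, 1000), end = seq(0, 7000, 1000) + 100,
                      stringsAsFactors = FALSE)
  tes <- data.frame(chrom = "Chr1", start = c(150, 1180, 2300, 3500, 4210,
                                              5170, 6300, 7450),
                    end = c(160, 1190, 2310, 3510, 4220, 5180, 6310, 7460))
  nd <- nearest_distance_ttest(genes[1:4, ], genes[1:4, ], tes)
  expect_equal(nd$mean_a, nd$mean_b)
  expect_equal(nd$p, 1)
  # planted inflation
  tes_far <- tes; tes_far$start <- tes_far$start + 300
  tes_far$end <- tes_far$end + 300
  set.seed(44)
  da <- vapply(1:500, function(i) {
    # two groups from one distance distribution -> p approx uniform
    d <- rgamma(165, 1.5, scale = 800)
    g <- sample(rep(c(1, 2), c(59, 106)))
    t.test(d[g == 1], d[g == 2])$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(da, "punif")$p.value), 0.01)
})

test_that("superfamily_size_proportions sums to one and weighs by length", {
  te1 <- data.frame(chrom = "c", start = 0, end = 500, superfamily = "Gypsy")
  pr <- superfamily_size_proportions(te1)
  expect_equal(unname(pr["Gypsy"]), 1)
  expect_equal(sum(pr), 1)
  te2 <- rbind(te1,
               data.frame(chrom = "c", start = c(600, 1200),
                          end = c(850, 1450), superfamily = "Copia"))
  pr2 <- superfamily_size_proportions(te2)
  expect_equal(unname(pr2["Gypsy"]), 0.5)
  expect_equal(unname(pr2["Copia"]), 0.5)
  set.seed(45)
  tes <- random_intervals(50)
  tes$superfamily <- sample(c("Gypsy", "Copia", "LINE", "DNA", "other"),
                            50, TRUE)
  pr3 <- superfamily_size_proportions(tes)
  expect_equal(sum(pr3), 1)
  len <- tes$end - tes$start
  expect_equal(unname(pr3["LINE"]),
               sum(len[tes$superfamily == "LINE"]) / sum(len))
  expect_error(superfamily_size_proportions(tes[0, ]), "non-empty")
})

test_that("randomized_fisher_enrichment computes observed and null summaries", {
  ann <- generate_annotation(synth_config(seed = 46, n_chrom = 1L,
                                          chrom_length = 6e5, n_genes = 100L,
                                          n_nlr = 20L, n_focal_nlr = 5L,
                                          n_te = 1000L,
                                          planted_nlr_te_excess_bp = 0))
  a <- ann$annotation
  # proportional focal set -> p near 1 on a balanced table
  tes5 <- data.frame(id = paste0("t", 1:110), chrom = "c", start = 0,
                     end = 10,
                     superfamily = rep(c("Gypsy", "other"),
                                       times = c(55, 55)))
  part1 <- data.frame(chrom = "c", start = 0, end = 100, label = "arm")
  tes5$start <- seq(0, 109) ; tes5$end <- tes5$start + 1
  part1$end <- 200
  focal5 <- tes5[c(1:5, 56:60), ]  # 5/5 vs 50/50
  row <- randomized_fisher_enrichment(focal5, tes5, part1, "Gypsy", "arm",
                                      n_random = 50, seed = 1)
  expect_equal(row$p_observed, 1)
  # extreme enrichment: focal all one superfamily, background 10%
  n_pool <- 1000
  tesx <- data.frame(id = paste0("x", seq_len(n_pool)), chrom = "c",
                     start = seq_len(n_pool) - 1, end = seq_len(n_pool),
                     superfamily = c(rep("Copia", 140),
                                     rep("other", n_pool - 140)))
  focalx <- tesx[1:50, ]  # 100% Copia focal vs ~10% background
  partx <- data.frame(chrom = "c", start = 0, end = n_pool, label = "arm")
  rowx <- randomized_fisher_enrichment(focalx, tesx, partx, "Copia", "arm",
                                       n_random = 1000, seed = 2)
  expect_lt(rowx$p_observed, 1e-10)
  expect_lte(rowx$rank_observed, 1 / 1000)
  # empty focal set in compartment -> undefined-marker row
  row0 <- randomized_fisher_enrichment(tesx[0, ], tesx, partx, "Copia",
                                       "pericentromere", n_random = 10)
  expect_true(is.na(row0$p_observed))
  # determinism
  r1 <- randomized_fisher_enrichment(focalx, tesx, partx, "Copia", "arm",
                                     n_random = 100, seed = 9)
  r2 <- randomized_fisher_enrichment(focalx, tesx, partx, "Copia", "arm",
                                     n_random = 100, seed = 9)
  expect_identical(r1, r2)
})

test_that("Fisher exact p agrees with hypergeometric enumeration", {
  set.seed(47)
  for (rep in 1:200) {
    n <- sample(4:40, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c_ <- sample(0:(n - a - b), 1); d <- n - a - b - c_
    p_lib <- fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    p_or <- oracle_fisher_p(a, b, c_, d)
    expect_equal(p_lib, p_or, tolerance = 1e-7)
  }
})

test_that("null randomized-Fisher ranks are roughly uniform", {
  set.seed(48)
  n_pool <- 300
  tesn <- data.frame(id = paste0("n", seq_len(n_pool)), chrom = "c",
                     start = seq_len(n_pool) - 1, end = seq_len(n_pool),
                     superfamily = sample(c("Gypsy", "other"), n_pool, TRUE))
  partn <- data.frame(chrom = "c", start = 0, end = n_pool, label = "arm")
  ranks <- vapply(1:60, function(i) {
    focal <- tesn[sample.int(n_pool, 40), ]
    randomized_fisher_enrichment(focal, tesn, partn, "Gypsy", "arm",
                                 n_random = 99, seed = i)$rank_observed
  }, numeric(1))
  # discrete null: check coarse uniformity of the rank distribution
  expect_gt(mean(ranks), 0.3)
  expect_lt(mean(ranks), 0.7)
  expect_gt(mean(ranks < 0.25), 0.08)
  expect_gt(mean(ranks > 0.75), 0.08)
})
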