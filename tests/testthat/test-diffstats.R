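# Normalization, NB Wald test, BH FDR and the low-count filter.

test_that("size factors are 1 for identical samples and scale-equivariant", {
  cm <- toy_counts(rep(c(10, 20, 30), 3), 3, c("s1", "s2", "s3"),
                   c("case", "case", "control"))
  expect_equal(unname(size_factors_median_of_ratios(cm)), rep(1, 3))
  m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
              dimnames = list(paste0("f", 1:3), c("A", "B")))
  sf <- size_factors_median_of_ratios(m)
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("size factors match the direct formula on a random matrix", {
  set.seed(1)
  m <- matrix(rpois(300, 50) + 1, nrow = 50,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:6)))
  sf <- size_factors_median_of_ratios(m)
  ref <- exp(rowMeans(log(m)))
  direct <- apply(m / ref, 2, median)
  direct <- direct / exp(mean(log(direct)))
  expect_equal(unname(sf), unname(direct), tolerance = 1e-12)
})

test_that("no all-positive feature errors with fallback advice", {
  m <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors_median_of_ratios(m), "fallback_total")
  expect_length(size_factors_median_of_ratios(m, fallback_total = TRUE), 2)
})

test_that("degenerate features: equal groups give p = 1, all-zero give NA", {
  # equal size factors by construction, so normalization is neutral
  m <- rbind(f1 = c(3, 3, 3, 3), f2 = c(7, 7, 7, 7), f3 = c(0, 0, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  cm <- count_matrix(m, setNames(c("case", "case", "control", "control"),
                                 colnames(m)))
  res <- nb_wald_test(cm)
  flat <- res[res$feature_id == "f2", ]   # identical in both groups
  expect_equal(flat$log2fc, 0)
  expect_equal(flat$pvalue, 1)
  zero <- res[res$feature_id == "f3", ]
  expect_equal(zero$log2fc, 0)
  expect_true(is.na(zero$pvalue) && is.na(zero$qvalue))
})

test_that("sample rescaling is absorbed by the size factors", {
  cfg <- simulation_config(seed = 31, n_genes = 300, n_tfs = 0,
                           n_null_tfs = 0, n_hit_compounds = 0)
  cm <- simulate_expression_counts(cfg, simulate_truth(cfg))
  base <- nb_wald_test(cm)
  s1 <- cm$counts; s1[, 1] <- s1[, 1] * 4
  s2 <- cm$counts; s2[, 2] <- s2[, 2] * 4
  r1 <- nb_wald_test(count_matrix(s1, cm$groups))
  r2 <- nb_wald_test(count_matrix(s2, cm$groups))
  # the scaled sample's factor absorbs the constant exactly ...
  sf0 <- attr(base, "size_factors"); sf1 <- attr(r1, "size_factors")
  expect_equal(unname(sf1[1] / sf0[1] / (sf1[2] / sf0[2])), 4,
               tolerance = 1e-12)
  # ... so it is irrelevant which sample carries the scaling,
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-10)
  # and the residual drift through the global normalization constant
  # (4^(1/10) here) is far below scientific relevance.
  expect_lt(max(abs(r1$pvalue - base$pvalue), na.rm = TRUE), 0.01)
})

test_that("null simulations keep the rejection rate near nominal", {
  rates <- vapply(1:3, function(s) {
    cfg <- simulation_config(seed = s, frac_de = 0, frac_dm_promoter = 0,
                             n_tfs = 0, n_null_tfs = 0,
                             n_hit_compounds = 0)
    res <- nb_wald_test(simulate_expression_counts(cfg,
                                                   simulate_truth(cfg)))
    mean(res$pvalue < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.07)
})

test_that("planted fold-changes are detected with the right sign", {
  cfg <- simulation_config(seed = 41, baseline_mean_expr = 500,
                           nb_dispersion = 0.05, lfc_de = 2,
                           frac_dm_promoter = 0, coupling = "none",
                           n_tfs = 0, n_null_tfs = 0, n_hit_compounds = 0)
  truth <- simulate_truth(cfg)
  res <- nb_wald_test(simulate_expression_counts(cfg, truth))
  planted <- res[match(truth$de_genes$gene_id, res$feature_id), ]
  up <- truth$de_genes$lfc > 0
  expect_gte(mean(planted$qvalue < 0.05, na.rm = TRUE), 0.9)
  expect_gte(mean(sign(planted$log2fc[up]) == 1), 0.95)
  expect_gte(mean(sign(planted$log2fc[!up]) == -1), 0.95)
})

test_that("BH matches the hand step-up formula and known examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(7)
  for (i in 1:5) {
    p <- runif(20)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("BH passes missing values through and stays monotone in p", {
  p <- c(0.01, NA, 0.5, 0.002, NA, 0.2)
  q <- bh_fdr(p)
  expect_true(all(is.na(q[is.na(p)])))
  expect_equal(q[!is.na(p)], oracle_bh(p[!is.na(p)]))
  set.seed(8)
  p2 <- runif(50)
  q2 <- bh_fdr(p2)
  o <- order(p2)
  expect_true(all(diff(q2[o]) >= -1e-12))
  perm <- sample(50)
  expect_equal(bh_fdr(p2[perm]), q2[perm])
})

test_that("low-count filter uses strict less-than on raw means", {
  m <- matrix(c(49, 50.8, 50, 50, 51, 51), nrow = 3, byrow = TRUE,
              dimnames = list(c("lo", "edge", "hi"), c("s1", "s2")))
  m["lo", ] <- c(49, 50)       # mean 49.5 -> removed
  m["edge", ] <- c(50, 50)     # mean 50 -> kept
  m["hi", ] <- c(51, 51)
  cm <- count_matrix(m, c(s1 = "case", s2 = "control"))
  kept <- filter_low_expression(cm, 50)
  expect_setequal(rownames(kept$counts), c("edge", "hi"))
  expect_equal(dim(filter_low_expression(cm, 0)), dim(cm))
  empty <- count_matrix(m[0, , drop = FALSE], c(s1 = "case",
                                                s2 = "control"))
  expect_equal(nrow(filter_low_expression(empty, 50)$counts), 0)
})
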