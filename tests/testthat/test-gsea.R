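# Ranked-list construction, weighted-KS enrichment score, permutation
# significance.  fgsea::calcGseaStat serves as an independent external
# oracle for the score; the naive loop in helper-oracles.R is the
# in-suite one.

test_that("ranking scores are signed -log10 p with deterministic ties", {
  de <- data.frame(feature_id = c("up", "dn", "flat", "one"),
                   log2fc = c(2, -2, 0, 1),
                   pvalue = c(0.001, 0.001, 0.5, 1))
  r <- build_ranked_list(de)
  expect_equal(r$score[r$gene_id == "up"], 3)
  expect_equal(r$score[r$gene_id == "dn"], -3)
  expect_equal(r$score[r$gene_id == "flat"], 0)   # lfc 0 scores 0
  expect_equal(r$score[r$gene_id == "one"], 0)    # p = 1 scores 0
  expect_equal(r$gene_id[1], "up")
  # ties broken lexicographically, descending order overall
  expect_equal(r$gene_id, r$gene_id[order(-r$score, r$gene_id)])
})

test_that("ranking matches a brute-force sort and handles edge cases", {
  set.seed(21)
  de <- data.frame(feature_id = sprintf("g%02d", 1:10),
                   log2fc = rnorm(10), pvalue = runif(10))
  r <- build_ranked_list(de)
  score <- sign(de$log2fc) * -log10(de$pvalue)
  ord <- order(-score, de$feature_id)
  expect_equal(r$gene_id, de$feature_id[ord])
  de$pvalue[3] <- NA
  expect_warning(r2 <- build_ranked_list(de), "skipped")
  expect_equal(nrow(r2), 9)
  de$pvalue[3] <- 0       # clamped, not infinite
  expect_true(all(is.finite(build_ranked_list(de)$score)))
})

test_that("integer-rank metric assigns magnitude N to the smallest p", {
  de <- data.frame(feature_id = c("a", "b", "c"),
                   log2fc = c(1, -1, 1),
                   pvalue = c(0.5, 0.01, 0.2))
  r <- build_ranked_list(de, metric = "signed_rank")
  expect_equal(r$score[r$gene_id == "b"], -3)
  expect_equal(r$score[r$gene_id == "c"], 2)
  expect_equal(r$score[r$gene_id == "a"], 1)
})

test_that("methylation gene sets split by region kind at the q threshold", {
  dm <- data.frame(
    feature_id = c("a|promoter", "b|promoter", "c|promoter", "a|exon",
                   "a|body"),
    log2fc = 1, pvalue = 0.01,
    qvalue = c(0.01, 0.04, 0.2, 0.03, 0.9))
  sets <- suppressWarnings(build_methylation_gene_sets(dm))
  expect_equal(sets$promoter, c("a", "b"))
  expect_equal(sets$exon, "a")       # same gene may appear in both sets
  expect_equal(sets$body, character(0))
  expect_warning(build_methylation_gene_sets(dm), "body")
  bad <- dm; bad$feature_id[1] <- "no-kind"
  expect_error(build_methylation_gene_sets(bad), "parseable")
})

test_that("enrichment score reproduces hand-evaluated running sums", {
  r <- toy_ranking()
  all_first <- gsea_enrichment_score(r, c("g1", "g2"))
  expect_equal(all_first$es, 1)      # all hits precede all misses
  expect_equal(all_first$leading_edge, c("g1", "g2"))
  split <- gsea_enrichment_score(r, c("g1", "g4"))
  expect_equal(split$es, 0.75)
  expect_equal(unname(split$running_sum),
               c(0.75, 0.75 - 1 / 3, 0.75 - 2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
  expect_equal(split$leading_edge, "g1")
  expect_error(gsea_enrichment_score(r, paste0("g", 1:5)), "universe")
  expect_error(gsea_enrichment_score(r, "absent"), "intersect")
})

test_that("enrichment score agrees with fgsea on random cases", {
  skip_if_not_installed("fgsea")
  set.seed(33)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    scores <- sort(round(rnorm(n), 3), decreasing = TRUE)
    # distinct scores keep the orderings comparable across codebases
    scores <- scores - seq_len(n) * 1e-6
    ids <- sprintf("g%03d", seq_len(n))
    sel <- sort(sample.int(n, sample(2:5, 1)))
    mine <- gsea_enrichment_score(
      data.frame(gene_id = ids, score = scores), ids[sel])$es
    ref <- fgsea::calcGseaStat(setNames(scores, ids), sel, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("fast positional score equals the full running-sum score", {
  set.seed(34)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    ids <- sprintf("g%03d", seq_len(n))
    sel <- sort(sample.int(n, sample(1:6, 1)))
    full <- gsea_enrichment_score(
      data.frame(gene_id = ids, score = scores), ids[sel])$es
    fast <- methyltrx:::es_from_positions(sel, abs(scores[sel]), n)
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("the running sum is conservative and the score is bounded", {
  set.seed(35)
  for (i in 1:10) {
    n <- 30
    scores <- sort(rnorm(n), decreasing = TRUE)
    ids <- sprintf("g%03d", seq_len(n))
    sel <- sample.int(n, 5)
    res <- gsea_enrichment_score(data.frame(gene_id = ids, score = scores),
                                 ids[sel])
    expect_lt(abs(res$running_sum[n]), 1e-9)
    expect_lte(abs(res$es), 1)
  }
})

test_that("negating scores and reversing the ranking negates the score", {
  r <- toy_ranking()
  set <- c("g1", "g4")
  es <- gsea_enrichment_score(r, set)$es
  flipped <- data.frame(gene_id = rev(r$gene_id), score = rev(-r$score))
  expect_equal(gsea_enrichment_score(flipped, set)$es, -es,
               tolerance = 1e-12)
})

test_that("a planted top-of-list set attains the minimal permutation p", {
  set.seed(36)
  n <- 200
  scores <- sort(rnorm(n), decreasing = TRUE)
  ids <- sprintf("g%03d", seq_len(n))
  ranked <- data.frame(gene_id = ids, score = scores)
  res <- gsea_significance(ranked, ids[1:10], n_perm = 999, seed = 2)
  expect_equal(res$es, 1)
  expect_lte(res$pvalue, 1 / 100)  # at or near the +1-smoothed floor
  expect_gt(res$nes, 1)
})

test_that("permutation significance is seed-deterministic", {
  ranked <- data.frame(gene_id = sprintf("g%03d", 1:50),
                       score = sort(rnorm(50), decreasing = TRUE))
  a <- gsea_significance(ranked, c("g001", "g010", "g030"), n_perm = 200,
                         seed = 5)
  b <- gsea_significance(ranked, c("g001", "g010", "g030"), n_perm = 200,
                         seed = 5)
  expect_identical(a, b)
  expect_error(gsea_significance(ranked, "g001", n_perm = 50), "100")
})

test_that("batch GSEA applies BH across the evaluated sets", {
  set.seed(37)
  ranked <- data.frame(gene_id = sprintf("g%03d", 1:100),
                       score = sort(rnorm(100), decreasing = TRUE))
  sets <- list(top = ranked$gene_id[1:8],
               rand1 = sample(ranked$gene_id, 8),
               rand2 = sample(ranked$gene_id, 8))
  res <- gsea_batch(ranked, sets, n_perm = 300, seed = 1)
  expect_equal(res$qvalue, bh_fdr(res$pvalue))
  expect_warning(
    res2 <- gsea_batch(ranked, c(sets, list(empty = "zzz")), n_perm = 300,
                       seed = 1),
    "skipped")
  expect_true(is.na(res2$es[res2$set_name == "empty"]))
})
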