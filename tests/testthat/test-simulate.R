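# Seed determinism, truth-set consistency and parameter recovery of the
# synthetic-data generator.

test_that("all generators are bit-reproducible under one seed", {
  cfg <- simulation_config(seed = 101, n_genes = 120, n_compounds = 10,
                           n_hit_compounds = 2, n_tfs = 2,
                           regulon_size = 5, n_null_tfs = 2)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  expect_identical(a$expr$counts, b$expr$counts)
  expect_identical(a$meth$counts, b$meth$counts)
  expect_identical(a$trn, b$trn)
  expect_identical(a$signatures$data, b$signatures$data)
})

test_that("truth sets are consistent with the simulated matrices", {
  cfg <- simulation_config(seed = 102, n_genes = 500, n_tfs = 2,
                           regulon_size = 20, n_null_tfs = 4,
                           n_compounds = 10, n_hit_compounds = 2)
  ds <- simulate_dataset(cfg)
  truth <- ds$truth
  expect_equal(nrow(truth$de_genes), round(cfg$frac_de * cfg$n_genes))
  expect_true(all(truth$de_genes$gene_id %in% rownames(ds$expr$counts)))
  expect_true(all(paste0(truth$dm_promoters$gene_id, "|promoter") %in%
                    rownames(ds$meth$counts)))
  # anti-coupling: coupled genes sit in both truth sets, downregulated
  expect_true(all(truth$coupled_pairs %in% truth$de_genes$gene_id))
  expect_true(all(truth$coupled_pairs %in% truth$dm_promoters$gene_id))
  lfc <- truth$de_genes$lfc[match(truth$coupled_pairs,
                                  truth$de_genes$gene_id)]
  expect_true(all(lfc < 0))
  # TF ids are disjoint from regulon target ids
  expect_length(intersect(truth$tf_table$tf_id, truth$regulons$target), 0)
})

test_that("regulon alteration counts follow the configured fractions", {
  cfg <- simulation_config(seed = 103, n_tfs = 4, regulon_size = 50,
                           frac_regulon_altered = 0.3)
  truth <- simulate_truth(cfg)
  planted <- truth$tf_table$tf_id[truth$tf_table$planted]
  for (tf in planted) {
    reg <- truth$regulons[truth$regulons$tf_id == tf, ]
    expect_equal(nrow(reg), 50)
    expect_equal(sum(reg$altered), 15)
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(seed = 1, frac_de = 0.02,
                                 frac_dm_promoter = 0.05),
               "frac_dm_promoter <= frac_de")
  expect_error(simulation_config(seed = 1, frac_de = 0.04,
                                 frac_dm_promoter = 0.03),
               "budget")
  expect_error(simulation_config(seed = 1, n_genes = 100, n_tfs = 10,
                                 n_null_tfs = 0, regulon_size = 20,
                                 frac_de = 1, frac_dm_promoter = 0),
               "too small")
  expect_error(simulation_config(n_genes = 10), "seed")
})

test_that("frac_de = 0 centers observed expression log-ratios at zero", {
  cfg <- simulation_config(seed = 104, frac_de = 0, frac_dm_promoter = 0,
                           n_case = 10, n_control = 10, n_tfs = 0,
                           n_null_tfs = 0, n_hit_compounds = 0)
  cm <- simulate_expression_counts(cfg, simulate_truth(cfg))
  m1 <- rowMeans(cm$counts[, cm$groups == "case"])
  m2 <- rowMeans(cm$counts[, cm$groups == "control"])
  expect_lt(abs(median(log2((m1 + 0.5) / (m2 + 0.5)))), 0.1)
})

test_that("planted expression fold-changes are recovered on average", {
  obs <- vapply(1:5, function(s) {
    cfg <- simulation_config(seed = s, baseline_mean_expr = 500,
                             nb_dispersion = 0.05, lfc_de = 2,
                             frac_dm_promoter = 0, coupling = "none",
                             n_tfs = 0, n_null_tfs = 0,
                             n_hit_compounds = 0)
    truth <- simulate_truth(cfg)
    cm <- simulate_expression_counts(cfg, truth)
    up <- truth$de_genes$gene_id[truth$de_genes$lfc > 0]
    m1 <- rowMeans(cm$counts[up, cm$groups == "case"])
    m2 <- rowMeans(cm$counts[up, cm$groups == "control"])
    mean(log2(m1 / m2))
  }, numeric(1))
  expect_lt(abs(mean(obs) - 2), 0.2)
})

test_that("planted promoter hypermethylation is recovered on average", {
  obs <- vapply(1:5, function(s) {
    cfg <- simulation_config(seed = s, lfc_dm = 1.5,
                             baseline_mean_meth = 200)
    truth <- simulate_truth(cfg)
    cm <- simulate_methylation_counts(cfg, truth,
                                      simulate_annotation(cfg))
    rid <- paste0(truth$dm_promoters$gene_id, "|promoter")
    m1 <- rowMeans(cm$counts[rid, cm$groups == "case"])
    m2 <- rowMeans(cm$counts[rid, cm$groups == "control"])
    mean(log2(m1 / m2))
  }, numeric(1))
  expect_lt(abs(mean(obs) - 1.5), 0.2)
})

test_that("frac_dm_promoter = 0 leaves the hypermethylation set empty", {
  cfg <- simulation_config(seed = 105, frac_dm_promoter = 0)
  expect_equal(nrow(simulate_truth(cfg)$dm_promoters), 0)
})

test_that("a written dataset loads back into equivalent objects", {
  cfg <- simulation_config(seed = 106, n_genes = 60, n_compounds = 4,
                           n_hit_compounds = 0, n_tfs = 0,
                           n_null_tfs = 2, regulon_size = 5,
                           n_replicates_per_signature = 2)
  d <- tempfile()
  ds <- simulate_dataset(cfg, d)
  expect_true(all(file.exists(file.path(d, c(
    "annotation.gtf", "expr_counts.tsv", "meth_counts.tsv", "groups.tsv",
    "trn.tsv", "truth.json")))))
  expr <- read_count_matrix(file.path(d, "expr_counts.tsv"),
                            file.path(d, "groups.tsv"))
  expect_identical(expr$counts, ds$expr$counts)
  net <- read_network(file.path(d, "trn.tsv"))
  expect_equal(nrow(net$edges), nrow(ds$trn$edges))
  sg <- read_compound_signatures(file.path(d, "signatures"))
  expect_equal(sg$contexts, ds$signatures$contexts)
})

test_that("one-gene and tiny edge configurations stay valid", {
  cfg <- simulation_config(seed = 107, n_genes = 1, frac_de = 0,
                           frac_dm_promoter = 0, n_tfs = 0,
                           n_null_tfs = 0, n_hit_compounds = 0,
                           n_compounds = 0)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 1)
  expect_gte(nrow(ann$exons), 1)
  expect_equal(ann$genes$tss,
               ifelse(ann$genes$strand == "+", ann$genes$start,
                      ann$genes$end - 1))
})
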