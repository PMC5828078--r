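# Consensus signatures and the top-k compound query.

test_that("consensus of identical replicates is the z-scored replicate", {
  set.seed(71)
  v <- rnorm(50)
  names(v) <- sprintf("g%02d", 1:50)
  reps <- cbind(v, v, v)
  cons <- consensus_signature(reps)
  expect_equal(cons, setNames((v - mean(v)) / sd(v), names(v)))
})

test_that("a sign-flipped gene shrinks toward zero under the median", {
  set.seed(70)
  v <- setNames(c(5, rnorm(49)), sprintf("g%02d", 1:50))
  flip <- v; flip["g01"] <- -5
  cons <- consensus_signature(cbind(v, flip))
  solo <- consensus_signature(cbind(v, v))
  expect_lt(abs(cons["g01"]), abs(solo["g01"]))
})

test_that("consensus matches the median-of-z oracle and checks universes", {
  set.seed(72)
  m <- matrix(rnorm(150), 50, 3,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  cons <- consensus_signature(m)
  z <- apply(m, 2, function(col) (col - mean(col)) / sd(col))
  expect_equal(unname(cons), unname(apply(z, 1, median)),
               tolerance = 1e-12)
  bad <- list(setNames(rnorm(3), c("a", "b", "c")),
              setNames(rnorm(3), c("a", "b", "d")))
  expect_error(consensus_signature(bad), "universes differ")
})

test_that("the vectorized consensus equals the per-compound function", {
  set.seed(73)
  arr <- array(rnorm(40 * 6 * 3), dim = c(40, 6, 3),
               dimnames = list(sprintf("g%02d", 1:40),
                               sprintf("c%d", 1:6), 1:3))
  cm <- methyltrx:::consensus_matrix(arr)
  for (ci in 1:6) {
    expect_equal(unname(cm[, ci]),
                 unname(consensus_signature(arr[, ci, ])),
                 tolerance = 1e-12)
  }
})

test_that("top-k membership respects the exact rank-k boundary", {
  sig <- setNames(seq(500, 1, -1), sprintf("g%03d", 1:500))
  expect_equal(top_k_membership(sig, "g100", k = 100)$direction, "up")
  expect_equal(top_k_membership(sig, "g101", k = 100)$direction, "none")
  expect_equal(top_k_membership(sig, "g500", k = 1)$direction, "down")
  expect_error(top_k_membership(sig, "g001", k = 250), "n_genes / 2")
  expect_error(top_k_membership(sig, "zz"), "not in the signature")
})

test_that("membership is invariant under strictly monotone transforms", {
  set.seed(74)
  sig <- setNames(rnorm(400), sprintf("g%03d", 1:400))
  for (g in sample(names(sig), 10)) {
    a <- top_k_membership(sig, g, 50)
    b <- top_k_membership(exp(2 * sig) + 7, g, 50)
    expect_equal(a$direction, b$direction)
    expect_equal(a$rank_up, b$rank_up)
  }
})

test_that("query ranks agree with a brute-force sort oracle", {
  set.seed(75)
  n <- 500
  genes <- sprintf("g%03d", 1:n)
  arr <- array(rnorm(n * 20 * 2), dim = c(n, 20, 2),
               dimnames = list(genes, sprintf("c%02d", 1:20), 1:2))
  set <- structure(list(genes = genes, contexts = "NEU",
                        compounds = sprintf("c%02d", 1:20),
                        data = list(NEU = arr)),
                   class = "compound_signature_set")
  tf <- "g250"
  hits <- query_compounds(set, tf, k = 50)
  for (ci in 1:20) {
    cons <- consensus_signature(arr[, ci, ])
    ord_up <- order(-cons, names(cons))
    r_up <- which(names(cons)[ord_up] == tf)
    ord_dn <- order(cons, names(cons))
    r_dn <- which(names(cons)[ord_dn] == tf)
    row <- hits[hits$compound_id == sprintf("c%02d", ci), ]
    if (r_up <= 50) {
      expect_equal(row$direction, "up"); expect_equal(row$tf_rank, r_up)
    } else if (r_dn <= 50) {
      expect_equal(row$direction, "down"); expect_equal(row$tf_rank, r_dn)
    } else {
      expect_equal(nrow(row), 0)
    }
  }
})

test_that("planted hit compounds rank first in every replicate", {
  cfg <- simulation_config(seed = 76, n_genes = 500, n_compounds = 30,
                           n_hit_compounds = 3, compound_effect_size = 10,
                           n_tfs = 2, regulon_size = 10, n_null_tfs = 0)
  truth <- simulate_truth(cfg)
  sg <- simulate_compound_signatures(cfg, truth)
  h <- truth$compound_hits[1, ]
  arr <- sg$data[[h$context]]
  for (r in seq_len(dim(arr)[3])) {
    v <- arr[, h$compound_id, r]
    rk <- if (h$direction == "up") which.max(v) else which.min(v)
    expect_equal(names(rk), h$tf_id)
  }
  hits <- query_compounds(sg, h$tf_id, k = 50)
  match_row <- hits[hits$compound_id == h$compound_id &
                      hits$context == h$context, ]
  expect_equal(match_row$direction, h$direction)
  expect_equal(match_row$tf_rank, 1L)
})

test_that("signature sets round-trip through per-context TSV files", {
  cfg <- simulation_config(seed = 77, n_genes = 40, n_compounds = 5,
                           n_hit_compounds = 0, n_tfs = 0, n_null_tfs = 0,
                           n_replicates_per_signature = 2)
  sg <- simulate_compound_signatures(cfg, simulate_truth(cfg))
  d <- tempfile()
  write_compound_signatures(sg, d)
  back <- read_compound_signatures(d)
  expect_equal(back$genes, sg$genes)
  expect_equal(back$contexts, sg$contexts)
  for (cx in sg$contexts) {
    expect_equal(unname(back$data[[cx]]), unname(sg$data[[cx]]),
                 tolerance = 1e-9)
  }
})
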