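# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (plain loops, O(P x R) scans, explicit
# step-up formulas) and never share code with the implementation paths
# they check.

# Brute-force weighted-KS running sum: plain loop over the ranking.
oracle_es <- function(scores, ids, set, weight = 1) {
  hit <- ids %in% set
  w <- abs(scores[hit])^weight
  if (sum(w) == 0) w <- rep(1, length(w))
  run <- 0; best <- 0
  wi <- 0
  for (i in seq_along(ids)) {
    if (hit[i]) {
      wi <- wi + 1
      run <- run + w[wi] / sum(w)
    } else {
      run <- run - 1 / (length(ids) - sum(hit))
    }
    if (abs(run) > abs(best) ||
        (abs(run) == abs(best) && run > best)) best <- run
  }
  best
}

# Brute-force per-position membership scan against every region interval.
oracle_region_counts <- function(positions, regions) {
  iv <- regions$intervals
  rid <- regions$regions$region_id
  out <- matrix(0, length(rid), length(positions),
                dimnames = list(rid, names(positions)))
  for (j in seq_along(positions)) {
    for (p in positions[[j]]) {
      for (r in seq_len(nrow(iv))) {
        if (p >= iv$start[r] && p < iv$end[r]) {
          out[iv$region_id[r], j] <- out[iv$region_id[r], j] + 1
        }
      }
    }
  }
  out
}

# Explicit BH step-up evaluated from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# Tiny deterministic count matrix.
toy_counts <- function(values, n_feat, samples, groups) {
  m <- matrix(values, nrow = n_feat,
              dimnames = list(paste0("f", seq_len(n_feat)), samples))
  count_matrix(m, setNames(groups, samples))
}

# The 5-gene reference ranking used in several GSEA tests.
toy_ranking <- function() {
  data.frame(gene_id = paste0("g", 1:5), score = c(3, 2, 1, -1, -2),
             stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
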