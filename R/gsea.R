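# Preranked GSEA: signed expression ranking, methylation-derived gene
# sets, the weighted Kolmogorov-Smirnov running-sum enrichment score, and
# gene-tag permutation significance with BH FDR across sets.  This is the
# coupling test between promoter/exon/body methylation calls and the
# genome-wide expression ranking.

#' Build the signed expression ranking
#'
#' Upregulated genes score positive, downregulated negative.  The default
#' metric is `sign(log2fc) * -log10(p)` (p clamped to the smallest positive
#' double; a zero log2 fold-change scores 0); `metric = "signed_rank"`
#' uses literal integer ranks (most significant gene gets magnitude N)
#' instead.  Ties are broken lexicographically by gene id and the list is
#' ordered best-up first.
#'
#' @param de differential-result data.frame (feature_id, log2fc, pvalue).
#' @param metric `"signed_logp"` (default) or `"signed_rank"`.
#' @return data.frame with columns gene_id, score, in descending score
#'   order.
#' @export
build_ranked_list <- function(de, metric = c("signed_logp", "signed_rank")) {
  metric <- match.arg(metric)
  stopifnot(all(c("feature_id", "log2fc", "pvalue") %in% names(de)))
  if (anyDuplicated(de$feature_id)) stop("duplicate gene ids in input")
  drop <- is.na(de$pvalue)
  if (any(drop)) {
    warning(sum(drop), " feature(s) without p-value skipped")
    de <- de[!drop, , drop = FALSE]
  }
  check_pvalues(de$pvalue)
  p <- pmax(de$pvalue, .Machine$double.xmin)
  if (metric == "signed_logp") {
    score <- sign(de$log2fc) * -log10(p)
  } else {
    ord <- order(p, de$feature_id)
    mag <- numeric(length(p))
    mag[ord] <- seq(length(p), 1)
    score <- sign(de$log2fc) * mag
  }
  score[de$log2fc == 0] <- 0
  out <- data.frame(gene_id = de$feature_id, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene sets from differentially methylated regions
#'
#' Region ids of the form `"gene|kind"` with q below the threshold define
#' one gene set per region kind (promoter, exon, body).
#'
#' @param meth_de differential-result data.frame over region ids.
#' @param q_threshold FDR cut for set membership (default 0.05).
#' @return named list of character vectors, one per region kind present in
#'   the input.  Empty sets are kept and flagged with a warning.
#' @export
build_methylation_gene_sets <- function(meth_de, q_threshold = 0.05) {
  check_diff_result(meth_de)
  ids <- meth_de$feature_id
  if (any(!grepl("|", ids, fixed = TRUE))) {
    stop("region id not parseable as 'gene|kind': ",
         ids[!grepl("|", ids, fixed = TRUE)][1])
  }
  gene <- sub("\\|[^|]*$", "", ids)
  kind <- sub("^.*\\|", "", ids)
  if (!all(kind %in% c("promoter", "exon", "body"))) {
    stop("unknown region kind: ",
         paste(unique(setdiff(kind, c("promoter", "exon", "body"))),
               collapse = ", "))
  }
  sets <- lapply(split(seq_along(ids), kind), function(idx) {
    sig <- idx[!is.na(meth_de$qvalue[idx]) & meth_de$qvalue[idx] < q_threshold]
    sort(unique(gene[sig]))
  })
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) {
    warning("no significant regions for set(s): ",
            paste(empty, collapse = ", "))
  }
  sets
}

# Normalize ranking input to an ordered data.frame(gene_id, score).
as_ranked <- function(ranked) {
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- data.frame(gene_id = names(ranked), score = unname(ranked),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "score") %in% names(ranked)))
  if (anyDuplicated(ranked$gene_id)) stop("duplicate gene ids in ranking")
  ranked <- ranked[order(-ranked$score, ranked$gene_id), , drop = FALSE]
  rownames(ranked) <- NULL
  ranked
}

#' Weighted-KS enrichment score and running sum
#'
#' Walking the ranking from the top, set members ("hits") add
#' `|score|^weight / sum_hits |score|^weight` and non-members subtract
#' `1 / (N - N_hits)`.  The enrichment score is the running-sum value of
#' maximal absolute deviation (a sign tie breaks toward positive); the
#' leading edge collects the hits at or before the extremum (at or after,
#' for a negative score).  If all hit weights are zero they are replaced
#' by equal weights.
#'
#' @param ranked ordered ranking (data.frame gene_id/score or named vector).
#' @param gene_set character vector of member gene ids.
#' @param weight weighting exponent on `|score|` (default 1, the classic
#'   weighted statistic).
#' @return list with `es`, `running_sum` (named by gene, in rank order) and
#'   `leading_edge`.
#' @export
gsea_enrichment_score <- function(ranked, gene_set, weight = 1) {
  ranked <- as_ranked(ranked)
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop("gene set does not intersect the ranking")
  if (nh == N) stop("gene set equals the ranked universe; no misses defined")
  w <- abs(ranked$score[hit])^weight
  if (sum(w) == 0) w <- rep(1, nh)
  step <- numeric(N)
  step[hit] <- w / sum(w)
  step[!hit] <- -1 / (N - nh)
  running <- cumsum(step)
  mx <- max(running); mn <- min(running)
  es <- if (mx >= -mn) mx else mn
  if (es >= 0) {
    iext <- which.max(running)
    le <- ranked$gene_id[seq_len(iext)][hit[seq_len(iext)]]
  } else {
    iext <- which.min(running)
    le <- ranked$gene_id[iext:N][hit[iext:N]]
  }
  list(es = es, running_sum = setNames(running, ranked$gene_id),
       leading_edge = le)
}

# O(s) enrichment score from sorted hit positions; identical statistic to
# gsea_enrichment_score, used inside the permutation loop.
es_from_positions <- function(pos, w, N) {
  s <- length(pos)
  if (sum(w) == 0) w <- rep(1, s)
  cw <- cumsum(w) / sum(w)
  d <- 1 / (N - s)
  drop_ <- (pos - seq_len(s)) * d
  R <- cw - drop_                       # value just after each hit
  L <- c(0, cw[-s]) - drop_             # value just before each hit
  mx <- max(R); mn <- min(L)
  if (mx >= -mn) mx else mn
}

#' Permutation significance for one gene set
#'
#' The null distribution is the enrichment score of `n_perm` uniformly
#' resampled gene sets of the same size (gene-tag permutation,
#' seed-deterministic).  The p-value is
#' `(1 + #{|null same-sign| >= |es|}) / (1 + #same-sign nulls)` and the
#' normalized score divides es by the mean absolute same-sign null.
#'
#' @param ranked ordered ranking (data.frame or named vector).
#' @param gene_set character vector of member gene ids.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed for the permutation stream.
#' @param weight weighting exponent (default 1).
#' @param set_name label recorded in the result.
#' @return one-row data.frame: set_name, size, es, nes, pvalue, qvalue
#'   (equal to pvalue for a single set; BH-adjusted across sets by
#'   [gsea_batch()]), leading_edge (comma-collapsed).
#' @export
gsea_significance <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                              weight = 1, set_name = "set") {
  if (n_perm < 100) stop("n_perm must be >= 100")
  ranked <- as_ranked(ranked)
  obs <- gsea_enrichment_score(ranked, gene_set, weight)
  N <- nrow(ranked)
  s <- sum(ranked$gene_id %in% gene_set)
  aw <- abs(ranked$score)^weight
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(b) {
    pos <- sort(sample.int(N, s))
    es_from_positions(pos, aw[pos], N)
  }, numeric(1))
  same <- if (obs$es >= 0) null_es >= 0 else null_es < 0
  n_same <- sum(same)
  pvalue <- (1 + sum(same & abs(null_es) >= abs(obs$es))) / (1 + n_same)
  nes <- if (n_same > 0) obs$es / mean(abs(null_es[same])) else NA_real_
  data.frame(set_name = set_name, size = s, es = obs$es, nes = nes,
             pvalue = pvalue, qvalue = pvalue,
             leading_edge = paste(obs$leading_edge, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Permutation GSEA over a collection of gene sets
#'
#' Runs [gsea_significance()] per set (with a per-set sub-seed derived from
#' `seed` and the set name) and BH-adjusts the p-values across all sets
#' evaluated in the call.  Sets that do not intersect the ranking are
#' reported with missing scores and a warning rather than an error.
#'
#' @param ranked ordered ranking.
#' @param sets named list of gene sets.
#' @param n_perm,seed,weight as in [gsea_significance()].
#' @return data.frame, one row per set, with BH q-values.
#' @export
gsea_batch <- function(ranked, sets, n_perm = 1000, seed = 1, weight = 1) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  rows <- lapply(names(sets), function(nm) {
    res <- tryCatch(
      gsea_significance(ranked, sets[[nm]], n_perm = n_perm,
                        seed = stage_seed(seed, nm), weight = weight,
                        set_name = nm),
      error = function(e) {
        warning("set '", nm, "' skipped: ", conditionMessage(e))
        data.frame(set_name = nm, size = length(sets[[nm]]), es = NA_real_,
                   nes = NA_real_, pvalue = NA_real_, qvalue = NA_real_,
                   leading_edge = "", stringsAsFactors = FALSE)
      })
    res
  })
  out <- do.call(rbind, rows)
  out$qvalue <- bh_fdr(out$pvalue)
  rownames(out) <- NULL
  out
}
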