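# Overlay of differential expression on a directed TF-target network:
# select dysregulated TFs, tabulate their altered direct targets, rank TFs
# by the number of altered targets, and intersect target lists across
# brain regions.

#' Select dysregulated transcription factors
#'
#' A TF (network node with out-degree >= 1) is selected iff it appears in
#' the differential table with `q < q_max` and `|log2fc| > lfc_min` (both
#' strict, so a log2 fold-change of exactly 1 is not selected).
#'
#' @param de differential-result data.frame (feature_id, log2fc, qvalue).
#' @param network a [regulatory_network()].
#' @param q_max FDR threshold (default 0.05).
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @return character vector of selected TF ids (sorted).
#' @export
select_dysregulated_tfs <- function(de, network, q_max = 0.05, lfc_min = 1) {
  check_diff_result(de)
  tfs <- network_tfs(network)
  absent <- setdiff(tfs, de$feature_id)
  if (length(absent)) {
    warning(length(absent), " TF(s) absent from the differential table: ",
            paste(head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ..." else "")
  }
  idx <- match(tfs, de$feature_id)
  ok <- !is.na(idx) &
    !is.na(de$qvalue[idx]) & de$qvalue[idx] < q_max &
    abs(de$log2fc[idx]) > lfc_min
  sort(tfs[ok])
}

#' Summarize the altered direct targets of one TF
#'
#' Targets are the TF's nearest downstream neighbors (direct
#' out-neighbors).  A target counts as altered iff its q-value is below
#' `target_q_max`, classified up/down by the sign of its log2 fold-change;
#' no fold-change threshold is applied to targets.  Targets missing from
#' the differential table count toward the total but are never altered.
#'
#' @param tf TF id (must have out-degree >= 1 in the network).
#' @param network a [regulatory_network()].
#' @param de differential-result data.frame.
#' @param target_q_max FDR threshold for target alteration (default 0.05).
#' @return one-row data.frame: tf_id, tf_log2fc, tf_qvalue,
#'   n_targets_total, n_altered, up_targets / down_targets
#'   (comma-collapsed, sorted).
#' @export
tf_target_summary <- function(tf, network, de, target_q_max = 0.05) {
  stopifnot(inherits(network, "regulatory_network"))
  check_diff_result(de)
  targets <- network$edges$target[network$edges$source == tf]
  if (!length(targets)) stop("'", tf, "' has no targets in the network")
  idx <- match(targets, de$feature_id)
  called <- !is.na(idx) & !is.na(de$qvalue[idx]) &
    de$qvalue[idx] < target_q_max
  up <- sort(targets[called & de$log2fc[idx] > 0])
  down <- sort(targets[called & de$log2fc[idx] < 0])
  ti <- match(tf, de$feature_id)
  data.frame(tf_id = tf,
             tf_log2fc = if (is.na(ti)) NA_real_ else de$log2fc[ti],
             tf_qvalue = if (is.na(ti)) NA_real_ else de$qvalue[ti],
             n_targets_total = length(targets),
             n_altered = length(up) + length(down),
             up_targets = paste(up, collapse = ","),
             down_targets = paste(down, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Summarize several TFs at once
#'
#' @param tfs character vector of TF ids; defaults to every TF in the
#'   network.
#' @inheritParams tf_target_summary
#' @return data.frame, one row per TF (see [tf_target_summary()]).
#' @export
tf_target_summaries <- function(network, de, tfs = NULL,
                                target_q_max = 0.05) {
  if (is.null(tfs)) tfs <- network_tfs(network)
  out <- do.call(rbind, lapply(tfs, tf_target_summary, network = network,
                               de = de, target_q_max = target_q_max))
  rownames(out) <- NULL
  out
}

#' Rank TFs by their number of altered targets
#'
#' Descending by `n_altered`, ties broken by descending altered/total
#' ratio, then lexicographic TF id.
#'
#' @param summaries data.frame from [tf_target_summaries()].
#' @param top_n how many TFs to return (default 4); values beyond the
#'   number of TFs return all of them.
#' @return character vector of TF ids, best first.
#' @export
rank_tfs_by_altered_targets <- function(summaries, top_n = 4) {
  stopifnot(all(c("tf_id", "n_altered", "n_targets_total") %in%
                  names(summaries)))
  ord <- order(-summaries$n_altered,
               -(summaries$n_altered / summaries$n_targets_total),
               summaries$tf_id)
  head(summaries$tf_id[ord], top_n)
}

#' Targets altered in the same direction in two regions
#'
#' Per TF present in both summaries: the intersection of the up lists
#' united with the intersection of the down lists.  A gene up in one
#' region and down in the other is not shared.
#'
#' @param summary1,summary2 data.frames from [tf_target_summaries()] for
#'   two brain regions.
#' @return data.frame: tf_id, shared_up, shared_down (comma-collapsed).
#' @export
cross_region_shared_targets <- function(summary1, summary2) {
  tfs <- intersect(summary1$tf_id, summary2$tf_id)
  split_list <- function(x) if (nzchar(x)) strsplit(x, ",")[[1]] else
    character(0)
  rows <- lapply(tfs, function(tf) {
    s1 <- summary1[summary1$tf_id == tf, ]
    s2 <- summary2[summary2$tf_id == tf, ]
    up <- intersect(split_list(s1$up_targets), split_list(s2$up_targets))
    dn <- intersect(split_list(s1$down_targets),
                    split_list(s2$down_targets))
    data.frame(tf_id = tf,
               shared_up = paste(sort(up), collapse = ","),
               shared_down = paste(sort(dn), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf_id = character(), shared_up = character(),
                      shared_down = character(), stringsAsFactors = FALSE)
  }
  out
}
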