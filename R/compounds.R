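# File-based connectivity-map-style query: which compounds place a chosen
# TF among the k most up- or down-regulated genes of their consensus
# signature, per cell context (NEU / NEU.KCL / NPC in the study design).

#' Consensus signature across replicates
#'
#' Each replicate vector is z-scored (mean 0, sd 1 over genes) and the
#' consensus is the per-gene median of the z-scored replicates; a single
#' replicate yields its z-scored self.  This is the package's
#' reproducibility rule: replicate disagreement shrinks a gene's consensus
#' toward zero instead of discarding the compound.
#'
#' @param replicates genes x replicates numeric matrix with gene rownames,
#'   or a list of identically named vectors.
#' @return named consensus score vector.
#' @export
consensus_signature <- function(replicates) {
  if (is.list(replicates) && !is.data.frame(replicates)) {
    gu <- names(replicates[[1]])
    for (r in replicates) {
      if (!identical(names(r), gu)) stop("replicate gene universes differ")
    }
    replicates <- do.call(cbind, replicates)
  }
  replicates <- as.matrix(replicates)
  if (is.null(rownames(replicates))) stop("replicates need gene rownames")
  z <- scale(replicates)
  if (any(attr(z, "scaled:scale") == 0)) {
    stop("constant replicate cannot be z-scored")
  }
  setNames(apply(z, 1, median), rownames(replicates))
}

#' Top-k membership of a gene in a signature
#'
#' Ranks genes by descending score for the "up" direction and ascending
#' for "down" (ties broken lexicographically by gene id); the gene is a
#' member iff its rank is at most k.  Requires `k < n_genes / 2` so the
#' two directions cannot overlap.
#'
#' @param signature named score vector.
#' @param gene gene id to look up.
#' @param k membership depth (default 100, the study's query depth).
#' @return list with `direction` (`"up"`, `"down"` or `"none"`), `rank_up`,
#'   `rank_down` and `n_genes`.
#' @export
top_k_membership <- function(signature, gene, k = 100) {
  n <- length(signature)
  if (k >= n / 2) stop("k must be < n_genes / 2")
  if (!gene %in% names(signature)) {
    stop("gene '", gene, "' not in the signature universe")
  }
  ids <- names(signature)
  rank_up <- which(ids[order(-signature, ids)] == gene)
  rank_down <- which(ids[order(signature, ids)] == gene)
  direction <- if (rank_up <= k) "up" else if (rank_down <= k) "down" else
    "none"
  list(direction = direction, rank_up = rank_up, rank_down = rank_down,
       n_genes = n)
}

# Vectorized consensus over a genes x compounds x replicates array:
# z-score every (compound, replicate) column over genes (n-1 sd, matching
# consensus_signature), then take the per-gene median across replicates.
consensus_matrix <- function(arr) {
  d <- dim(arr)
  n <- d[1]; R <- d[3]
  zs <- lapply(seq_len(R), function(r) {
    m <- arr[, , r, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = n)
    mu <- colMeans(m)
    s <- sqrt((colSums(m^2) - n * mu^2) / (n - 1))
    if (any(s == 0)) stop("constant replicate cannot be z-scored")
    sweep(sweep(m, 2, mu), 2, s, "/")
  })
  cons <- if (R == 1) zs[[1]]
  else if (R == 2) (zs[[1]] + zs[[2]]) / 2
  else if (R == 3) {
    zs[[1]] + zs[[2]] + zs[[3]] -
      pmax(zs[[1]], zs[[2]], zs[[3]]) - pmin(zs[[1]], zs[[2]], zs[[3]])
  } else {
    zarr <- array(unlist(zs), dim = d)
    apply(zarr, c(1, 2), median)
  }
  dimnames(cons) <- dimnames(arr)[1:2]
  cons
}

#' Query compounds that move a TF into the top-k of their signature
#'
#' For every (compound, context) the replicate signatures are collapsed by
#' [consensus_signature()] and the TF's membership among the k most up- or
#' down-regulated genes is tested; hits are emitted with their direction,
#' context and rank.  A compound may appear in several contexts.
#'
#' @param set a `compound_signature_set` (see
#'   [read_compound_signatures()] / [simulate_compound_signatures()]).
#' @param tf gene id of the transcription factor.
#' @param k membership depth (default 100).
#' @return data.frame: compound_id, context, direction, tf_rank, n_genes —
#'   one row per hit, sorted by context then compound.
#' @export
query_compounds <- function(set, tf, k = 100) {
  stopifnot(inherits(set, "compound_signature_set"))
  if (!tf %in% set$genes) stop("TF '", tf, "' not in the gene universe")
  n <- length(set$genes)
  if (k >= n / 2) stop("k must be < n_genes / 2")
  before_tf <- set$genes < tf          # lexicographic tie-break
  rows <- list()
  for (cx in set$contexts) {
    cons <- consensus_matrix(set$data[[cx]])
    stf <- cons[tf, ]
    for (ci in seq_along(set$compounds)) {
      s <- cons[, ci]
      tie_first <- sum(s == stf[ci] & before_tf)
      rank_up <- 1L + sum(s > stf[ci]) + tie_first
      rank_down <- 1L + sum(s < stf[ci]) + tie_first
      direction <- if (rank_up <= k) "up" else if (rank_down <= k) "down"
      else "none"
      if (direction != "none") {
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = set$compounds[ci], context = cx,
          direction = direction,
          tf_rank = if (direction == "up") rank_up else rank_down,
          n_genes = n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(compound_id = character(), context = character(),
                      direction = character(), tf_rank = integer(),
                      n_genes = integer(), stringsAsFactors = FALSE)
  }
  out[order(out$context, out$compound_id), , drop = FALSE]
}
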