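# Differential-count engine shared by the expression and methylation arms:
# median-of-ratios size factors, a negative-binomial Wald test with
# method-of-moments dispersion, BH FDR, and the low-expression filter.

#' Median-of-ratios size factors
#'
#' For every feature with all-positive counts, each sample's count is
#' divided by the feature's geometric mean across samples; the sample's
#' factor is the median of those ratios, rescaled so that the geometric
#' mean of the factors is 1.
#'
#' @param cm a [count_matrix()] or numeric matrix.
#' @param fallback_total use column totals when no feature is positive in
#'   every sample (default FALSE: such inputs are an error advising the
#'   flag).
#' @return numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(cm, fallback_total = FALSE) {
  sf <- size_factors_raw(cm, fallback_total)
  sf / exp(mean(log(sf)))                     # geometric mean 1
}

# Un-rescaled median-of-ratios factors.  The Wald test divides by these
# directly: scaling one sample's column then scales only that sample's
# factor, so the normalized matrix — and every downstream p-value — is
# exactly invariant.  (The geometric-mean-1 rescale used for reporting
# would instead spread a constant across all samples.)
size_factors_raw <- function(cm, fallback_total = FALSE) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    if (!fallback_total) {
      stop("no feature has positive counts in every sample; ",
           "use fallback_total = TRUE for total-count factors")
    }
    sf <- colSums(m) / mean(colSums(m))
    if (any(sf <= 0)) stop("sample with zero total count")
  } else {
    lg <- log(m[pos, , drop = FALSE])
    ref <- rowMeans(lg)                       # log geometric mean
    sf <- apply(exp(lg - ref), 2, median)
  }
  setNames(sf, colnames(m))
}

#' Normalize counts by size factors
#'
#' @param cm a [count_matrix()] or matrix.
#' @param size_factors optional precomputed factors; defaults to
#'   [size_factors_median_of_ratios()].
#' @return list with `matrix` (counts / factor per sample) and
#'   `size_factors`.
#' @export
normalize_counts <- function(cm, size_factors = NULL) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(m)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  list(matrix = sweep(m, 2, size_factors, "/"), size_factors = size_factors)
}

#' Negative-binomial Wald test for a two-group design
#'
#' Per feature, on median-of-ratios-normalized counts: the log2 fold-change
#' is `log2((mean_case + 0.5) / (mean_control + 0.5))`; the NB dispersion
#' is estimated by method-of-moments from within-group means and variances
#' and floored at 1e-8; the Wald statistic divides the log2 fold-change by
#' its delta-method standard error from the NB variance function
#' `v = m + a m^2`, with a two-sided p-value from the normal reference and
#' BH q-values over all tested features.
#'
#' By default the method-of-moments estimate pools the within-group moments
#' across all features into one common dispersion; `dispersion =
#' "per_feature"` estimates it per feature instead (noisier at small n, and
#' anticonservative under the null at n = 5 + 5).
#'
#' Features whose mean normalized count falls below `min_mean`, and all-zero
#' features, are reported with missing p/q (and excluded from the BH family).
#'
#' @param cm a [count_matrix()] with >= 2 samples per group.
#' @param min_mean normalized-mean threshold below which a feature is not
#'   tested (default 0: test everything).
#' @param dispersion `"pooled"` (common, default) or `"per_feature"`.
#' @return data.frame with columns feature_id, mean_count, log2fc, pvalue,
#'   qvalue; attribute `size_factors` and `dispersion` (the pooled
#'   estimate, or the per-feature vector).
#' @export
nb_wald_test <- function(cm, min_mean = 0,
                         dispersion = c("pooled", "per_feature")) {
  stopifnot(inherits(cm, "count_matrix"))
  dispersion <- match.arg(dispersion)
  is_case <- cm$groups == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  sf <- size_factors_raw(cm)
  m <- sweep(cm$counts, 2, sf, "/")
  m1 <- rowMeans(m[, is_case, drop = FALSE])
  m2 <- rowMeans(m[, !is_case, drop = FALSE])
  v1 <- apply(m[, is_case, drop = FALSE], 1, var)
  v2 <- apply(m[, !is_case, drop = FALSE], 1, var)
  vw <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mo <- (n1 * m1 + n2 * m2) / (n1 + n2)
  if (dispersion == "pooled") {
    use <- mo > 0
    alpha <- max((sum(vw[use] - mo[use])) / sum(mo[use]^2), 1e-8)
  } else {
    alpha <- ifelse(mo > 0, pmax((vw - mo) / mo^2, 1e-8), 1e-8)
  }
  log2fc <- log2((m1 + 0.5) / (m2 + 0.5))
  nbv <- function(mu) mu + alpha * mu^2
  se <- sqrt(nbv(m1) / (n1 * (m1 + 0.5)^2) +
               nbv(m2) / (n2 * (m2 + 0.5)^2)) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(z))
  mean_count <- rowMeans(m)
  untested <- (m1 == 0 & m2 == 0) | mean_count < min_mean
  p[untested] <- NA_real_
  out <- data.frame(feature_id = rownames(m),
                    mean_count = mean_count,
                    log2fc = log2fc,
                    pvalue = p,
                    qvalue = bh_fdr(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "size_factors") <- sf
  attr(out, "dispersion") <- alpha
  out
}

#' Benjamini-Hochberg step-up FDR
#'
#' `q_(i) = min_(j >= i)(p_(j) m / j)` capped at 1 and mapped back to the
#' input order.  Missing p-values pass through as missing and do not count
#' toward the family size m.  Delegates the step-up computation to
#' [stats::p.adjust()] on the non-missing subset.
#'
#' @param pvalues numeric vector in `[0, 1]`, NA allowed.
#' @return q-values in input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(pvalues) {
  check_pvalues(pvalues)
  q <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  q[ok] <- p.adjust(pvalues[ok], method = "BH")
  q
}

#' Filter features with low average raw counts
#'
#' Strict comparison on the raw-count scale: features with mean < `min_mean`
#' are removed; a mean of exactly `min_mean` is retained.
#'
#' @param x a [count_matrix()], or a data.frame with a `mean_count` column
#'   (e.g. from [nb_wald_test()]).
#' @param min_mean threshold (default 50, the mRNA read-number filter used
#'   before the regression stage).
#' @return the filtered object, same class as the input.
#' @export
filter_low_expression <- function(x, min_mean = 50) {
  if (inherits(x, "count_matrix")) {
    keep <- rowMeans(x$counts) >= min_mean
    return(count_matrix(x$counts[keep, , drop = FALSE], x$groups))
  }
  if (is.data.frame(x)) {
    if (!"mean_count" %in% names(x)) stop("data.frame needs mean_count")
    return(x[x$mean_count >= min_mean, , drop = FALSE])
  }
  stop("unsupported input for filter_low_expression")
}
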