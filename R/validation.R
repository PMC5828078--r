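# Small statistics used for laboratory validation: Mann-Whitney U (exact
# by enumeration at small n, normal approximation with tie correction
# otherwise), ddPCR reference-gene normalization with log2 fold-change,
# pyrosequencing percent methylation, and the Spearman marker-correlation
# check.

#' Mann-Whitney U test
#'
#' `U = #\{(i, j): x_i > y_j\} + 0.5 #ties`.  When `n_x + n_y <= 12` and
#' there are no ties across the pooled sample, the p-value is exact by
#' enumeration of all group assignments; otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @return list with `U`, `pvalue` and `method` ("exact" or "normal").
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$pvalue  # 0.1, exact
mann_whitney_u <- function(x, y, alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (nx + ny <= 12 && !ties) {
    # enumerate the null distribution of U over all C(n, nx) assignments
    combs <- combn(nx + ny, nx)
    rr <- rank(pooled)
    u_null <- apply(combs, 2, function(idx) {
      sum(rr[idx]) - nx * (nx + 1) / 2
    })
    p <- switch(alternative,
                two.sided = min(1, 2 * min(mean(u_null <= U),
                                           mean(u_null >= U))),
                greater = mean(u_null >= U),
                less = mean(u_null <= U))
    return(list(U = U, pvalue = p, method = "exact"))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  sigma2 <- nx * ny / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    p <- if (alternative == "two.sided") 1 else 0.5
    return(list(U = U, pvalue = p, method = "normal"))
  }
  sigma <- sqrt(sigma2)
  p <- if (alternative == "two.sided") {
    min(1, 2 * pnorm(-max(0, abs(U - mu) - 0.5) / sigma))
  } else {
    zc <- (U - mu - if (U >= mu) 0.5 else -0.5) / sigma
    if (alternative == "greater") pnorm(zc, lower.tail = FALSE) else
      pnorm(zc)
  }
  list(U = U, pvalue = p, method = "normal")
}

#' ddPCR reference-gene normalization and log2 fold-change
#'
#' Per sample the target concentration is divided by the reference-gene
#' concentration; the log2 fold-change is computed on the group means of
#' the normalized values (fold-change-of-means convention) and the p-value
#' comes from [mann_whitney_u()] on the normalized values.
#'
#' @param target_conc per-sample target concentrations (copies/ul).
#' @param ref_conc per-sample reference-gene concentrations (> 0).
#' @param groups per-sample `"case"` / `"control"` labels.
#' @return list with `log2fc`, `pvalue`, `normalized`.
#' @export
ddpcr_log2fc <- function(target_conc, ref_conc, groups) {
  if (length(target_conc) != length(ref_conc) ||
      length(target_conc) != length(groups)) {
    stop("target, reference and groups must have equal length")
  }
  if (any(ref_conc <= 0)) stop("reference concentrations must be > 0")
  if (!all(groups %in% c("case", "control"))) {
    stop("groups must be 'case'/'control'")
  }
  norm <- target_conc / ref_conc
  mw <- mann_whitney_u(norm[groups == "case"], norm[groups == "control"])
  list(log2fc = log2(mean(norm[groups == "case"]) /
                       mean(norm[groups == "control"])),
       pvalue = mw$pvalue, normalized = norm)
}

#' Pyrosequencing percent methylation
#'
#' By default the bounded percentage `100 * meth / (meth + unmeth)`;
#' `literal_ratio = TRUE` instead returns the unbounded literal ratio
#' `100 * meth / unmeth` (which can exceed 100).
#'
#' @param meth_signal,unmeth_signal non-negative signals, not both zero.
#' @param literal_ratio use the unbounded methylated/unmethylated ratio.
#' @return percentage(s).
#' @export
percent_methylation <- function(meth_signal, unmeth_signal,
                                literal_ratio = FALSE) {
  if (any(meth_signal < 0) || any(unmeth_signal < 0)) {
    stop("signals must be >= 0")
  }
  if (any(meth_signal + unmeth_signal == 0)) {
    stop("both signals zero: percentage undefined")
  }
  if (literal_ratio) {
    if (any(unmeth_signal == 0)) stop("literal ratio undefined at unmeth = 0")
    return(100 * meth_signal / unmeth_signal)
  }
  100 * meth_signal / (meth_signal + unmeth_signal)
}

#' Spearman correlation of TF counts against cell-type marker counts
#'
#' @param tf_counts,marker_counts per-sample normalized counts (n >= 4).
#' @return list with `r` (Spearman rho; NA for a constant vector) and
#'   `pvalue` (two-sided).
#' @export
marker_correlation <- function(tf_counts, marker_counts) {
  if (length(tf_counts) != length(marker_counts)) {
    stop("vectors must have equal length")
  }
  if (length(tf_counts) < 4) stop("need n >= 4 samples")
  if (sd(tf_counts) == 0 || sd(marker_counts) == 0) {
    return(list(r = NA_real_, pvalue = NA_real_))
  }
  ct <- suppressWarnings(cor.test(tf_counts, marker_counts,
                                  method = "spearman",
                                  alternative = "two.sided"))
  list(r = unname(ct$estimate), pvalue = ct$p.value)
}
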