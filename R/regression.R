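# Per-gene linear models linking methylation and expression:
# (a) expression ~ methylation, and (b) injury -> expression via
# methylation as a product-of-coefficients mediation with percentile
# bootstrap inference.  Inputs are log2(normalized count + 1) by default;
# genes below the average-raw-read filter are excluded before testing.

# Resolve expr/meth inputs into aligned numeric matrices on the model
# scale, plus the 0/1 group vector and the raw expression means used by
# the filter.
prepare_regression_input <- function(expr, meth, groups = NULL,
                                     transform = c("log2_normalized",
                                                   "identity")) {
  transform <- match.arg(transform)
  get_mat <- function(x) if (inherits(x, "count_matrix")) x$counts else
    as.matrix(x)
  em <- get_mat(expr); mm <- get_mat(meth)
  if (!setequal(colnames(em), colnames(mm))) {
    stop("expression and methylation matrices must share samples")
  }
  mm <- mm[, colnames(em), drop = FALSE]
  if (inherits(expr, "count_matrix")) {
    groups <- expr$groups
  } else if (is.null(groups)) {
    stop("groups must be supplied when expression is a plain matrix")
  } else {
    groups <- setNames(as.character(groups),
                       names(groups) %||% colnames(em))[colnames(em)]
  }
  raw_means <- rowMeans(em)
  if (transform == "log2_normalized") {
    em <- log2(normalize_counts(em)$matrix + 1)
    mm <- log2(normalize_counts(mm)$matrix + 1)
  }
  list(expr = em, meth = mm, g = as.numeric(groups == "case"),
       raw_means = raw_means)
}

# Default gene <-> region pairing through "gene|kind" region ids.
default_pairing <- function(gene_ids, region_ids, region_kind = "promoter") {
  rid <- paste0(gene_ids, "|", region_kind)
  keep <- rid %in% region_ids
  data.frame(gene_id = gene_ids[keep], region_id = rid[keep],
             stringsAsFactors = FALSE)
}

#' Per-gene regression of expression on methylation
#'
#' Ordinary least squares of `log2(normalized expression + 1)` on
#' `log2(normalized methylation + 1)` across samples, with a two-sided t
#' test on the slope and BH adjustment over all tested genes.  Genes whose
#' average raw expression count is below `min_mean` are filtered out before
#' testing; genes with zero-variance methylation are reported with missing
#' results.
#'
#' @param expr expression [count_matrix()].
#' @param meth methylation region [count_matrix()] (region ids
#'   `"gene|kind"`), sharing the expression samples.
#' @param pairing optional data.frame (gene_id, region_id); defaults to
#'   matching each gene to its `"gene|<region_kind>"` region.
#' @param region_kind region kind used by the default pairing.
#' @param min_mean average raw-read filter (default 50).
#' @param transform `"log2_normalized"` (default) or `"identity"` for
#'   pre-transformed matrices.
#' @param groups case/control labels; only needed when `expr` is a plain
#'   matrix rather than a [count_matrix()].
#' @return data.frame: gene_id, region_id, estimate (slope), se, ci_lo,
#'   ci_hi (95 percent, t-based), pvalue, qvalue.
#' @export
regress_methylation_on_expression <- function(expr, meth, pairing = NULL,
                                              region_kind = "promoter",
                                              min_mean = 50,
                                              transform = "log2_normalized",
                                              groups = NULL) {
  inp <- prepare_regression_input(expr, meth, groups, transform)
  n <- ncol(inp$expr)
  if (n < 3) stop("need at least 3 samples for regression")
  if (is.null(pairing)) {
    pairing <- default_pairing(rownames(inp$expr), rownames(inp$meth),
                               region_kind)
  }
  keep <- if (min_mean > 0) inp$raw_means[pairing$gene_id] >= min_mean else
    rep(TRUE, nrow(pairing))
  pairing <- pairing[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairing)), function(i) {
    y <- inp$expr[pairing$gene_id[i], ]
    x <- inp$meth[pairing$region_id[i], ]
    if (var(x) == 0) {
      return(data.frame(gene_id = pairing$gene_id[i],
                        region_id = pairing$region_id[i],
                        estimate = NA_real_, se = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        pvalue = NA_real_, stringsAsFactors = FALSE))
    }
    fit <- lm(y ~ x)
    co <- summary(fit)$coefficients
    est <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    p <- if (se == 0) 0 else co["x", "Pr(>|t|)"]
    tcrit <- stats::qt(0.975, df = n - 2)
    data.frame(gene_id = pairing$gene_id[i],
               region_id = pairing$region_id[i],
               estimate = est, se = se,
               ci_lo = est - tcrit * se, ci_hi = est + tcrit * se,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), region_id = character(),
                      estimate = numeric(), se = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE)
  }
  out$qvalue <- bh_fdr(out$pvalue)
  rownames(out) <- NULL
  out
}

# Per-gene bootstrap of the indirect effect; resamples within groups.
# Returns the bootstrap draws of a*b (NA where a resample is degenerate).
boot_indirect <- function(m, y, g, n_boot) {
  case <- which(g == 1); ctrl <- which(g == 0)
  n1 <- length(case); n2 <- length(ctrl); n <- n1 + n2
  I <- rbind(matrix(sample(case, n_boot * n1, replace = TRUE), n1),
             matrix(sample(ctrl, n_boot * n2, replace = TRUE), n2))
  gb <- c(rep(1, n1), rep(0, n2))
  M <- matrix(m[I], n); Y <- matrix(y[I], n)
  Sm <- colSums(M); Sy <- colSums(Y)
  Cmm <- colSums(M * M) - Sm^2 / n
  Cmg <- colSums(M[gb == 1, , drop = FALSE]) - Sm * n1 / n
  Cgg <- n1 - n1^2 / n
  Cmy <- colSums(M * Y) - Sm * Sy / n
  Cgy <- colSums(Y[gb == 1, , drop = FALSE]) - n1 * Sy / n
  det <- Cmm * Cgg - Cmg^2
  a <- Cmg / Cgg
  b <- (Cmy * Cgg - Cgy * Cmg) / det
  ind <- a * b
  ind[abs(det) < 1e-12] <- NA_real_
  ind
}

# Point estimates of the mediation decomposition for one gene.
mediation_point <- function(m, y, g) {
  n <- length(g); n1 <- sum(g == 1)
  Cmm <- sum(m * m) - sum(m)^2 / n
  Cmg <- sum(m[g == 1]) - sum(m) * n1 / n
  Cgg <- n1 - n1^2 / n
  Cmy <- sum(m * y) - sum(m) * sum(y) / n
  Cgy <- sum(y[g == 1]) - n1 * sum(y) / n
  det <- Cmm * Cgg - Cmg^2
  a <- Cmg / Cgg
  b <- (Cmy * Cgg - Cgy * Cmg) / det
  direct <- (Cgy * Cmm - Cmy * Cmg) / det
  list(a = a, b = b, direct = direct, indirect = a * b,
       total = Cgy / Cgg)
}

#' Mediation of the injury effect on expression through methylation
#'
#' Product-of-coefficients mediation per gene: stage 1 regresses
#' methylation on group (coefficient `a`), stage 2 regresses expression on
#' methylation and group (coefficients `b` and `direct`); the indirect
#' effect is `a * b`.  A percentile bootstrap (resampling samples within
#' groups, seed-deterministic) provides the 95 percent CI and a two-sided
#' p-value for the indirect effect, BH-adjusted over tested genes.
#'
#' @inheritParams regress_methylation_on_expression
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap stream.
#' @return data.frame: gene_id, region_id, a, b, direct, indirect, ci_lo,
#'   ci_hi, pvalue, qvalue.  OLS algebra guarantees
#'   `total group effect = direct + indirect` per gene.
#' @export
mediation_tbi_via_methylation <- function(expr, meth, pairing = NULL,
                                          region_kind = "promoter",
                                          min_mean = 50, n_boot = 2000,
                                          seed = 1,
                                          transform = "log2_normalized",
                                          groups = NULL) {
  inp <- prepare_regression_input(expr, meth, groups, transform)
  if (sum(inp$g == 1) < 3 || sum(inp$g == 0) < 3) {
    stop("each group needs at least 3 samples for mediation")
  }
  if (is.null(pairing)) {
    pairing <- default_pairing(rownames(inp$expr), rownames(inp$meth),
                               region_kind)
  }
  keep <- if (min_mean > 0) inp$raw_means[pairing$gene_id] >= min_mean else
    rep(TRUE, nrow(pairing))
  pairing <- pairing[keep, , drop = FALSE]
  set.seed(seed)
  res <- lapply(seq_len(nrow(pairing)), function(i) {
    y <- inp$expr[pairing$gene_id[i], ]
    m <- inp$meth[pairing$region_id[i], ]
    base <- data.frame(gene_id = pairing$gene_id[i],
                       region_id = pairing$region_id[i],
                       a = NA_real_, b = NA_real_, direct = NA_real_,
                       indirect = NA_real_, ci_lo = NA_real_,
                       ci_hi = NA_real_, pvalue = NA_real_,
                       stringsAsFactors = FALSE)
    if (var(m) == 0) return(base)
    pt <- mediation_point(m, y, inp$g)
    bo <- boot_indirect(m, y, inp$g, n_boot)
    bo <- bo[!is.na(bo)]
    if (!length(bo)) return(base)
    ci <- unname(quantile(bo, c(0.025, 0.975)))
    p <- 2 * min((1 + sum(bo <= 0)) / (1 + length(bo)),
                 (1 + sum(bo >= 0)) / (1 + length(bo)))
    base$a <- pt$a; base$b <- pt$b; base$direct <- pt$direct
    base$indirect <- pt$indirect
    base$ci_lo <- min(ci[1], pt$indirect)
    base$ci_hi <- max(ci[2], pt$indirect)
    base$pvalue <- min(p, 1)
    base
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), region_id = character(),
                      a = numeric(), b = numeric(), direct = numeric(),
                      indirect = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$qvalue <- bh_fdr(out$pvalue)
  rownames(out) <- NULL
  out
}
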