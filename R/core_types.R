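# Shared domain containers.  Coordinates are 0-based half-open everywhere
# inside the package; GTF (1-based inclusive) is converted on ingress and
# egress, BED passes through unchanged.

#' Construct a genomic interval table
#'
#' A light container for 0-based half-open intervals.  Used for promoter /
#' exon / gene-body windows rather than a full GRanges because the pipeline
#' only ever needs integer arithmetic on one synthetic or real chromosome;
#' conversion helpers to [IRanges::IRanges] exist where overlap machinery is
#' required.
#'
#' @param chrom character chromosome name(s).
#' @param start 0-based inclusive start(s).
#' @param end 0-based exclusive end(s); must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @return a `data.frame` with columns chrom, start, end, strand.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  out <- data.frame(chrom = rep_len(as.character(chrom), n),
                    start = rep_len(as.numeric(start), n),
                    end = rep_len(as.numeric(end), n),
                    strand = rep_len(as.character(strand), n),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0)) stop("interval start must be >= 0")
  if (any(out$start >= out$end)) stop("interval requires start < end")
  if (!all(out$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  out
}

#' Construct a gene annotation object
#'
#' Holds per-gene body spans and exons in 0-based half-open coordinates.
#' Invariants enforced: unique gene ids; TSS equals body start on the plus
#' strand and `body end - 1` on the minus strand; exons lie within the body
#' and are merged if overlapping.
#'
#' @param genes data.frame with columns gene_id, chrom, strand ('+'/'-'),
#'   start, end (0-based half-open body span).  A tss column is derived.
#' @param exons data.frame with columns gene_id, start, end; may be empty.
#' @return an object of class `gene_annotation` with elements `genes`
#'   (incl. derived `tss`) and `exons` (overlaps merged, sorted).
#' @export
gene_annotation <- function(genes, exons = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  if (any(genes$start < 0 | genes$start >= genes$end)) {
    stop("gene body requires 0 <= start < end")
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  if (is.null(exons) || nrow(exons) == 0L) {
    exons <- data.frame(gene_id = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE)
  } else {
    exons <- as.data.frame(exons, stringsAsFactors = FALSE)
    exons$gene_id <- as.character(exons$gene_id)
    if (!all(exons$gene_id %in% genes$gene_id)) {
      stop("exon refers to unknown gene_id")
    }
    exons <- merge_exons(exons)
    gi <- match(exons$gene_id, genes$gene_id)
    if (any(exons$start < genes$start[gi] | exons$end > genes$end[gi])) {
      stop("exon outside its gene body span")
    }
  }
  structure(list(genes = genes[order(genes$gene_id), , drop = FALSE],
                 exons = exons),
            class = "gene_annotation")
}

# Merge overlapping/adjacent-overlap exons per gene; sort by gene then start.
merge_exons <- function(exons) {
  if (nrow(exons) == 0L) return(exons)
  pieces <- lapply(split(exons, exons$gene_id), function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    s <- df$start; e <- df$end
    ks <- s[1]; ke <- e[1]; os <- c(); oe <- c()
    for (i in seq_len(nrow(df))[-1]) {
      if (s[i] < ke) {           # overlap (half-open: touching is disjoint)
        ke <- max(ke, e[i])
      } else {
        os <- c(os, ks); oe <- c(oe, ke); ks <- s[i]; ke <- e[i]
      }
    }
    os <- c(os, ks); oe <- c(oe, ke)
    data.frame(gene_id = df$gene_id[1], start = os, end = oe,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$gene_id, out$start), , drop = FALSE]
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,",
      nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Construct a count matrix with group labels
#'
#' Non-negative integer counts, features in rows and samples in columns,
#' with a two-level case/control label per sample.  Expression (gene level)
#' and methylation (region level) arms share this container.
#'
#' @param counts integer matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param groups named character vector (or factor) mapping every sample id
#'   to `"case"` or `"control"`.
#' @return an object of class `count_matrix` with elements `counts` and
#'   `groups` (character, aligned with `colnames(counts)`).
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (!is.numeric(counts) || any(is.na(counts))) {
    stop("counts must be numeric and non-missing")
  }
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"   # exact for counts < 2^53
  groups <- setNames(as.character(groups), names(groups))
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts)) {
      stop("unnamed groups must match the number of samples")
    }
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing)) {
    stop("samples missing from groups: ", paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(counts)]
  if (!all(groups %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control' (two-level design only)")
  }
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples (", sum(x$groups == "case"), "case /",
      sum(x$groups == "control"), "control )\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a directed regulatory network
#'
#' @param edges data.frame with character columns `source` (TF) and
#'   `target`.  Parallel duplicate edges are collapsed; self-loops are kept
#'   and flagged in the `self_loop` column.
#' @return object of class `regulatory_network` wrapping the edge table.
#' @export
regulatory_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target)) ||
      any(is.na(edges$source)) || any(is.na(edges$target))) {
    stop("edge with missing endpoint")
  }
  edges <- unique(edges[, c("source", "target")])
  edges$self_loop <- edges$source == edges$target
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", nrow(x$edges), "edges,",
      length(unique(x$edges$source)), "TFs,",
      sum(x$edges$self_loop), "self-loop(s)\n")
  invisible(x)
}

#' List the transcription factors of a network
#'
#' TFs are defined as nodes with out-degree >= 1.
#'
#' @param network a [regulatory_network()].
#' @return character vector of TF ids.
#' @export
network_tfs <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  sort(unique(network$edges$source))
}

# Internal: check a differential-result table (the DiffResult contract).
check_diff_result <- function(de) {
  stopifnot(is.data.frame(de),
            all(c("feature_id", "log2fc", "pvalue", "qvalue") %in% names(de)))
  if (anyDuplicated(de$feature_id)) stop("duplicate feature_id in results")
  check_pvalues(de$pvalue)
  check_pvalues(de$qvalue)
  invisible(de)
}
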