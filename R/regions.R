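# Promoter / exon / gene-body window construction and aggregation of
# per-base positions into region-level counts.  Promoter defaults follow
# the study design: 5000 bp upstream and 200 bp downstream of the TSS,
# strand-aware.  Intervals are half-open; the TSS base itself belongs to
# the downstream side.

#' Strand-aware promoter window around a TSS
#'
#' Plus strand: `[tss - upstream, tss + downstream)`; minus strand mirrors
#' the same rule around the TSS base: `[tss - downstream + 1,
#' tss + upstream + 1)`.  The window is clipped to `[0, chrom_length)`.
#'
#' @param tss 0-based TSS position(s).
#' @param strand `"+"` or `"-"`, recycled.
#' @param upstream,downstream window extents in bp (defaults 5000 / 200).
#' @param chrom_length chromosome length for clipping; `Inf` leaves the
#'   right edge unclipped.
#' @param chrom chromosome name(s) recorded in the output.
#' @return a genomic-interval data.frame (see [genomic_interval()]).
#' @export
#' @examples
#' promoter_window(10000, "+")  # [5000, 10200)
promoter_window <- function(tss, strand, upstream = 5000, downstream = 200,
                            chrom_length = Inf, chrom = "chr") {
  if (upstream < 0 || downstream < 0) stop("window extents must be >= 0")
  if (upstream == 0 && downstream == 0) stop("window cannot be empty")
  n <- max(length(tss), length(strand))
  tss <- rep_len(as.numeric(tss), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  s <- ifelse(strand == "+", tss - upstream, tss - downstream + 1)
  e <- ifelse(strand == "+", tss + downstream, tss + upstream + 1)
  cs <- pmax(s, 0)
  ce <- pmin(e, chrom_length)
  if (any(ce <= 0 | cs >= chrom_length | cs >= ce)) {
    stop("promoter window entirely outside the chromosome")
  }
  genomic_interval(rep_len(chrom, n), cs, ce, strand)
}

#' Build promoter, merged-exon and gene-body regions for each gene
#'
#' Per gene: one single-interval promoter region, one body region (the
#' annotated span) and one merged-exon region (possibly multiple
#' intervals).  Genes without exons get no exon region (with a warning).
#' Region ids follow the `"geneId|kind"` convention shared with the
#' synthetic generator and the methylation gene-set builder.
#'
#' @param annotation a [gene_annotation()].
#' @param upstream,downstream promoter extents (defaults 5000 / 200).
#' @param chrom_length chromosome length for promoter clipping.
#' @return an object of class `region_set`: list with `regions`
#'   (region_id, gene_id, kind) and `intervals` (one row per interval).
#' @export
gene_region_set <- function(annotation, upstream = 5000, downstream = 200,
                            chrom_length = Inf) {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  prom <- promoter_window(g$tss, g$strand, upstream, downstream,
                          chrom_length, g$chrom)
  iv <- rbind(
    data.frame(region_id = paste0(g$gene_id, "|promoter"),
               gene_id = g$gene_id, kind = "promoter",
               chrom = prom$chrom, start = prom$start, end = prom$end,
               strand = g$strand, stringsAsFactors = FALSE),
    data.frame(region_id = paste0(g$gene_id, "|body"),
               gene_id = g$gene_id, kind = "body",
               chrom = g$chrom, start = g$start, end = g$end,
               strand = g$strand, stringsAsFactors = FALSE))
  e <- annotation$exons
  no_exon <- setdiff(g$gene_id, unique(e$gene_id))
  if (length(no_exon)) {
    warning("no exons for gene(s): ", paste(no_exon, collapse = ", "),
            "; exon region omitted")
  }
  if (nrow(e)) {
    gi <- match(e$gene_id, g$gene_id)
    iv <- rbind(iv, data.frame(
      region_id = paste0(e$gene_id, "|exon"),
      gene_id = e$gene_id, kind = "exon",
      chrom = g$chrom[gi], start = e$start, end = e$end,
      strand = g$strand[gi], stringsAsFactors = FALSE))
  }
  iv <- iv[order(iv$region_id, iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  regions <- unique(iv[, c("region_id", "gene_id", "kind")])
  rownames(regions) <- NULL
  structure(list(regions = regions, intervals = iv), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", nrow(x$regions), "regions (",
      paste(names(table(x$regions$kind)), table(x$regions$kind),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Count per-sample positions falling in each region
#'
#' Each position (a 0-based bp, e.g. a read start) contributes one count to
#' every region whose interval union contains it.  The overlap join runs
#' through [IRanges::findOverlaps()].
#'
#' @param positions named list, one integer vector of 0-based positions per
#'   sample; names become sample ids.
#' @param regions a `region_set` from [gene_region_set()].
#' @param groups optional named case/control labels for the samples; when
#'   supplied a [count_matrix()] is returned, otherwise a plain matrix.
#' @return a [count_matrix()] (or matrix) with one row per region id.
#' @export
count_positions_in_regions <- function(positions, regions, groups = NULL) {
  stopifnot(inherits(regions, "region_set"), is.list(positions))
  if (is.null(names(positions))) {
    names(positions) <- paste0("s", seq_along(positions))
  }
  iv <- regions$intervals
  ir <- IRanges::IRanges(start = as.integer(iv$start) + 1L,
                         end = as.integer(iv$end))
  rid <- regions$regions$region_id
  counts <- matrix(0, nrow = length(rid), ncol = length(positions),
                   dimnames = list(rid, names(positions)))
  for (j in seq_along(positions)) {
    pos <- as.integer(positions[[j]])
    if (!length(pos)) next
    hits <- IRanges::findOverlaps(IRanges::IRanges(pos + 1L, width = 1L), ir)
    if (length(hits)) {
      tab <- table(iv$region_id[S4Vectors::subjectHits(hits)])
      counts[names(tab), j] <- counts[names(tab), j] + as.numeric(tab)
    }
  }
  if (is.null(groups)) return(counts)
  count_matrix(counts, groups)
}
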