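# Readers and writers for every external format the pipeline touches:
# GTF (Ensembl dialect) / BED12 annotation, TSV count matrices + groups,
# GMT gene sets, RNK ranked lists, TSV/SIF edge lists, per-context compound
# signature TSVs.  All writers emit UTF-8, LF, tab-separated text with a
# deterministic row order.

#' Read gene annotation from GTF or BED12
#'
#' GTF coordinates (1-based inclusive) are converted to the package's
#' internal 0-based half-open convention; BED12 is already 0-based and
#' passes through.  For GTF, `gene` features define the body span and
#' `exon` features the exons; a gene id seen only in exon records gets the
#' exon span as its body.  The TSS is the 5'-most base: body start on the
#' plus strand, `body end - 1` on the minus strand.
#'
#' @param path path to a `.gtf`/`.gff` or `.bed` file.
#' @param format `"auto"` (from extension), `"gtf"` or `"bed"`.
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  if (format == "gtf") {
    check_gtf_lines(path)
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    if (is.null(md$gene_id)) stop("GTF records lack gene_id attributes")
    type <- as.character(md$type)
    gid <- as.character(md$gene_id)
    is_gene <- type == "gene"
    is_exon <- type == "exon"
    if (any(duplicated(gid[is_gene]))) {
      stop("duplicate gene_id among GTF gene records: ",
           paste(unique(gid[is_gene][duplicated(gid[is_gene])]),
                 collapse = ", "))
    }
    gdf <- data.frame(
      gene_id = gid[is_gene],
      chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
      strand = as.character(GenomicRanges::strand(gr))[is_gene],
      start = GenomicRanges::start(gr)[is_gene] - 1,
      end = GenomicRanges::end(gr)[is_gene],
      stringsAsFactors = FALSE)
    edf <- data.frame(
      gene_id = gid[is_exon],
      start = GenomicRanges::start(gr)[is_exon] - 1,
      end = GenomicRanges::end(gr)[is_exon],
      stringsAsFactors = FALSE)
    orphan <- setdiff(edf$gene_id, gdf$gene_id)
    if (length(orphan)) {   # derive body from exon span
      for (g in orphan) {
        idx <- which(is_exon & gid == g)
        gdf <- rbind(gdf, data.frame(
          gene_id = g,
          chrom = as.character(GenomicRanges::seqnames(gr))[idx[1]],
          strand = as.character(GenomicRanges::strand(gr))[idx[1]],
          start = min(GenomicRanges::start(gr)[idx]) - 1,
          end = max(GenomicRanges::end(gr)[idx]),
          stringsAsFactors = FALSE))
      }
    }
    gene_annotation(gdf, edf)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$name)) stop("BED records need a name column (gene id)")
    gdf <- data.frame(
      gene_id = as.character(gr$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
    if (any(gdf$strand == "*")) stop("BED records must be stranded")
    edf <- NULL
    if (!is.null(gr$blocks)) {
      bl <- gr$blocks
      edf <- data.frame(
        gene_id = rep(gdf$gene_id, lengths(bl)),
        start = unlist(IRanges::start(bl)) - 1,
        end = unlist(IRanges::end(bl)),
        stringsAsFactors = FALSE)
    }
    gene_annotation(gdf, edf)
  }
}

# Cheap structural scan so malformed GTF lines are reported with a line
# number before handing the file to the importer.
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf < 9]
  if (length(bad)) {
    stop("malformed GTF line ", bad[1], ": expected 9 tab-separated fields")
  }
  invisible(TRUE)
}

#' Write gene annotation as GTF
#'
#' Emits one `gene` record per gene and one `exon` record per exon,
#' converting internal 0-based half-open coordinates back to the 1-based
#' inclusive GTF convention, so that read/write round-trips are identities.
#'
#' @param annotation a [gene_annotation()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  e <- annotation$exons
  fmt <- function(chrom, type, s0, e0, strand, gid) {
    sprintf("%s\tmethyltrx\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            chrom, type, as.integer(s0) + 1L, as.integer(e0), strand, gid)
  }
  lines <- fmt(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id)
  if (nrow(e)) {
    gi <- match(e$gene_id, g$gene_id)
    lines <- c(lines, fmt(g$chrom[gi], "exon", e$start, e$end,
                          g$strand[gi], e$gene_id))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a count matrix and its group labels
#'
#' The matrix TSV has feature ids in the first column and sample ids in the
#' header; the groups TSV has columns `sample` and `group` mapping every
#' sample to `case` or `control`.  Cells must parse as non-negative
#' integers.
#'
#' @param path count matrix TSV.
#' @param groups_path sample-to-group TSV.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, groups_path) {
  df <- read_tsv_plain(path)
  if (ncol(df) < 2L) stop("count matrix needs a feature column and samples")
  feats <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in count matrix")
  if (any(is.na(m))) stop("missing cell in count matrix")
  if (any(m < 0)) stop("negative cell in count matrix")
  if (any(m != round(m))) stop("non-integer cell in count matrix")
  rownames(m) <- feats
  gdf <- read_tsv_plain(groups_path)
  if (!all(c("sample", "group") %in% names(gdf))) {
    stop("groups file needs 'sample' and 'group' columns")
  }
  groups <- setNames(as.character(gdf$group), as.character(gdf$sample))
  count_matrix(m, groups)
}

#' Write a count matrix (and optionally its groups) as TSV
#'
#' @param cm a [count_matrix()].
#' @param path output TSV for the counts.
#' @param groups_path optional output TSV for the sample-to-group map.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, groups_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(feature_id = rownames(cm$counts),
                   cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  if (!is.null(groups_path)) {
    write_tsv_plain(data.frame(sample = names(cm$groups),
                               group = unname(cm$groups),
                               stringsAsFactors = FALSE), groups_path)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: per line a set name, a description, and tab-separated
#' members.  Duplicate members within a set are deduplicated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      stop("GMT line ", i, ": need name, description and >= 1 member")
    }
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], unique(sets[[i]])),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a directed TF-target edge list (two-column TSV or SIF)
#'
#' Two tab-separated columns are read as source/target; three columns are
#' treated as SIF (source, interaction, target).  A header line named
#' source/target is tolerated.
#'
#' @param path edge-list file.
#' @return a [regulatory_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[\t ]+")
  if (length(parts) &&
      identical(tolower(parts[[1]][1:2]), c("source", "target"))) {
    parts <- parts[-1]
  }
  src <- character(length(parts)); tgt <- character(length(parts))
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) == 2L) { src[i] <- f[1]; tgt[i] <- f[2] }
    else if (length(f) >= 3L) { src[i] <- f[1]; tgt[i] <- f[3] }
    else stop("edge line ", i, ": missing endpoint")
    if (!nzchar(src[i]) || !nzchar(tgt[i])) {
      stop("edge line ", i, ": missing endpoint")
    }
  }
  regulatory_network(data.frame(source = src, target = tgt,
                                stringsAsFactors = FALSE))
}

#' Write a regulatory network as two-column TSV
#' @param network a [regulatory_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  write_tsv_plain(network$edges[, c("source", "target")], path)
}

#' Write a ranked list as a two-column RNK file
#' @param ranked data.frame with columns `gene_id` and `score`
#'   (see [build_ranked_list()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(all(c("gene_id", "score") %in% names(ranked)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%.10g", ranked$gene_id, ranked$score), con,
             sep = "\n")
  invisible(path)
}

#' Read a two-column RNK file into a ranked list
#' @param path RNK file (gene, score).
#' @return data.frame with columns gene_id, score ordered by descending
#'   score (ties by gene id).
#' @export
read_rnk <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", "score")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene id in RNK file")
  df <- df[order(-df$score, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export a region set as BED
#'
#' One BED line per interval with the region id in the name column.
#' BED is natively 0-based half-open, so coordinates pass through.
#'
#' @param regions a region set from [gene_region_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
regions_to_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  df <- regions$intervals
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", df$chrom,
                   as.integer(df$start), as.integer(df$end),
                   df$region_id, df$strand)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read compound signature TSVs from a directory
#'
#' Expects one genes-by-compounds TSV per (context, replicate) named
#' `<context>_<replicate>.tsv`; the context may itself contain dots
#' (e.g. `NEU.KCL_2.tsv`).  All files must share the same gene universe
#' and compound set.
#'
#' @param dir directory of signature TSVs.
#' @return a `compound_signature_set`: list with `genes`, `contexts`,
#'   `compounds` and `data` (per context a genes x compounds x replicates
#'   array).
#' @export
read_compound_signatures <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no signature TSVs found in ", dir)
  base <- sub("\\.tsv$", "", basename(files))
  ctx <- sub("_[^_]+$", "", base)
  rep_id <- sub("^.*_", "", base)
  mats <- lapply(files, function(f) {
    df <- read_tsv_plain(f)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
  })
  genes <- rownames(mats[[1]])
  cmpds <- colnames(mats[[1]])
  for (m in mats) {
    if (!identical(rownames(m), genes) || !identical(colnames(m), cmpds)) {
      stop("signature files disagree on gene universe or compound set")
    }
  }
  data <- list()
  for (cx in unique(ctx)) {
    idx <- which(ctx == cx)
    arr <- array(NA_real_, dim = c(length(genes), length(cmpds), length(idx)),
                 dimnames = list(genes, cmpds, rep_id[idx]))
    for (j in seq_along(idx)) arr[, , j] <- mats[[idx[j]]]
    data[[cx]] <- arr
  }
  structure(list(genes = genes, contexts = sort(unique(ctx)),
                 compounds = cmpds, data = data),
            class = "compound_signature_set")
}

#' Write a compound signature set to a directory of TSVs
#' @param set a `compound_signature_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_compound_signatures <- function(set, dir) {
  stopifnot(inherits(set, "compound_signature_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cx in names(set$data)) {
    arr <- set$data[[cx]]
    for (r in seq_len(dim(arr)[3])) {
      df <- data.frame(gene_id = set$genes, arr[, , r],
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv_plain(df, file.path(dir, sprintf("%s_%d.tsv", cx, r)))
    }
  }
  invisible(dir)
}

#' @export
print.compound_signature_set <- function(x, ...) {
  cat("compound_signature_set:", length(x$genes), "genes,",
      length(x$compounds), "compounds,",
      length(x$contexts), "contexts\n")
  invisible(x)
}
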