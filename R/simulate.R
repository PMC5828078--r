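# Synthetic-data generator with planted, recoverable structure emulating
# the study design: two groups of 5 samples, negative-binomial counts, a
# minority of genes with planted log2 fold-changes, promoter
# hypermethylation optionally anti-coupled to expression, TF regulons with
# a stated altered fraction, and compound signatures with planted top-rank
# hits.  All generators are seed-deterministic; every stochastic component
# draws from a sub-seed fanned out by stage_seed().

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: 2000 genes, 5 injured vs
#' 5 sham samples, negative-binomial dispersion 0.1, 10 percent of genes
#' differentially expressed at |log2FC| 1.5, 5 percent of promoters
#' hypermethylated at log2FC 1.5 and anti-coupled to expression, 4 planted
#' TFs (log2FC 2) with 50-gene regulons of which 30 percent are altered
#' against 16 background TFs at 2 percent, and 200 compounds across the
#' NEU / NEU.KCL / NPC contexts with 5 planted hits at effect size 10.
#'
#' Under anti-coupling the hypermethylated promoters' genes are forced into
#' the downregulated part of the DE set, so planted TFs, altered regulon
#' targets and coupled genes all draw from the `frac_de` budget; the
#' configuration is rejected when the budget or the gene count cannot
#' accommodate them.
#'
#' @param seed integer seed (mandatory).
#' @param n_genes,n_case,n_control design sizes.
#' @param nb_dispersion NB dispersion (scalar or per-feature).
#' @param baseline_mean_expr,baseline_mean_meth median baseline counts for
#'   the expression and methylation arms.
#' @param library_size_factors optional fixed per-sample factors; `NULL`
#'   draws mild lognormal factors per arm.
#' @param frac_de,lfc_de fraction and |log2FC| of DE genes.
#' @param frac_dm_promoter,lfc_dm fraction and log2FC of hypermethylated
#'   promoters.
#' @param coupling `"anti"` (hypermethylated promoter implies
#'   downregulated gene) or `"none"`.
#' @param n_tfs,regulon_size,frac_regulon_altered,tf_lfc planted TF layer.
#' @param n_null_tfs,frac_regulon_altered_null background TF layer.
#' @param n_compounds,cell_contexts,n_replicates_per_signature,
#'   compound_effect_size,n_hit_compounds compound-signature layer.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 2000, n_case = 5, n_control = 5,
                              nb_dispersion = 0.1,
                              baseline_mean_expr = 200,
                              baseline_mean_meth = 100,
                              library_size_factors = NULL,
                              frac_de = 0.1, lfc_de = 1.5,
                              frac_dm_promoter = 0.05, lfc_dm = 1.5,
                              coupling = c("anti", "none"),
                              n_tfs = 4, regulon_size = 50,
                              frac_regulon_altered = 0.3, tf_lfc = 2,
                              n_null_tfs = 16,
                              frac_regulon_altered_null = 0.02,
                              n_compounds = 200,
                              cell_contexts = c("NEU", "NEU.KCL", "NPC"),
                              n_replicates_per_signature = 3,
                              compound_effect_size = 10,
                              n_hit_compounds = 5) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  coupling <- match.arg(coupling)
  fr <- c(frac_de, frac_dm_promoter, frac_regulon_altered,
          frac_regulon_altered_null)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (n_genes < 1 || n_case < 1 || n_control < 1) {
    stop("sizes must be positive")
  }
  cfg <- list(seed = as.integer(seed), n_genes = n_genes, n_case = n_case,
              n_control = n_control, nb_dispersion = nb_dispersion,
              baseline_mean_expr = baseline_mean_expr,
              baseline_mean_meth = baseline_mean_meth,
              library_size_factors = library_size_factors,
              frac_de = frac_de, lfc_de = lfc_de,
              frac_dm_promoter = frac_dm_promoter, lfc_dm = lfc_dm,
              coupling = coupling, n_tfs = n_tfs,
              regulon_size = regulon_size,
              frac_regulon_altered = frac_regulon_altered, tf_lfc = tf_lfc,
              n_null_tfs = n_null_tfs,
              frac_regulon_altered_null = frac_regulon_altered_null,
              n_compounds = n_compounds, cell_contexts = cell_contexts,
              n_replicates_per_signature = n_replicates_per_signature,
              compound_effect_size = compound_effect_size,
              n_hit_compounds = n_hit_compounds)
  m_de <- round(frac_de * n_genes)
  m_dm <- round(frac_dm_promoter * n_genes)
  if (coupling == "anti" && m_dm > m_de) {
    stop("coupling = 'anti' needs frac_dm_promoter <= frac_de")
  }
  n_tf_all <- n_tfs + n_null_tfs
  k_alt <- round(frac_regulon_altered * regulon_size)
  k_alt_null <- round(frac_regulon_altered_null * regulon_size)
  planted <- n_tfs + n_tfs * k_alt + n_null_tfs * k_alt_null +
    if (coupling == "anti") m_dm else 0
  if (n_tf_all > 0 && m_de > 0 && planted > m_de) {
    stop("DE budget round(frac_de * n_genes) = ", m_de,
         " too small for planted TFs, altered targets and coupled genes (",
         planted, ")")
  }
  if (n_tf_all * (1 + regulon_size) > n_genes) {
    stop("n_genes too small for the requested TF regulons")
  }
  structure(cfg, class = "simulation_config")
}

gene_ids_for <- function(n) sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))

#' Draw the planted truth for one simulated dataset
#'
#' Allocates DE genes, hypermethylated promoters (anti-coupled if
#' requested), planted and background TF regulons with their altered
#' target subsets, and the intended compound hits.  The DE set has exactly
#' `round(frac_de * n_genes)` members.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_truth`: `de_genes` (gene_id, lfc),
#'   `dm_promoters` (gene_id, lfc), `coupled_pairs`, `tf_table` (tf_id,
#'   planted, lfc), `regulons` (tf_id, target, altered, lfc),
#'   `compound_hits` (compound_id, context, tf_id, direction).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "truth"))
  genes <- gene_ids_for(config$n_genes)
  m_de <- round(config$frac_de * config$n_genes)
  m_dm <- round(config$frac_dm_promoter * config$n_genes)
  n_tf_all <- config$n_tfs + config$n_null_tfs
  k_alt <- round(config$frac_regulon_altered * config$regulon_size)
  k_alt_null <- round(config$frac_regulon_altered_null *
                        config$regulon_size)

  tf_ids <- if (n_tf_all > 0) sample(genes, n_tf_all) else character(0)
  planted_tfs <- tf_ids[seq_len(config$n_tfs)]
  null_tfs <- setdiff(tf_ids, planted_tfs)
  pool <- setdiff(genes, tf_ids)
  regulons <- NULL
  if (n_tf_all > 0 && config$regulon_size > 0) {
    tgt <- sample(pool, n_tf_all * config$regulon_size)
    regulons <- data.frame(
      tf_id = rep(tf_ids, each = config$regulon_size),
      target = tgt, altered = FALSE, lfc = 0, stringsAsFactors = FALSE)
    for (tf in tf_ids) {
      k <- if (tf %in% planted_tfs) k_alt else k_alt_null
      if (k > 0) {
        rows <- which(regulons$tf_id == tf)[seq_len(k)]
        regulons$altered[rows] <- TRUE
        regulons$lfc[rows] <- sample(c(-1, 1), k, replace = TRUE) *
          abs(config$lfc_de)
      }
    }
  } else {
    regulons <- data.frame(tf_id = character(), target = character(),
                           altered = logical(), lfc = numeric(),
                           stringsAsFactors = FALSE)
  }
  altered_targets <- regulons[regulons$altered, , drop = FALSE]

  avail <- setdiff(genes, c(tf_ids, altered_targets$target))
  if (config$coupling == "anti") {
    dm_genes <- if (m_dm > 0) sample(avail, m_dm) else character(0)
    avail <- setdiff(avail, dm_genes)
  } else {
    dm_genes <- if (m_dm > 0) sample(genes, m_dm) else character(0)
  }

  de <- data.frame(gene_id = character(), lfc = numeric(),
                   stringsAsFactors = FALSE)
  if (m_de > 0) {
    de <- rbind(
      if (length(planted_tfs)) data.frame(gene_id = planted_tfs,
                                          lfc = config$tf_lfc,
                                          stringsAsFactors = FALSE),
      if (nrow(altered_targets)) data.frame(
        gene_id = altered_targets$target, lfc = altered_targets$lfc,
        stringsAsFactors = FALSE),
      if (config$coupling == "anti" && length(dm_genes)) data.frame(
        gene_id = dm_genes, lfc = -abs(config$lfc_de),
        stringsAsFactors = FALSE))
    n_rest <- m_de - NROW(de)
    if (n_rest > 0) {
      rest <- sample(setdiff(avail, de$gene_id), n_rest)
      de <- rbind(de, data.frame(
        gene_id = rest,
        lfc = sample(c(-1, 1), n_rest, replace = TRUE) * abs(config$lfc_de),
        stringsAsFactors = FALSE))
    }
  }

  dm <- data.frame(gene_id = dm_genes,
                   lfc = rep(abs(config$lfc_dm), length(dm_genes)),
                   stringsAsFactors = FALSE)
  coupled <- if (config$coupling == "anti") dm_genes else character(0)

  hits <- data.frame(compound_id = character(), context = character(),
                     tf_id = character(), direction = character(),
                     stringsAsFactors = FALSE)
  if (config$n_hit_compounds > 0 && length(planted_tfs)) {
    cmpds <- sprintf("cmpd%03d", seq_len(config$n_compounds))
    hit_cmpds <- sample(cmpds, config$n_hit_compounds)
    hits <- data.frame(
      compound_id = hit_cmpds,
      context = rep_len(config$cell_contexts, config$n_hit_compounds),
      tf_id = rep_len(planted_tfs, config$n_hit_compounds),
      direction = rep_len(c("up", "down"), config$n_hit_compounds),
      stringsAsFactors = FALSE)
  }

  structure(list(
    gene_ids = genes,
    de_genes = de[order(de$gene_id), , drop = FALSE],
    dm_promoters = dm[order(dm$gene_id), , drop = FALSE],
    coupled_pairs = sort(coupled),
    tf_table = data.frame(tf_id = tf_ids,
                          planted = tf_ids %in% planted_tfs,
                          lfc = ifelse(tf_ids %in% planted_tfs &
                                         tf_ids %in% de$gene_id,
                                       config$tf_lfc, 0),
                          stringsAsFactors = FALSE),
    regulons = regulons,
    compound_hits = hits), class = "synthetic_truth")
}

#' Simulate gene annotation on one synthetic chromosome
#'
#' Genes are tiled with at least 12 kb between neighboring spans so
#' default promoter windows never collide, with alternating strands and
#' 1-5 exons per gene.
#'
#' @param config a [simulation_config()].
#' @return a [gene_annotation()] on chromosome `"chrS1"`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "annotation"))
  n <- config$n_genes
  ids <- gene_ids_for(n)
  len <- round(runif(n, 2000, 8000))
  start <- cumsum(c(6000, len[-n] + 12000))
  end <- start + len
  strand <- rep_len(c("+", "-"), n)
  exon_rows <- vector("list", n)
  for (i in seq_len(n)) {
    n_ex <- sample(1:5, 1)
    cuts <- sort(round(runif(2 * n_ex, 0, len[i])))
    es <- start[i] + cuts[seq(1, 2 * n_ex, 2)]
    ee <- start[i] + cuts[seq(2, 2 * n_ex, 2)]
    ee <- pmin(pmax(ee, es + 1), end[i])
    es <- pmin(es, ee - 1)
    exon_rows[[i]] <- data.frame(gene_id = ids[i], start = es, end = ee,
                                 stringsAsFactors = FALSE)
  }
  gene_annotation(
    data.frame(gene_id = ids, chrom = "chrS1", strand = strand,
               start = start, end = end, stringsAsFactors = FALSE),
    do.call(rbind, exon_rows))
}

# Shared NB sampler: baseline medians, per-sample library factors, planted
# case-group fold-changes.
nb_count_matrix <- function(feature_ids, lfc, config, baseline, seed_tag) {
  set.seed(stage_seed(config$seed, seed_tag))
  nf <- length(feature_ids)
  n1 <- config$n_case; n2 <- config$n_control
  samples <- c(sprintf("case_%d", seq_len(n1)),
               sprintf("control_%d", seq_len(n2)))
  groups <- setNames(rep(c("case", "control"), c(n1, n2)), samples)
  base <- rlnorm(nf, log(baseline), 0.5)
  sf <- config$library_size_factors
  if (is.null(sf)) sf <- rlnorm(n1 + n2, 0, 0.1)
  sf <- rep_len(sf, n1 + n2)
  sf <- sf / exp(mean(log(sf)))
  mu <- outer(base, sf)
  mu[, seq_len(n1)] <- mu[, seq_len(n1)] * 2^lfc
  size <- 1 / rep_len(config$nb_dispersion, nf)
  counts <- matrix(rnbinom(nf * (n1 + n2), mu = as.vector(mu),
                           size = rep(size, n1 + n2)),
                   nrow = nf, dimnames = list(feature_ids, samples))
  count_matrix(counts, groups)
}

#' Simulate the expression count matrix
#'
#' Negative-binomial counts with lognormal per-gene baselines around
#' `baseline_mean_expr`, mild per-sample library factors, and case-group
#' means multiplied by `2^lfc` for the planted DE genes.
#'
#' @param config a [simulation_config()].
#' @param truth a `synthetic_truth` from [simulate_truth()].
#' @return a [count_matrix()] over all genes.
#' @export
simulate_expression_counts <- function(config, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  genes <- truth$gene_ids
  lfc <- setNames(rep(0, length(genes)), genes)
  lfc[truth$de_genes$gene_id] <- truth$de_genes$lfc
  nb_count_matrix(genes, unname(lfc), config, config$baseline_mean_expr,
                  "expr")
}

#' Simulate the methylation region count matrix
#'
#' One region per gene and kind (`"gene|promoter"`, `"gene|exon"`,
#' `"gene|body"`), negative-binomial counts around `baseline_mean_meth`;
#' planted hypermethylated promoters get case means times `2^lfc_dm`.
#'
#' @param config a [simulation_config()].
#' @param truth a `synthetic_truth`.
#' @param annotation the matching [gene_annotation()] (region kinds follow
#'   its genes; exon regions only for genes with exons).
#' @return a [count_matrix()] over region ids.
#' @export
simulate_methylation_counts <- function(config, truth, annotation) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(annotation, "gene_annotation"))
  if (config$coupling == "anti" &&
      nrow(truth$dm_promoters) > nrow(truth$de_genes)) {
    stop("anti-coupling requires no more hypermethylated promoters than ",
         "DE genes")
  }
  g <- annotation$genes$gene_id
  with_exon <- unique(annotation$exons$gene_id)
  rid <- c(paste0(g, "|promoter"), paste0(with_exon, "|exon"),
           paste0(g, "|body"))
  lfc <- setNames(rep(0, length(rid)), rid)
  lfc[paste0(truth$dm_promoters$gene_id, "|promoter")] <-
    truth$dm_promoters$lfc
  nb_count_matrix(rid, unname(lfc), config, config$baseline_mean_meth,
                  "meth")
}

#' Materialize the TF regulatory network of the truth
#'
#' @param config a [simulation_config()].
#' @param truth a `synthetic_truth`.
#' @return a [regulatory_network()] with one edge per (TF, regulon member).
#' @export
simulate_trn <- function(config, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  regulatory_network(data.frame(source = truth$regulons$tf_id,
                                target = truth$regulons$target,
                                stringsAsFactors = FALSE))
}

#' Simulate compound signature matrices
#'
#' Per (context, replicate) a genes x compounds matrix of standard-normal
#' scores; each intended hit adds plus/minus `compound_effect_size` to its
#' target TF's score in the designated context, consistently across
#' replicates.
#'
#' @param config a [simulation_config()].
#' @param truth a `synthetic_truth`.
#' @return a `compound_signature_set`.
#' @export
simulate_compound_signatures <- function(config, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(stage_seed(config$seed, "compounds"))
  genes <- truth$gene_ids
  cmpds <- sprintf("cmpd%03d", seq_len(config$n_compounds))
  nrep <- config$n_replicates_per_signature
  data <- list()
  for (cx in config$cell_contexts) {
    arr <- array(rnorm(length(genes) * length(cmpds) * nrep),
                 dim = c(length(genes), length(cmpds), nrep),
                 dimnames = list(genes, cmpds, seq_len(nrep)))
    hits <- truth$compound_hits[truth$compound_hits$context == cx, ,
                                drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      eff <- if (hits$direction[i] == "up") config$compound_effect_size else
        -config$compound_effect_size
      arr[hits$tf_id[i], hits$compound_id[i], ] <-
        arr[hits$tf_id[i], hits$compound_id[i], ] + eff
    }
    data[[cx]] <- arr
  }
  structure(list(genes = genes, contexts = sort(config$cell_contexts),
                 compounds = cmpds, data = data),
            class = "compound_signature_set")
}

#' Simulate a complete dataset (and optionally write it to disk)
#'
#' Runs every generator under one configuration and, when `outdir` is
#' given, writes `annotation.gtf`, `expr_counts.tsv`, `meth_counts.tsv`,
#' `groups.tsv`, `trn.tsv`, `signatures/<context>_<replicate>.tsv` and
#' `truth.json`.
#'
#' @param config a [simulation_config()].
#' @param outdir optional output directory.
#' @return list with `config`, `truth`, `annotation`, `expr`, `meth`,
#'   `trn`, `signatures`.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- simulate_truth(config)
  annotation <- simulate_annotation(config)
  expr <- simulate_expression_counts(config, truth)
  meth <- simulate_methylation_counts(config, truth, annotation)
  trn <- simulate_trn(config, truth)
  signatures <- simulate_compound_signatures(config, truth)
  out <- list(config = config, truth = truth, annotation = annotation,
              expr = expr, meth = meth, trn = trn, signatures = signatures)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_gene_annotation(annotation, file.path(outdir, "annotation.gtf"))
    write_count_matrix(expr, file.path(outdir, "expr_counts.tsv"),
                       file.path(outdir, "groups.tsv"))
    write_count_matrix(meth, file.path(outdir, "meth_counts.tsv"))
    write_network(trn, file.path(outdir, "trn.tsv"))
    write_compound_signatures(signatures, file.path(outdir, "signatures"))
    truth_js <- truth
    truth_js$gene_ids <- NULL
    class(truth_js) <- NULL
    jsonlite::write_json(truth_js, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Simulate per-gene mediation chains
#'
#' Small continuous-scale generator for the mediation models: per gene,
#' methylation is `a * group + noise` and expression is
#' `b * methylation + direct * group + noise`, so the true indirect effect
#' is `a * b`.  Intended for use with `transform = "identity"` and
#' `min_mean = 0` in the mediation functions.
#'
#' @param n_genes number of independent genes.
#' @param a,b,direct true coefficients (set `a = 0` for null genes).
#' @param noise_sd Gaussian noise sd for both stages.
#' @param n_case,n_control group sizes.
#' @param seed integer seed.
#' @return list with `expr` ([count_matrix()]-free numeric matrix), `meth`
#'   (rows `"gene|promoter"`), `groups`, and the true `indirect` effect.
#' @export
simulate_mediation_chain <- function(n_genes = 200, a = 1, b = -0.5,
                                     direct = 0, noise_sd = 0.2,
                                     n_case = 5, n_control = 5, seed = 1) {
  set.seed(stage_seed(seed, "chain"))
  n <- n_case + n_control
  samples <- c(sprintf("case_%d", seq_len(n_case)),
               sprintf("control_%d", seq_len(n_control)))
  g <- rep(c(1, 0), c(n_case, n_control))
  ids <- gene_ids_for(n_genes)
  meth <- matrix(rep(a * g, each = n_genes) +
                   rnorm(n_genes * n, sd = noise_sd),
                 nrow = n_genes, dimnames = list(paste0(ids, "|promoter"),
                                                 samples))
  expr <- b * meth + matrix(rep(direct * g, each = n_genes), nrow = n_genes) +
    matrix(rnorm(n_genes * n, sd = noise_sd), nrow = n_genes)
  rownames(expr) <- ids
  list(expr = expr, meth = meth,
       groups = setNames(rep(c("case", "control"), c(n_case, n_control)),
                         samples),
       indirect = a * b)
}
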