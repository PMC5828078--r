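# Staged pipeline runner: data (simulated or loaded) -> differential
# expression + methylation -> GSEA coupling -> mediation -> TRN summaries
# -> compound query, with per-stage provenance signatures, caching, and a
# machine-readable JSON report.  One global seed is fanned out to
# per-stage sub-seeds through stage_seed(), so the run is byte-for-byte
# reproducible given (inputs, config, seed).

#' Pipeline configuration
#'
#' Bundles either a [simulation_config()] or a set of input paths with the
#' analysis thresholds used throughout the study design: FDR 0.05, TF
#' |log2FC| > 1, average-read filter 50, 1000 GSEA permutations, top-100
#' signature membership, top-4 TFs.
#'
#' @param seed integer global seed (mandatory; fanned out per stage).
#' @param sim a [simulation_config()]; mutually exclusive with `inputs`.
#' @param inputs named list of paths (`expr`, `groups`, `meth`, `network`,
#'   `signatures_dir`; optionally `annotation`) for file-based runs.
#' @param q_max FDR threshold shared by all calls (default 0.05).
#' @param tf_lfc_min TF |log2FC| threshold (default 1).
#' @param min_mean average raw-read filter for the regression stage
#'   (default 50).
#' @param gsea_n_perm GSEA permutations (default 1000).
#' @param n_boot mediation bootstrap replicates (default 2000).
#' @param top_k signature membership depth (default 100).
#' @param top_n_tfs number of top TFs carried into the compound query
#'   (default 4).
#' @param mediation_region_kind mediator region kind (default promoter).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, sim = NULL, inputs = NULL,
                            q_max = 0.05, tf_lfc_min = 1, min_mean = 50,
                            gsea_n_perm = 1000, n_boot = 2000,
                            top_k = 100, top_n_tfs = 4,
                            mediation_region_kind = "promoter") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(sim) == is.null(inputs)) {
    stop("provide exactly one of 'sim' or 'inputs'")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "simulation_config"))
  if (!is.null(inputs)) {
    need <- c("expr", "groups", "meth", "network", "signatures_dir")
    if (!all(need %in% names(inputs))) {
      stop("inputs must name: ", paste(need, collapse = ", "))
    }
  }
  if (any(c(q_max, tf_lfc_min, min_mean, gsea_n_perm, n_boot, top_k,
            top_n_tfs) < 0)) {
    stop("thresholds must be non-negative")
  }
  structure(list(seed = as.integer(seed), sim = sim, inputs = inputs,
                 q_max = q_max, tf_lfc_min = tf_lfc_min,
                 min_mean = min_mean, gsea_n_perm = gsea_n_perm,
                 n_boot = n_boot, top_k = top_k, top_n_tfs = top_n_tfs,
                 mediation_region_kind = mediation_region_kind),
            class = "pipeline_config")
}

# Strip the class so a simulation_config serializes deterministically.
sim_params <- function(sim) {
  x <- unclass(sim)
  x[order(names(x))]
}

read_diff_tsv <- function(path) {
  df <- read_tsv_plain(path)
  df$feature_id <- as.character(df$feature_id)
  df
}

#' Run the full integration pipeline
#'
#' Stages run in dependency order: `data` (simulate or load), `diff_expr`,
#' `diff_meth`, `gsea`, `mediation`, `trn`, `compounds`, then the report.
#' Every stage writes its outputs under `outdir`, records a provenance
#' signature (md5 of its parameters and upstream signatures) in
#' `manifest.json`, and is skipped on re-run when its signature and
#' outputs are unchanged — so changing one parameter re-executes only the
#' stages downstream of it.  Any stage error aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param force re-run every stage regardless of the cache.
#' @return invisibly, a list with `report` (also written as
#'   `report.json`), `executed` (character vector of stages actually run)
#'   and `outdir`.
#' @export
run_pipeline <- function(config, outdir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  executed <- character(0)
  sig <- list()

  run_stage <- function(name, params, outputs, fn) {
    sig[[name]] <<- object_signature(list(stage = name, params = params))
    paths <- file.path(outdir, outputs)
    cached <- !force && identical(manifest[[name]], sig[[name]]) &&
      all(file.exists(paths))
    if (cached) {
      message(sprintf("[%s] cached (signature %s)", name,
                      substr(sig[[name]], 1, 8)))
      return(FALSE)
    }
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    executed <<- c(executed, name)
    message(sprintf("[%s] executed (signature %s)", name,
                    substr(sig[[name]], 1, 8)))
    TRUE
  }

  # ---- data ----------------------------------------------------------
  data_params <- if (!is.null(config$sim)) {
    list(mode = "simulate", sim = sim_params(config$sim))
  } else {
    tryCatch(
      list(mode = "load",
           md5 = lapply(config$inputs[c("expr", "groups", "meth",
                                        "network")], file_signature)),
      error = function(e) {
        stop("pipeline stage 'data' failed: ", conditionMessage(e),
             call. = FALSE)
      })
  }
  data_out <- c("expr_counts.tsv", "groups.tsv", "meth_counts.tsv",
                "trn.tsv")
  run_stage("data", data_params, data_out, function() {
    if (!is.null(config$sim)) {
      simulate_dataset(config$sim, outdir)
    } else {
      file.copy(unlist(config$inputs[c("expr", "groups", "meth",
                                       "network")]),
                file.path(outdir, data_out), overwrite = TRUE)
      sigdir <- file.path(outdir, "signatures")
      dir.create(sigdir, showWarnings = FALSE)
      file.copy(list.files(config$inputs$signatures_dir,
                           full.names = TRUE), sigdir, overwrite = TRUE)
    }
  })
  expr <- read_count_matrix(file.path(outdir, "expr_counts.tsv"),
                            file.path(outdir, "groups.tsv"))
  meth <- read_count_matrix(file.path(outdir, "meth_counts.tsv"),
                            file.path(outdir, "groups.tsv"))
  network <- read_network(file.path(outdir, "trn.tsv"))

  # ---- differential tests -------------------------------------------
  run_stage("diff_expr", list(upstream = sig$data), "diff_expr.tsv",
            function() {
    write_tsv_plain(nb_wald_test(expr), file.path(outdir, "diff_expr.tsv"))
  })
  run_stage("diff_meth", list(upstream = sig$data), "diff_meth.tsv",
            function() {
    write_tsv_plain(nb_wald_test(meth), file.path(outdir, "diff_meth.tsv"))
  })
  de <- read_diff_tsv(file.path(outdir, "diff_expr.tsv"))
  dm <- read_diff_tsv(file.path(outdir, "diff_meth.tsv"))

  # ---- GSEA coupling -------------------------------------------------
  run_stage("gsea", list(upstream = c(sig$diff_expr, sig$diff_meth),
                         q_max = config$q_max,
                         n_perm = config$gsea_n_perm,
                         seed = stage_seed(config$seed, "gsea")),
            "gsea.tsv", function() {
    ranked <- build_ranked_list(de)
    sets <- suppressWarnings(
      build_methylation_gene_sets(dm, config$q_max))
    res <- suppressWarnings(
      gsea_batch(ranked, sets, n_perm = config$gsea_n_perm,
                 seed = stage_seed(config$seed, "gsea")))
    write_tsv_plain(res, file.path(outdir, "gsea.tsv"))
  })
  gsea_res <- read_tsv_plain(file.path(outdir, "gsea.tsv"))

  # ---- mediation -----------------------------------------------------
  run_stage("mediation",
            list(upstream = sig$data, min_mean = config$min_mean,
                 n_boot = config$n_boot,
                 kind = config$mediation_region_kind,
                 seed = stage_seed(config$seed, "mediation")),
            "mediation.tsv", function() {
    res <- mediation_tbi_via_methylation(
      expr, meth, region_kind = config$mediation_region_kind,
      min_mean = config$min_mean, n_boot = config$n_boot,
      seed = stage_seed(config$seed, "mediation"))
    write_tsv_plain(res, file.path(outdir, "mediation.tsv"))
  })
  mediation <- read_tsv_plain(file.path(outdir, "mediation.tsv"))

  # ---- TRN -----------------------------------------------------------
  run_stage("trn", list(upstream = c(sig$data, sig$diff_expr),
                        q_max = config$q_max,
                        lfc_min = config$tf_lfc_min,
                        top_n = config$top_n_tfs),
            c("tf_summary.tsv", "tf_selected.json"), function() {
    selected <- suppressWarnings(
      select_dysregulated_tfs(de, network, config$q_max,
                              config$tf_lfc_min))
    summaries <- tf_target_summaries(network, de,
                                     target_q_max = config$q_max)
    top <- rank_tfs_by_altered_targets(
      summaries[summaries$tf_id %in% selected, , drop = FALSE],
      config$top_n_tfs)
    write_tsv_plain(summaries, file.path(outdir, "tf_summary.tsv"))
    jsonlite::write_json(list(selected = selected, top = top),
                         file.path(outdir, "tf_selected.json"),
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
  })
  tf_summary <- read_tsv_plain(file.path(outdir, "tf_summary.tsv"))
  tf_sel <- jsonlite::read_json(file.path(outdir, "tf_selected.json"),
                                simplifyVector = TRUE)

  # ---- compound query ------------------------------------------------
  run_stage("compounds", list(upstream = c(sig$data, sig$trn),
                              k = config$top_k),
            "compound_hits.tsv", function() {
    set <- read_compound_signatures(file.path(outdir, "signatures"))
    tfs <- intersect(unlist(tf_sel$top), set$genes)
    hits <- do.call(rbind, c(list(data.frame(
      tf_id = character(), compound_id = character(),
      context = character(), direction = character(),
      tf_rank = integer(), n_genes = integer(),
      stringsAsFactors = FALSE)),
      lapply(tfs, function(tf) {
        h <- query_compounds(set, tf, config$top_k)
        if (nrow(h)) cbind(tf_id = tf, h) else NULL
      })))
    write_tsv_plain(hits, file.path(outdir, "compound_hits.tsv"))
  })
  hits <- read_tsv_plain(file.path(outdir, "compound_hits.tsv"))

  # ---- report --------------------------------------------------------
  manifest <- sig
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  kind <- sub("^.*\\|", "", dm$feature_id)
  sig_regions <- !is.na(dm$qvalue) & dm$qvalue < config$q_max
  report <- list(
    parameters = list(seed = config$seed, q_max = config$q_max,
                      tf_lfc_min = config$tf_lfc_min,
                      min_mean = config$min_mean,
                      gsea_n_perm = config$gsea_n_perm,
                      n_boot = config$n_boot, top_k = config$top_k,
                      top_n_tfs = config$top_n_tfs),
    stage_signatures = sig,
    n_features = list(expression = nrow(de), methylation_regions = nrow(dm)),
    significant_methylation_regions = lapply(
      split(dm$feature_id[sig_regions], kind[sig_regions]), as.list),
    gsea = gsea_res,
    mediation_hits = mediation[!is.na(mediation$qvalue) &
                                 mediation$qvalue < config$q_max, ,
                               drop = FALSE],
    tf_selected = tf_sel$selected, tf_top = tf_sel$top,
    tf_summary = tf_summary,
    compound_hits = hits)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(list(report = report, executed = executed, outdir = outdir))
}
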