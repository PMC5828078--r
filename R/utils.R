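# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic TSV writer: UTF-8, LF, tab-separated, no quoting.
write_tsv_plain <- function(df, path, row_names = FALSE) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE, eol = "\n",
              fileEncoding = "")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' One global seed is fanned out to per-stage sub-seeds through a fixed
#' polynomial hash of the stage name, so that each stochastic stage is
#' reproducible independently of execution order.  The result is always a
#' valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
#' @examples
#' stage_seed(7, "gsea") != stage_seed(7, "mediation")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 2654435 + h) %% 2147483647)
}

# md5 signature of an arbitrary parameter list via canonical JSON.
# Used for stage provenance / cache invalidation in the pipeline runner.
object_signature <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf, sep = "")
  unname(tools::md5sum(tf))
}

file_signature <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  unname(tools::md5sum(path))
}

# Validate a probability vector, NA allowed.
check_pvalues <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values outside [0, 1] at positions: ",
                     paste(which(bad), collapse = ", "))
  invisible(p)
}
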