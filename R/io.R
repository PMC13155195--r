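#' Read and write OTU count tables
#'
#' Count tables are TSV or CSV files whose first column holds sample IDs
#' and whose header names the taxa. `read_otu_table()` validates that every
#' cell is a non-negative integer (a float like `3.0` is accepted as 3;
#' `3.5` is an error) and reports the offending row and column otherwise.
#'
#' @param path File path; the delimiter is chosen by extension (`.csv` vs
#'   anything else = tab).
#' @return An integer count matrix with sample IDs as row names and taxon
#'   labels as column names.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a sample-ID column and at least one taxon",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric entries in count table", call. = FALSE)
  bad <- which(is.na(M) | M < 0 | abs(M - round(M)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop("invalid count at sample '", ids[b[1L]], "', taxon '",
         colnames(M)[b[2L]], "': ", df[b[1L], b[2L] + 1L], call. = FALSE)
  }
  M <- round(M)
  storage.mode(M) <- "integer"
  rownames(M) <- ids
  M
}

#' @param X Count matrix with row names (sample IDs) and column names.
#' @rdname read_otu_table
#' @export
write_otu_table <- function(X, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  df <- data.frame(sample = ids, X, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample covariate table
#'
#' CSV/TSV with columns: sample ID (first), `group` (the 0/1 contrast
#' indicator), optional `subject` (random-effect labels), and any further
#' numeric covariate columns.
#'
#' @param path File path.
#' @return A list: `design` (a [da_design()]) and `sample_ids`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!("group" %in% names(df))) {
    stop("covariate table needs a 'group' column", call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  s <- df$group
  g <- if ("subject" %in% names(df)) df$subject else NULL
  zc <- setdiff(names(df), c(names(df)[1L], "group", "subject"))
  Z <- if (length(zc)) as.matrix(df[, zc, drop = FALSE]) else NULL
  list(design = da_design(s, Z = Z, g = g), sample_ids = ids)
}

#' Read a run configuration
#'
#' YAML configuration with a `task` (`simulate`, `fit`, `da`, `ppc` or
#' `losses`), file `paths`, and a `model` block (lambda, c_beta, m or
#' p0_null, t, u, iters, burn, seed, diagonal_precision). A seed is
#' mandatory so that every run is reproducible.
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$task) ||
      !cfg$task %in% c("simulate", "fit", "da", "ppc", "losses")) {
    stop("config needs task: simulate | fit | da | ppc | losses", call. = FALSE)
  }
  if (is.null(cfg$model$seed)) stop("config needs model$seed", call. = FALSE)
  it <- cfg$model$iters %||% 10000
  bu <- cfg$model$burn %||% floor(it / 2)
  if (!(it > bu)) stop("config needs iters > burn", call. = FALSE)
  for (nm in intersect(names(cfg$paths), c("counts", "tree", "covariates"))) {
    if (!file.exists(cfg$paths[[nm]])) {
      stop("config path '", nm, "' does not exist: ", cfg$paths[[nm]],
           call. = FALSE)
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
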