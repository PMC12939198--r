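# Delimited-text and matrix-market I/O for the pipeline's tables. All
# tabular files are tab-separated with a header; the observation window of
# a cell table travels in a '#! window:' comment line so round trips are
# lossless.

#' Write / read a cell table as tab-separated text
#'
#' @param cells Cell table (the observation window in
#'   `attr(cells, "window")` is stored in a `#! window:` header comment).
#' @param path File path.
#' @return `write_cell_table` returns `path` invisibly; `read_cell_table`
#'   the cell table with its window attribute restored.
#' @export
write_cell_table <- function(cells, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- attr(cells, "window")
  if (!is.null(w))
    writeLines(sprintf("#! window: %s", paste(format(w, digits = 15),
                                              collapse = " ")), con)
  write.table(cells, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  first <- readLines(path, n = 1L)
  window <- NULL
  if (startsWith(first, "#! window:"))
    window <- as.numeric(strsplit(sub("#! window:", "", first), " +")[[1L]][-1L])
  cells <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
  if (!is.null(window) && length(window) == 4L)
    attr(cells, "window") <- window
  cells
}

#' Write / read a patient cohort table as tab-separated text
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @export
write_cohort_table <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  cohort <- read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  if ("age_group" %in% names(cohort))
    cohort$age_group <- factor(cohort$age_group, levels = c("<65", ">=65"))
  if ("sex" %in% names(cohort))
    cohort$sex <- factor(cohort$sex, levels = c("F", "M"))
  if ("tnm_stage" %in% names(cohort))
    cohort$tnm_stage <- factor(cohort$tnm_stage,
                               levels = c("I", "II", "III", "IV"),
                               ordered = TRUE)
  cohort
}

#' Write / read an expression matrix as matrix-market triplets
#'
#' Writes `<prefix>.mtx` plus `<prefix>.genes.txt` and
#' `<prefix>.cells.txt` sidecars.
#'
#' @param counts Genes x cells matrix (coerced to sparse).
#' @param prefix File prefix (no extension).
#' @export
write_expression_mtx <- function(counts, prefix) {
  m <- methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                   "CsparseMatrix")
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  writeLines(rownames(counts) %||% as.character(seq_len(nrow(counts))),
             paste0(prefix, ".genes.txt"))
  writeLines(colnames(counts) %||% as.character(seq_len(ncol(counts))),
             paste0(prefix, ".cells.txt"))
  invisible(prefix)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(prefix) {
  m <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(prefix, ".genes.txt")),
                      readLines(paste0(prefix, ".cells.txt")))
  m
}

#' Write / read a run configuration as YAML or JSON
#'
#' The format follows the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param config A list-like configuration.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(cfg, path)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else stop_config("config path must end in .yaml, .yml or .json")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else stop_config("config path must end in .yaml, .yml or .json")
}
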