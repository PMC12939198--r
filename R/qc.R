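#' Quality-control thresholds for single-cell expression data
#'
#' A cell is retained when its detected feature count lies inside
#' `[min_features, max_features]` (inclusive, "between"), its
#' mitochondrial UMI fraction is strictly below `max_mito_fraction` and
#' its erythroid UMI fraction strictly below `max_erythroid_fraction`.
#' "Features" are genes with count > 0; mitochondrial genes are matched by
#' prefix (default `MT-`); the erythroid set is an explicit haemoglobin
#' gene list.
#'
#' @param min_features,max_features Inclusive feature-count bounds.
#' @param max_mito_fraction Strict upper bound on the mitochondrial UMI
#'   share.
#' @param max_erythroid_fraction Strict upper bound on the erythroid UMI
#'   share.
#' @param mito_pattern Regular expression matching mitochondrial gene
#'   names.
#' @param erythroid_genes Character vector of erythroid (haemoglobin)
#'   genes.
#'
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 200L, max_features = 3000L,
                          max_mito_fraction = 0.10,
                          max_erythroid_fraction = 0.01,
                          mito_pattern = "^MT-",
                          erythroid_genes = c("HBA1", "HBA2", "HBB")) {
  if (min_features > max_features)
    stop_config("min_features must be <= max_features")
  if (max_mito_fraction < 0 || max_mito_fraction > 1 ||
      max_erythroid_fraction < 0 || max_erythroid_fraction > 1)
    stop_config("fraction thresholds must lie in [0, 1]")
  structure(list(min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 max_mito_fraction = max_mito_fraction,
                 max_erythroid_fraction = max_erythroid_fraction,
                 mito_pattern = mito_pattern,
                 erythroid_genes = erythroid_genes),
            class = "qc_thresholds")
}

#' Filter cells on feature counts and mitochondrial/erythroid fractions
#'
#' @param counts Genes x cells count matrix (base matrix or sparse
#'   \pkg{Matrix}), non-negative.
#' @param genes Gene names aligned to the rows (defaults to
#'   `rownames(counts)`).
#' @param thresholds A [qc_thresholds()].
#'
#' @return Integer indices of the retained cells (columns).
#' @export
#' @examples
#' m <- matrix(rpois(300 * 4, 2), 300,
#'             dimnames = list(c(paste0("MT-", 1:5), paste0("G", 1:295)), NULL))
#' qc_filter(m, thresholds = qc_thresholds(min_features = 100))
qc_filter <- function(counts, genes = rownames(counts),
                      thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (is.null(genes))
    stop("gene names are required (rownames or `genes`)", call. = FALSE)
  if (length(genes) != nrow(counts))
    stop(sprintf("gene names (%d) do not match matrix rows (%d)",
                 length(genes), nrow(counts)), call. = FALSE)
  if (ncol(counts) == 0L) return(integer(0))
  if (min(counts) < 0) stop("counts must be non-negative", call. = FALSE)

  features <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)
  frac_of <- function(rows) {
    s <- if (any(rows)) Matrix::colSums(counts[rows, , drop = FALSE]) else 0
    ifelse(totals > 0, s / totals, 0)
  }
  mito <- frac_of(grepl(thresholds$mito_pattern, genes))
  ery <- frac_of(genes %in% thresholds$erythroid_genes)
  unname(which(features >= thresholds$min_features &
                 features <= thresholds$max_features &
                 mito < thresholds$max_mito_fraction &
                 ery < thresholds$max_erythroid_fraction))
}

#' Score cells by the mean expression of a gene signature
#'
#' The score of a cell is the arithmetic mean of the normalised expression
#' of the signature genes present in the matrix. Genes absent from the
#' matrix are dropped with a warning; an empty intersection is an error
#' (never a silent zero).
#'
#' @param expr Normalised expression matrix, genes x cells, with gene
#'   rownames (base matrix or sparse \pkg{Matrix}).
#' @param gene_set Character vector of signature genes.
#'
#' @return Named numeric vector, one score per cell.
#' @export
signature_score <- function(expr, gene_set) {
  if (is.null(rownames(expr)))
    stop("expression matrix must have gene rownames", call. = FALSE)
  if (!length(gene_set)) stop("gene_set is empty", call. = FALSE)
  gene_set <- unique(gene_set)
  present <- gene_set[gene_set %in% rownames(expr)]
  if (!length(present))
    stop("none of the signature genes are present in the matrix",
         call. = FALSE)
  dropped <- setdiff(gene_set, present)
  if (length(dropped))
    warning(sprintf("dropping %d signature gene(s) absent from the matrix: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  scores <- Matrix::colMeans(expr[present, , drop = FALSE])
  setNames(as.numeric(scores),
           colnames(expr) %||% as.character(seq_len(ncol(expr))))
}
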