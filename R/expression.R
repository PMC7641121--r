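#' Construct a validated FPKM expression matrix
#'
#' Bundles a gene x sample matrix of FPKM values with per-sample metadata
#' (tissue, replicate, cultivar).  All values must be finite and
#' non-negative, gene and sample identifiers must be unique, and every
#' sample must be described in the metadata with a replicate index that is
#' unique within its (tissue, cultivar) group.
#'
#' @param values Numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry names (gene ids / sample ids).
#' @param sample_meta Data frame with columns `sample_id`, `tissue`,
#'   `replicate` and `cultivar`, covering every column of `values`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `samples` (metadata aligned to the columns).
#' @seealso [load_expression()], [summarize_replicates()]
#' @export
expression_matrix <- function(values, sample_meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("format error: 'values' must have gene row names and sample column names")
  }
  if (anyDuplicated(gene_ids)) {
    stop("format error: duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("format error: duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    stop("format error: expression values must be finite numbers")
  }
  if (any(values < 0)) {
    stop("format error: negative expression value(s); FPKM must be >= 0")
  }

  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  needed <- c("sample_id", "tissue", "replicate", "cultivar")
  miss_col <- setdiff(needed, names(sample_meta))
  if (length(miss_col)) {
    stop("metadata error: missing column(s): ", paste(miss_col, collapse = ", "))
  }
  missing <- setdiff(sample_ids, sample_meta$sample_id)
  if (length(missing)) {
    stop("metadata error: sample(s) absent from metadata: ",
         paste(missing, collapse = ", "))
  }
  samples <- sample_meta[match(sample_ids, sample_meta$sample_id), needed,
                         drop = FALSE]
  rownames(samples) <- NULL
  grp <- paste(samples$tissue, samples$cultivar, sep = "\r")
  dup <- unlist(lapply(split(samples$replicate, grp), duplicated))
  if (any(dup)) {
    stop("metadata error: replicate indices must be distinct within a tissue")
  }

  structure(list(values = values, samples = samples),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d tissues, %d cultivars)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$tissue)),
              length(unique(x$samples$cultivar))))
  invisible(x)
}

#' Read an FPKM matrix and its sample metadata from TSV files
#'
#' The matrix file has a header row of sample ids, a first column of gene
#' ids and one row per gene; the metadata file maps every sample id to a
#' tissue label, a replicate index and a cultivar label.  Row and column
#' order are preserved from the files.
#'
#' @param path Path to the tab-delimited expression matrix.
#' @param meta_path Path to the tab-delimited sample metadata with columns
#'   `sample_id`, `tissue`, `replicate`, `cultivar`.
#' @return An [expression_matrix()] object.
#' @export
load_expression <- function(path, meta_path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 2L || nrow(df) < 1L) {
    stop("format error: expression matrix needs a gene id column, at least one sample column and one gene row")
  }
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("format error: duplicate gene id(s) in ", path)
  }
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(vals),
                dimnames = list(gene_ids, colnames(vals)))
  if (anyNA(num)) {
    stop("format error: non-numeric expression value(s) in ", path)
  }
  meta <- utils::read.delim(meta_path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  expression_matrix(num, meta)
}

#' Write an expression matrix and its metadata as TSV files
#'
#' Emits the same dialect that [load_expression()] reads back: first
#' column `gene_id`, header row of sample ids, tab-delimited.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path for the matrix TSV.
#' @param meta_path Output path for the sample-metadata TSV.
#' @return Invisibly, `c(path, meta_path)`.
#' @export
write_expression <- function(m, path, meta_path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Summarize replicates into per-tissue expression profiles
#'
#' Collapses the replicate columns of each tissue to their per-gene median
#' and calls a gene expressed in a tissue when that median exceeds
#' `threshold` (strictly: a median of exactly `threshold` is *not*
#' expressed).  The conventional FPKM floor for calling expression is 0.3.
#'
#' @param m An `ExpressionMatrix`.
#' @param threshold FPKM expression-call cutoff (default 0.3).
#' @return An object of class `TissueProfile`: list with `summary_values`
#'   (gene x tissue medians), `expressed` (logical gene x tissue),
#'   `threshold`, `gene_ids` and `tissue_ids`.  Tissue order follows first
#'   appearance in the sample metadata.
#' @export
summarize_replicates <- function(m, threshold = 0.3) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (nrow(m$values) == 0L || ncol(m$values) == 0L) {
    stop("cannot summarize an empty expression matrix")
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  tissues <- unique(m$samples$tissue)
  summ <- vapply(tissues, function(t) {
    cols <- m$values[, m$samples$tissue == t, drop = FALSE]
    apply(cols, 1L, stats::median)
  }, numeric(nrow(m$values)))
  summ <- matrix(summ, nrow = nrow(m$values),
                 dimnames = list(rownames(m$values), tissues))
  structure(list(summary_values = summ,
                 expressed = summ > threshold,
                 threshold = threshold,
                 gene_ids = rownames(m$values),
                 tissue_ids = tissues),
            class = "TissueProfile")
}

#' @export
print.TissueProfile <- function(x, ...) {
  cat(sprintf("TissueProfile: %d genes x %d tissues (expressed when median FPKM > %g)\n",
              length(x$gene_ids), length(x$tissue_ids), x$threshold))
  invisible(x)
}

#' Per-sample expression calls
#'
#' Variant of the expression call applied to individual sample columns
#' instead of tissue medians, for designs where per-sample calls are
#' preferred.
#'
#' @param m An `ExpressionMatrix`.
#' @param threshold FPKM cutoff; a value of exactly `threshold` is not
#'   called expressed.
#' @return Logical gene x sample matrix.
#' @export
call_expressed <- function(m, threshold = 0.3) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  m$values > threshold
}

#' Count the tissues in which each gene is expressed
#'
#' @param p A `TissueProfile`.
#' @return List with `breadth` (named integer vector, one entry per gene,
#'   values in 0..n_tissues) and `histogram` (data frame `breadth`,
#'   `n_genes` covering every breadth value 0..n_tissues).
#' @export
tissue_breadth <- function(p) {
  stopifnot(inherits(p, "TissueProfile"))
  breadth <- as.integer(rowSums(p$expressed))
  names(breadth) <- p$gene_ids
  nt <- length(p$tissue_ids)
  counts <- tabulate(breadth + 1L, nbins = nt + 1L)
  list(breadth = breadth,
       histogram = data.frame(breadth = 0:nt, n_genes = counts))
}

#' Pairwise Pearson correlation between samples
#'
#' Quality-control view of replicate agreement: the correlation of every
#' pair of sample columns across all genes.  Samples that are constant
#' across genes have no defined correlation; they are flagged and their
#' rows/columns reported as `NA` rather than silently set to zero.
#'
#' @param m An `ExpressionMatrix` with at least two genes.
#' @return List with `correlation` (symmetric sample x sample matrix,
#'   diagonal 1 for non-constant samples) and `constant_samples`
#'   (character vector of flagged sample ids).
#' @export
replicate_correlation <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (nrow(m$values) < 2L) {
    stop("replicate correlation needs at least two genes")
  }
  v <- m$values
  sds <- apply(v, 2L, stats::sd)
  const <- !is.finite(sds) | sds == 0
  cc <- suppressWarnings(stats::cor(v))
  cc[const, ] <- NA_real_
  cc[, const] <- NA_real_
  diag(cc)[!const] <- 1
  list(correlation = cc,
       constant_samples = colnames(v)[const])
}
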