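# All-pairs Pearson correlation with explicit handling of undefined
# (zero-variance) cases.

#' Pearson correlation between two expression vectors
#'
#' The correlation of two genes' expression profiles across the same
#' samples.  When either vector has zero variance the correlation is
#' undefined; `NA_real_` is returned rather than an arbitrary number.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return A value in \[-1, 1\], or `NA_real_` when undefined.
#' @export
pcc <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("correlation needs n >= 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' All-pairs gene correlation matrix
#'
#' Computes the Pearson correlation between every pair of genes, after
#' excluding genes that are expressed in fewer than
#' `min_expressed_tissues` tissues (at the `expression_threshold` median
#' FPKM call) or that have zero variance in the correlated data.  By
#' default correlation runs over all replicate samples; set
#' `use_tissue_medians = TRUE` to correlate tissue-median profiles
#' instead, and `log_transform = TRUE` to correlate `log2(FPKM + 1)`.
#'
#' @param x An `ExpressionMatrix` or a `TissueProfile`.  A profile is
#'   always correlated on its tissue medians.
#' @param min_expressed_tissues Minimum number of tissues a gene must be
#'   expressed in to enter the network (default 1; genes expressed
#'   nowhere are dropped entirely).
#' @param expression_threshold FPKM floor for the expression call
#'   (default 0.3); ignored when `x` is already a `TissueProfile`, whose
#'   own calls are used.
#' @param use_tissue_medians Correlate tissue medians instead of all
#'   samples.
#' @param log_transform Correlate `log2(FPKM + 1)` instead of raw FPKM.
#' @return An object of class `correlation_store`: list with `gene_ids`
#'   (genes kept), `pcc` (symmetric matrix, unit diagonal) and `dropped`
#'   (data frame `gene_id`, `reason` in `"unexpressed"`/`"zero_variance"`).
#' @export
pcc_matrix <- function(x, min_expressed_tissues = 1L,
                       expression_threshold = 0.3,
                       use_tissue_medians = FALSE,
                       log_transform = FALSE) {
  if (inherits(x, "ExpressionMatrix")) {
    profile <- summarize_replicates(x, expression_threshold)
    data <- if (use_tissue_medians) profile$summary_values else x$values
  } else if (inherits(x, "TissueProfile")) {
    profile <- x
    data <- x$summary_values
  } else {
    stop("x must be an ExpressionMatrix or a TissueProfile")
  }
  breadth <- rowSums(profile$expressed)
  if (log_transform) data <- log2(data + 1)

  vars <- apply(data, 1L, stats::var)
  unexpressed <- breadth < min_expressed_tissues
  zero_var <- !unexpressed & (!is.finite(vars) | vars == 0)
  keep <- !unexpressed & !zero_var

  if (sum(keep) < 2L) {
    stop("fewer than 2 genes pass the expression/variance filters")
  }
  dropped <- data.frame(
    gene_id = rownames(data)[!keep],
    reason = ifelse(unexpressed[!keep], "unexpressed", "zero_variance"),
    stringsAsFactors = FALSE)

  cc <- stats::cor(t(data[keep, , drop = FALSE]))
  diag(cc) <- 1
  structure(list(gene_ids = rownames(data)[keep],
                 pcc = cc,
                 dropped = dropped),
            class = "correlation_store")
}

#' @export
print.correlation_store <- function(x, ...) {
  cat(sprintf("correlation_store: %d genes (%d dropped)\n",
              length(x$gene_ids), nrow(x$dropped)))
  invisible(x)
}

#' Asymmetric neighbor ranks and mutual ranks
#'
#' For each gene `a`, partners are sorted by decreasing `|PCC|` (ties
#' broken by ascending gene id) and `rank[a, b]` is the 1-based position
#' of `b` in that list.  The mutual rank of a pair is the geometric mean
#' `MR(a,b) = sqrt(rank[a,b] * rank[b,a])`; MR is symmetric, at least 1,
#' and small for pairs that rank each other highly.
#'
#' @param store A [pcc_matrix()] result.
#' @return An object of class `rank_store`: list with `gene_ids`, `rank`
#'   (integer matrix, `NA` diagonal) and `mr` (symmetric numeric matrix,
#'   `NA` diagonal).
#' @export
rank_neighbors <- function(store) {
  stopifnot(inherits(store, "correlation_store"))
  ids <- store$gene_ids
  n <- length(ids)
  a <- abs(store$pcc)
  diag(a) <- NA_real_
  rk <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ord <- order(-a[i, ], ids, na.last = TRUE)
    ord <- ord[ord != i]
    rk[i, ord] <- seq_len(n - 1L)
  }
  mr <- sqrt(rk * t(rk))
  structure(list(gene_ids = ids, rank = rk, mr = mr), class = "rank_store")
}
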