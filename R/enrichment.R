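# Overlap-based gene-set enrichment: hypergeometric point probability,
# one-sided Fisher upper tail, BH FDR, and the query-level GSEA driver.

#' Build a gene-set collection over a stated universe
#'
#' @param sets Named list of character vectors (set members).  Members
#'   outside the universe are dropped with a message stating how many.
#' @param universe Character vector of all gene ids (the `N` of the
#'   enrichment test).
#' @param categories Optional per-set category labels (e.g. GO BP/CC/MF
#'   or pathway); enrichment FDR is controlled within category when
#'   present.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, categories = NULL) {
  stopifnot(is.list(sets))
  universe <- unique(as.character(universe))
  if (length(sets) &&
      (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop("every gene set must have a non-empty name")
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set name(s)")
  n_outside <- 0L
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    keep <- s %in% universe
    n_outside <<- n_outside + sum(!keep)
    s[keep]
  })
  if (n_outside > 0L) {
    message(n_outside, " set member(s) outside the universe were dropped")
  }
  if (!is.null(categories)) {
    stopifnot(length(categories) == length(sets))
    categories <- as.character(categories)
    names(categories) <- names(sets)
  }
  structure(list(universe = universe, sets = sets, categories = categories),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated as
#' `name TAB description TAB member1 TAB member2 ...`.  The description
#' field is kept as the set's category label.
#'
#' @param path Path to the GMT file.
#' @param universe Optional gene universe; defaults to the union of all
#'   set members.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("format error: GMT line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  }
  nms <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nms
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe, categories = desc)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- collection$categories
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(collection$sets)),
                                             names(collection$sets))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, desc[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

check_hyper_args <- function(N, n, K, k) {
  vals <- c(N = N, n = n, K = K)
  if (any(vals != round(vals)) || any(k != round(k))) {
    stop("hypergeometric arguments must be integers")
  }
  if (N < 0 || n < 0 || K < 0) stop("hypergeometric counts must be >= 0")
  if (K > N) stop("K must be <= N")
  if (n > N) stop("n must be <= N")
  if (any(k < 0) || any(k > min(n, K))) {
    stop("k must satisfy 0 <= k <= min(n, K)")
  }
  if (any(n - k > N - K)) stop("n - k must be <= N - K")
  invisible(NULL)
}

#' Hypergeometric point probability
#'
#' The probability of exactly `k` overlaps when drawing `n` genes from a
#' universe of `N` that contains a set of `K`:
#' `C(K, k) * C(N - K, n - k) / C(N, n)`, computed in log space for
#' numerical stability at transcriptome scale.
#'
#' @param N Universe size.
#' @param n Query (draw) size.
#' @param K Set size.
#' @param k Overlap count (may be a vector).
#' @return Probability in \[0, 1\], vectorized over `k`.
#' @export
hypergeom_pmf <- function(N, n, K, k) {
  check_hyper_args(N, n, K, k)
  exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
}

#' One-sided enrichment probability (Fisher's exact upper tail)
#'
#' The probability of observing an overlap of at least `k`:
#' the sum of [hypergeom_pmf()] over `k' = k .. min(n, K)`.  This is the
#' quantity reported as enrichment significance; the point probability
#' alone is not a significance level.
#'
#' @inheritParams hypergeom_pmf
#' @return Upper-tail probability in (0, 1\], vectorized over `k`.
#' @export
fisher_enrichment_p <- function(N, n, K, k) {
  check_hyper_args(N, n, K, k)
  lower <- max(0, n - (N - K))
  vapply(k, function(ki) {
    if (ki <= lower) return(1)
    ks <- ki:min(n, K)
    lt <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
    m <- max(lt)
    min(exp(m + log(sum(exp(lt - m)))), 1)
  }, numeric(1))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} (p_j * m / j)`, capped at 1 and returned in input
#' order.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Overlap-based gene-set enrichment of a query gene list
#'
#' Tests every set with at least `min_overlap` query members via the
#' one-sided Fisher/hypergeometric upper tail ([fisher_enrichment_p()]),
#' then controls the FDR by Benjamini-Hochberg across the tested sets --
#' within each annotation category when the collection carries category
#' labels, across all sets otherwise.  Query genes outside the universe
#' are dropped (with a message stating how many).
#'
#' @param query Character vector of query gene ids.
#' @param collection A [gene_set_collection()]; its universe is the `N`
#'   of the test.
#' @param min_overlap Minimum overlap for a set to be tested (default 1).
#' @return Data frame with columns `set`, `category`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, sorted by ascending p (ties by set name).  Empty
#'   (zero rows) when no set reaches `min_overlap`.
#' @export
gsea <- function(query, collection, min_overlap = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe were dropped")
  }
  q <- intersect(query, collection$universe)
  if (!length(q)) stop("no query genes remain within the universe")
  N <- length(collection$universe)
  n <- length(q)

  ks <- vapply(collection$sets, function(s) length(intersect(q, s)),
               integer(1))
  Ks <- lengths(collection$sets)
  keep <- ks >= min_overlap
  if (!any(keep)) {
    return(data.frame(set = character(0), category = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE))
  }
  res <- data.frame(
    set = names(collection$sets)[keep],
    category = if (is.null(collection$categories)) "all" else
      unname(collection$categories[keep]),
    k = unname(ks[keep]), K = unname(Ks[keep]), n = n, N = N,
    stringsAsFactors = FALSE)
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    fisher_enrichment_p(N, n, res$K[i], res$k[i])
  }, numeric(1))
  res$fdr <- NA_real_
  for (cat in unique(res$category)) {
    sel <- res$category == cat
    res$fdr[sel] <- bh_fdr(res$p_value[sel])
  }
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write enrichment results as TSV
#'
#' @param results A [gsea()] result data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gsea <- function(results, path) {
  out <- results
  out$p_value <- sprintf("%.12g", out$p_value)
  out$fdr <- sprintf("%.12g", out$fdr)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
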