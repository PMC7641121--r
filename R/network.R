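# Thresholded signed co-expression network: |PCC| cutoff combined with a
# mutual-rank admission rule (global MR bound, or membership in either
# endpoint's top-k partners by MR).

#' Edge-selection parameters for the co-expression network
#'
#' Defaults are the conventional strict thresholds for mutual-rank
#' networks on multi-tissue FPKM data: `|PCC| >= 0.7` combined with
#' "MR top 3 + MR <= 30", i.e. a pair is admitted when its mutual rank is
#' at most 30 *or* one endpoint is among the other's three best partners
#' by MR, always subject to the PCC cutoff.
#'
#' @param pcc_cutoff Minimum `|PCC|` for any edge, in \[0, 1\]
#'   (default 0.7).
#' @param top_k Number of best-MR partners per gene that are always
#'   admitted (default 3); 0 disables this route.
#' @param mr_cutoff Global mutual-rank bound (default 30; MR is never
#'   below 1).
#' @param min_expressed_tissues Expression-breadth filter applied before
#'   correlation (default 1).
#' @return An object of class `network_params`.
#' @export
network_params <- function(pcc_cutoff = 0.7, top_k = 3L, mr_cutoff = 30,
                           min_expressed_tissues = 1L) {
  if (pcc_cutoff < 0 || pcc_cutoff > 1) stop("pcc_cutoff must be in [0, 1]")
  if (top_k < 0) stop("top_k must be >= 0")
  if (mr_cutoff < 1) stop("mr_cutoff must be >= 1")
  structure(list(pcc_cutoff = as.numeric(pcc_cutoff),
                 top_k = as.integer(top_k),
                 mr_cutoff = as.numeric(mr_cutoff),
                 min_expressed_tissues = as.integer(min_expressed_tissues)),
            class = "network_params")
}

#' Select network edges by PCC and mutual-rank thresholds
#'
#' An unordered pair `(a, b)` becomes an edge iff
#' `|pcc[a,b]| >= pcc_cutoff` and (`mr[a,b] <= mr_cutoff` or `b` is among
#' `a`'s `top_k` partners by MR or `a` is among `b`'s).  Edges carry the
#' pair's PCC, MR and a sign label: `"positive"` when PCC > 0,
#' `"negative"` otherwise.
#'
#' @param store A [pcc_matrix()] result.
#' @param ranks The matching [rank_neighbors()] result.
#' @param params A [network_params()] object.
#' @return An object of class `coexpression_network`: list with `nodes`
#'   (all ranked gene ids), `edges` (data frame `gene_a`, `gene_b`
#'   with `gene_a < gene_b`, `pcc`, `mr`, `sign`) and `params`.
#' @export
select_edges <- function(store, ranks, params = network_params()) {
  stopifnot(inherits(store, "correlation_store"),
            inherits(ranks, "rank_store"),
            inherits(params, "network_params"))
  ids <- store$gene_ids
  if (!identical(ids, ranks$gene_ids)) {
    stop("correlation and rank stores cover different gene universes")
  }
  n <- length(ids)

  in_top <- matrix(FALSE, n, n)
  if (params$top_k > 0L && n > 1L) {
    k <- min(params$top_k, n - 1L)
    for (i in seq_len(n)) {
      ord <- order(ranks$mr[i, ], ids, na.last = TRUE)
      ord <- ord[ord != i]
      in_top[i, ord[seq_len(k)]] <- TRUE
    }
  }
  keep <- abs(store$pcc) >= params$pcc_cutoff &
    (ranks$mr <= params$mr_cutoff | in_top | t(in_top))
  keep[is.na(keep)] <- FALSE
  idx <- which(upper.tri(keep) & keep, arr.ind = TRUE)

  a <- ids[idx[, 1L]]
  b <- ids[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  pv <- store$pcc[idx]
  edges <- data.frame(gene_a = a, gene_b = b,
                      pcc = pv,
                      mr = ranks$mr[idx],
                      sign = ifelse(pv > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges, params = params),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: %d nodes, %d edges (%d positive, %d negative)\n",
    length(x$nodes), nrow(x$edges),
    sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}

sign_subnetwork <- function(net, sign) {
  edges <- net$edges[net$edges$sign == sign, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = net$nodes, edges = edges, params = net$params),
            class = "coexpression_network")
}

#' Positive-sign subnetwork (edges with PCC > 0)
#' @param net A `coexpression_network`.
#' @return A `coexpression_network` over the same nodes.
#' @export
positive_network <- function(net) sign_subnetwork(net, "positive")

#' Negative-sign subnetwork (edges with PCC < 0)
#' @param net A `coexpression_network`.
#' @return A `coexpression_network` over the same nodes.
#' @export
negative_network <- function(net) sign_subnetwork(net, "negative")

#' Convert a co-expression network to an igraph object
#'
#' @param net A `coexpression_network`.
#' @param connected_only Drop isolated nodes (default `FALSE`).
#' @return An undirected [igraph::igraph] graph with edge attributes
#'   `pcc`, `mr`, `sign`.
#' @export
as_igraph <- function(net, connected_only = FALSE) {
  stopifnot(inherits(net, "coexpression_network"))
  verts <- if (connected_only) {
    sort(unique(c(net$edges$gene_a, net$edges$gene_b)))
  } else {
    net$nodes
  }
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = verts)
}

#' Node degree histogram and power-law fit
#'
#' Tabulates node degrees and fits `log10(count) ~ log10(degree)` by
#' least squares over degrees with at least one node, the usual quick
#' check that a network's degree distribution decays like a power law
#' (scale-free behaviour shows as a negative slope with high R-squared).
#'
#' @param net A `coexpression_network` with at least one edge.
#' @return List with `histogram` (data frame `degree`, `n_nodes`, degrees
#'   >= 1 only), `n_isolated` (nodes with no edge, reported separately),
#'   `slope` and `r_squared` (NA when fewer than two distinct degrees).
#' @export
degree_distribution <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  if (nrow(net$edges) == 0L) stop("degree distribution of an empty network")
  deg <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                      levels = net$nodes))
  n_isolated <- sum(deg == 0L)
  tab <- table(as.integer(deg[deg > 0L]))
  hist <- data.frame(degree = as.integer(names(tab)),
                     n_nodes = as.integer(tab))
  slope <- r2 <- NA_real_
  if (nrow(hist) >= 2L) {
    fit <- stats::lm(log10(n_nodes) ~ log10(degree), data = hist)
    slope <- unname(stats::coef(fit)[2L])
    r2 <- summary(fit)$r.squared
  }
  list(histogram = hist, n_isolated = n_isolated,
       slope = slope, r_squared = r2)
}

#' Write a network edge list as TSV
#'
#' Canonical dialect: columns `gene_a`, `gene_b`, `pcc`, `mr`, `sign`
#' with `gene_a < gene_b` lexicographically.
#'
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  edges <- net$edges
  edges$pcc <- sprintf("%.12g", edges$pcc)
  edges$mr <- sprintf("%.12g", edges$mr)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV edge list back into a network object
#'
#' @param path Edge-list TSV written by [write_edge_list()].
#' @param nodes Optional full node universe; defaults to the genes seen
#'   in the edge list.
#' @return A `coexpression_network` (with `params = NULL`).
#' @export
read_edge_list <- function(path, nodes = NULL) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_a", "gene_b", "pcc", "mr", "sign")
  if (!all(needed %in% names(edges))) {
    stop("format error: edge list must have columns ",
         paste(needed, collapse = ", "))
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(nodes = nodes, edges = edges[needed], params = NULL),
            class = "coexpression_network")
}

#' Write per-node attributes (degree and tissue expression calls) as TSV
#'
#' @param net A `coexpression_network`.
#' @param profile A `TissueProfile` covering the network genes.
#' @param path Output path; columns `gene_id`, `degree`, then one logical
#'   `expressed_<tissue>` column per tissue.
#' @return Invisibly, `path`.
#' @export
write_node_attributes <- function(net, profile, path) {
  stopifnot(inherits(net, "coexpression_network"),
            inherits(profile, "TissueProfile"))
  deg <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                      levels = net$nodes))
  idx <- match(net$nodes, profile$gene_ids)
  if (anyNA(idx)) stop("network gene(s) missing from the tissue profile")
  flags <- profile$expressed[idx, , drop = FALSE]
  colnames(flags) <- paste0("expressed_", profile$tissue_ids)
  df <- data.frame(gene_id = net$nodes, degree = as.integer(deg),
                   flags, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
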