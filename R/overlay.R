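# MR-bounded neighborhood extraction and node overlays (tissue expression
# state, differential-expression class).

#' Extract the MR-bounded neighborhood of query genes
#'
#' Neighbors are genes sharing an edge of mutual rank at most `mr_max`
#' with any query; edges among the selected node set (queries plus
#' neighbors) are included when their own MR is at most `mr_max`, so the
#' subnetwork shows inter-neighbor links, not just spokes.
#'
#' @param net A `coexpression_network`.
#' @param queries Character vector of query gene ids (must exist in the
#'   network).
#' @param mr_max Mutual-rank bound; common query bounds are 30 and 50.
#' @return An object of class `overlaid_subnetwork`: list with `queries`,
#'   `nodes` (data frame `gene_id`, `role` in `"query"`/`"neighbor"`),
#'   `edges` (same columns as the parent edge list, copied unchanged),
#'   `mr_max` and `tissue` (`NULL` until [overlay_tissue()] is applied).
#' @export
neighborhood <- function(net, queries, mr_max) {
  stopifnot(inherits(net, "coexpression_network"))
  queries <- unique(as.character(queries))
  unknown <- setdiff(queries, net$nodes)
  if (length(unknown)) {
    stop("unknown query gene(s): ", paste(unknown, collapse = ", "))
  }
  stopifnot(is.numeric(mr_max), length(mr_max) == 1L)
  e <- net$edges
  touch <- e$mr <= mr_max & (e$gene_a %in% queries | e$gene_b %in% queries)
  neighbors <- setdiff(unique(c(e$gene_a[touch], e$gene_b[touch])), queries)
  members <- c(queries, sort(neighbors))
  sub <- e[e$mr <= mr_max & e$gene_a %in% members & e$gene_b %in% members, ,
           drop = FALSE]
  rownames(sub) <- NULL
  nodes <- data.frame(gene_id = members,
                      role = c(rep("query", length(queries)),
                               rep("neighbor", length(neighbors))),
                      stringsAsFactors = FALSE)
  structure(list(queries = queries, nodes = nodes, edges = sub,
                 mr_max = mr_max, tissue = NULL),
            class = "overlaid_subnetwork")
}

#' @export
print.overlaid_subnetwork <- function(x, ...) {
  cat(sprintf("overlaid_subnetwork: %d queries, %d neighbors, %d edges (MR <= %g)\n",
              length(x$queries), sum(x$nodes$role == "neighbor"),
              nrow(x$edges), x$mr_max))
  invisible(x)
}

#' Overlay tissue expression state onto a subnetwork
#'
#' Annotates every member node with its expressed/not-expressed call in
#' one tissue, taken from a `TissueProfile`.  Topology is unchanged;
#' applying the overlay twice with the same tissue is a no-op.
#'
#' @param sub An `overlaid_subnetwork`.
#' @param profile A `TissueProfile` covering all member genes.
#' @param tissue Tissue id present in the profile.
#' @return The subnetwork with an `expressed` column on `nodes` and the
#'   `tissue` field set.
#' @export
overlay_tissue <- function(sub, profile, tissue) {
  stopifnot(inherits(sub, "overlaid_subnetwork"),
            inherits(profile, "TissueProfile"))
  if (!tissue %in% profile$tissue_ids) {
    stop("unknown tissue: ", tissue)
  }
  idx <- match(sub$nodes$gene_id, profile$gene_ids)
  if (anyNA(idx)) {
    stop("gene(s) missing from the tissue profile: ",
         paste(sub$nodes$gene_id[is.na(idx)], collapse = ", "))
  }
  sub$nodes$expressed <- unname(profile$expressed[idx, tissue])
  sub$tissue <- tissue
  sub
}

#' Classify differential expression from log2 fold change and adjusted p
#'
#' A gene is `"up"` when `padj < alpha` and `log2fc > fc_threshold`,
#' `"down"` when `padj < alpha` and `log2fc < -fc_threshold`, otherwise
#' `"ns"`.  Inequalities are strict, so boundary values (padj exactly
#' `alpha`, |log2fc| exactly `fc_threshold`) are not significant.  The
#' conventional thresholds are `padj < 0.05` with `|log2FC| > 1`; a
#' stricter variant uses `|log2FC| > 2`.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param padj Numeric vector of BH-adjusted p-values in \[0, 1\].
#' @param fc_threshold Fold-change cutoff on the log2 scale (default 1).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Character vector in `c("up", "down", "ns")`.
#' @export
classify_deg <- function(log2fc, padj, fc_threshold = 1, alpha = 0.05) {
  stopifnot(is.numeric(log2fc), is.numeric(padj),
            length(log2fc) == length(padj))
  if (anyNA(padj) || any(padj < 0 | padj > 1)) {
    stop("padj values must lie in [0, 1]")
  }
  out <- rep("ns", length(log2fc))
  out[padj < alpha & log2fc > fc_threshold] <- "up"
  out[padj < alpha & log2fc < -fc_threshold] <- "down"
  out
}

#' Build a differential-expression table
#'
#' @param gene_id Character vector of gene ids.
#' @param log2fc,padj Per-gene log2 fold change and adjusted p-value.
#' @param fc_threshold,alpha Thresholds for [classify_deg()].
#' @return Data frame of class `deg_table` with columns `gene_id`,
#'   `log2fc`, `padj`, `class`.
#' @export
deg_table <- function(gene_id, log2fc, padj, fc_threshold = 1,
                      alpha = 0.05) {
  stopifnot(length(gene_id) == length(log2fc),
            length(gene_id) == length(padj))
  if (anyDuplicated(gene_id)) stop("duplicate gene id(s) in DEG table")
  df <- data.frame(gene_id = as.character(gene_id),
                   log2fc = as.numeric(log2fc),
                   padj = as.numeric(padj),
                   class = classify_deg(log2fc, padj, fc_threshold, alpha),
                   stringsAsFactors = FALSE)
  class(df) <- c("deg_table", "data.frame")
  df
}

#' Read a DEG table from TSV
#'
#' Expects columns `gene_id`, `log2FoldChange`, `padj` (the usual output
#' columns of count-based differential-expression tools; the fitting
#' itself is out of scope here and tables are consumed as given).
#'
#' @param path Path to the TSV.
#' @param fc_threshold,alpha Thresholds for [classify_deg()].
#' @return A [deg_table()].
#' @export
read_deg_table <- function(path, fc_threshold = 1, alpha = 0.05) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "log2FoldChange", "padj")
  if (!all(needed %in% names(df))) {
    stop("format error: DEG table must have columns ",
         paste(needed, collapse = ", "))
  }
  deg_table(df$gene_id, df$log2FoldChange, df$padj, fc_threshold, alpha)
}

#' Write a DEG table as TSV
#'
#' @param table A [deg_table()].
#' @param path Output path (columns `gene_id`, `log2FoldChange`, `padj`).
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(table, path) {
  stopifnot(inherits(table, "deg_table"))
  out <- data.frame(gene_id = table$gene_id,
                    log2FoldChange = sprintf("%.12g", table$log2fc),
                    padj = sprintf("%.12g", table$padj),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Overlay differential-expression classes onto a subnetwork
#'
#' Nodes present in the table receive its class; nodes absent from the
#' table are annotated `"ns"`.  Topology is unchanged.
#'
#' @param sub An `overlaid_subnetwork`.
#' @param table A [deg_table()].
#' @return The subnetwork with a `deg_class` column on `nodes`.
#' @export
overlay_deg <- function(sub, table) {
  stopifnot(inherits(sub, "overlaid_subnetwork"),
            inherits(table, "deg_table"))
  idx <- match(sub$nodes$gene_id, table$gene_id)
  cls <- table$class[idx]
  cls[is.na(idx)] <- "ns"
  sub$nodes$deg_class <- cls
  sub
}

#' Naive log2 fold change between two mean expression values
#'
#' Convenience plumbing only: `log2((mean_a + pseudo) / (mean_b +
#' pseudo))`.  Not a substitute for a count-based differential test.
#'
#' @param mean_a,mean_b Mean FPKM in the two conditions.
#' @param pseudo Pseudocount stabilising low expression (default 0.5).
#' @return Numeric log2 ratio.
#' @export
naive_log2_fc <- function(mean_a, mean_b, pseudo = 0.5) {
  log2((mean_a + pseudo) / (mean_b + pseudo))
}

#' Export a subnetwork as Cytoscape-compatible JSON
#'
#' Writes an `elements` object with `nodes[]` and `edges[]`, each entry a
#' `data` record (`id`, `source`, `target` plus attribute fields), the
#' dialect consumed by Cytoscape and Cytoscape.js.
#'
#' @param sub An `overlaid_subnetwork`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cytoscape_json <- function(sub, path) {
  stopifnot(inherits(sub, "overlaid_subnetwork"))
  nodes <- lapply(seq_len(nrow(sub$nodes)), function(i) {
    d <- as.list(sub$nodes[i, , drop = FALSE])
    names(d)[names(d) == "gene_id"] <- "id"
    if (!is.null(sub$tissue)) d$tissue <- sub$tissue
    list(data = d)
  })
  edges <- lapply(seq_len(nrow(sub$edges)), function(i) {
    e <- sub$edges[i, , drop = FALSE]
    list(data = list(id = paste0(e$gene_a, "|", e$gene_b),
                     source = e$gene_a, target = e$gene_b,
                     pcc = e$pcc, mr = e$mr, sign = e$sign))
  })
  jsonlite::write_json(list(elements = list(nodes = nodes, edges = edges)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
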