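# Batch entry points over the package's functions: simulate a seeded
# dataset, build a network from TSV inputs, query a built network.
# Every command writes a manifest (parameters + md5 checksums) next to
# its outputs; all outputs are deterministic given the inputs and seed.

write_manifest <- function(out_dir, command, parameters, files) {
  sums <- tools::md5sum(files)
  manifest <- list(command = command,
                   parameters = parameters,
                   outputs = lapply(seq_along(files), function(i) {
                     list(file = basename(files[i]),
                          md5 = unname(sums[i]))
                   }))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create output directory ", out_dir)
  }
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("I/O error: output directory not writable: ", out_dir)
  unlink(probe)
  invisible(out_dir)
}

#' Simulate a full dataset and write it to disk
#'
#' Writes the expression matrix and sample metadata (TSV), the planted
#' truth (TSV), matched plus decoy gene sets (GMT), a consistent DEG
#' table (TSV) and a manifest.  Byte-identical across runs with the same
#' configuration.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [sim_config()].
#' @param n_random_sets,random_set_size Decoy gene-set parameters passed
#'   to [simulate_gene_sets()].
#' @return Invisibly, a named character vector of the written files.
#' @export
cmd_simulate <- function(out_dir, cfg = sim_config(), n_random_sets = 50L,
                         random_set_size = 25L) {
  ensure_out_dir(out_dir)
  sim <- simulate_expression(cfg)
  sets <- simulate_gene_sets(sim$truth, n_random_sets, random_set_size,
                             seed = cfg$seed)
  deg <- simulate_deg_table(sim$truth, seed = cfg$seed)

  files <- c(matrix = file.path(out_dir, "matrix.tsv"),
             meta = file.path(out_dir, "samples.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             gmt = file.path(out_dir, "gene_sets.gmt"),
             deg = file.path(out_dir, "deg_table.tsv"))
  write_expression(sim$matrix, files[["matrix"]], files[["meta"]])
  write_truth(sim$truth, files[["truth"]])
  write_gmt(sets, files[["gmt"]])
  write_deg_table(deg, files[["deg"]])
  write_manifest(out_dir, "simulate",
                 c(unclass(cfg),
                   list(n_random_sets = n_random_sets,
                        random_set_size = random_set_size)),
                 files)
  invisible(files)
}

#' Build a co-expression network from TSV inputs
#'
#' Runs the full construction pipeline -- load, replicate summarisation,
#' expression filtering, all-pairs PCC, mutual ranks, edge selection --
#' and writes the edge list, node attributes, degree histogram, a JSON
#' summary and a manifest.
#'
#' @param matrix_path,meta_path Expression matrix and sample metadata
#'   TSVs (the [load_expression()] dialect).
#' @param out_dir Output directory.
#' @param params A [network_params()].
#' @param expression_threshold FPKM floor for expression calls
#'   (default 0.3).
#' @param use_tissue_medians,log_transform Passed to [pcc_matrix()].
#' @return Invisibly, a list with `network`, `profile`, `summary` and
#'   `files`.
#' @export
cmd_build <- function(matrix_path, meta_path, out_dir,
                      params = network_params(),
                      expression_threshold = 0.3,
                      use_tissue_medians = FALSE, log_transform = FALSE) {
  ensure_out_dir(out_dir)
  m <- load_expression(matrix_path, meta_path)
  profile <- summarize_replicates(m, expression_threshold)
  store <- pcc_matrix(m,
                      min_expressed_tissues = params$min_expressed_tissues,
                      expression_threshold = expression_threshold,
                      use_tissue_medians = use_tissue_medians,
                      log_transform = log_transform)
  ranks <- rank_neighbors(store)
  net <- select_edges(store, ranks, params)

  connected <- unique(c(net$edges$gene_a, net$edges$gene_b))
  dd <- if (nrow(net$edges) > 0L) degree_distribution(net) else
    list(histogram = data.frame(degree = integer(0), n_nodes = integer(0)),
         n_isolated = length(net$nodes), slope = NA_real_,
         r_squared = NA_real_)
  summary <- list(
    n_genes_input = nrow(m$values),
    n_genes_ranked = length(store$gene_ids),
    n_nodes_connected = length(connected),
    coverage_pct = 100 * length(connected) / nrow(m$values),
    n_edges = nrow(net$edges),
    n_positive_edges = sum(net$edges$sign == "positive"),
    n_negative_edges = sum(net$edges$sign == "negative"),
    degree_slope = dd$slope,
    degree_r_squared = dd$r_squared)

  files <- c(edges = file.path(out_dir, "edges.tsv"),
             nodes = file.path(out_dir, "node_attributes.tsv"),
             degrees = file.path(out_dir, "degree_histogram.tsv"),
             summary = file.path(out_dir, "summary.json"))
  write_edge_list(net, files[["edges"]])
  write_node_attributes(net, profile, files[["nodes"]])
  utils::write.table(dd$histogram, files[["degrees"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_manifest(out_dir, "build",
                 c(unclass(params),
                   list(expression_threshold = expression_threshold,
                        use_tissue_medians = use_tissue_medians,
                        log_transform = log_transform,
                        matrix_md5 = unname(tools::md5sum(matrix_path)),
                        meta_md5 = unname(tools::md5sum(meta_path)))),
                 files)
  invisible(list(network = net, profile = profile, summary = summary,
                 files = files))
}

#' Query a built network: neighborhood, overlays and enrichment
#'
#' Reads a previously built edge list, extracts the MR-bounded
#' neighborhood of the query genes, optionally overlays one tissue's
#' expression state and/or a DEG table, writes the subnetwork as TSV and
#' Cytoscape JSON, and -- when gene sets are supplied -- runs enrichment
#' of the subnetwork members.
#'
#' @param edges_path Edge-list TSV from [cmd_build()].
#' @param queries Character vector of query gene ids.
#' @param mr_max Mutual-rank bound for the neighborhood.
#' @param out_dir Output directory.
#' @param matrix_path,meta_path Optional expression TSVs; required for a
#'   tissue overlay.
#' @param tissue Optional tissue id to overlay.
#' @param deg_path Optional DEG table TSV to overlay.
#' @param gmt_path Optional GMT file for enrichment of the subnetwork
#'   members (universe defaults to the network's genes).
#' @param expression_threshold FPKM floor for the tissue overlay.
#' @return Invisibly, a list with `subnetwork`, `gsea` (or `NULL`) and
#'   `files`.
#' @export
cmd_query <- function(edges_path, queries, mr_max, out_dir,
                      matrix_path = NULL, meta_path = NULL, tissue = NULL,
                      deg_path = NULL, gmt_path = NULL,
                      expression_threshold = 0.3) {
  ensure_out_dir(out_dir)
  net <- read_edge_list(edges_path)
  sub <- neighborhood(net, queries, mr_max)
  if (!is.null(tissue)) {
    if (is.null(matrix_path) || is.null(meta_path)) {
      stop("a tissue overlay needs matrix_path and meta_path")
    }
    m <- load_expression(matrix_path, meta_path)
    profile <- summarize_replicates(m, expression_threshold)
    sub <- overlay_tissue(sub, profile, tissue)
  }
  if (!is.null(deg_path)) {
    sub <- overlay_deg(sub, read_deg_table(deg_path))
  }

  files <- c(sub_tsv = file.path(out_dir, "subnetwork_edges.tsv"),
             sub_nodes = file.path(out_dir, "subnetwork_nodes.tsv"),
             sub_json = file.path(out_dir, "subnetwork.json"))
  sub_net <- structure(list(nodes = sub$nodes$gene_id, edges = sub$edges,
                            params = NULL),
                       class = "coexpression_network")
  write_edge_list(sub_net, files[["sub_tsv"]])
  utils::write.table(sub$nodes, files[["sub_nodes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_cytoscape_json(sub, files[["sub_json"]])

  enr <- NULL
  if (!is.null(gmt_path)) {
    collection <- read_gmt(gmt_path, universe = net$nodes)
    enr <- gsea(sub$nodes$gene_id, collection)
    files <- c(files, gsea = file.path(out_dir, "gsea.tsv"))
    write_gsea(enr, files[["gsea"]])
  }
  write_manifest(out_dir, "query",
                 list(queries = queries, mr_max = mr_max,
                      tissue = tissue,
                      expression_threshold = expression_threshold,
                      edges_md5 = unname(tools::md5sum(edges_path))),
                 files)
  invisible(list(subnetwork = sub, gsea = enr, files = files))
}
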