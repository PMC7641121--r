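test_that("pairwise correlation matches hand-evaluated cases", {
  expect_equal(pcc(c(1, 2, 3), c(2, 4, 6)), 1.0, tolerance = 1e-12)
  expect_equal(pcc(c(1, 2, 3), c(6, 4, 2)), -1.0, tolerance = 1e-12)
  # centered cross sum 4, each centered square sum 5 -> 4/5
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8, tolerance = 1e-12)
  expect_true(is.na(pcc(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pcc(1, c(1, 2)), "equal length")
  expect_error(pcc(1, 2), "n >= 2")
})

test_that("the correlation matrix equals the pairwise oracle and masks constants", {
  sim <- simulate_expression(sim_config(n_modules = 4, module_size = 40,
                                        n_background_genes = 40,
                                        n_silent_genes = 0, seed = 21))
  st <- pcc_matrix(sim$matrix)
  expect_length(st$gene_ids, 200)
  ref <- oracle_pcc_matrix(sim$matrix$values[st$gene_ids, ])
  expect_equal(st$pcc, ref, tolerance = 1e-12)
  expect_identical(st$pcc, t(st$pcc))

  # one constant (zero-variance) gene is masked; others unaffected
  v <- sim$matrix$values[1:20, ]
  v["gene00003", ] <- 7
  m <- tiny_matrix(v, tissues = sim$matrix$samples$tissue)
  st2 <- pcc_matrix(m)
  expect_false("gene00003" %in% st2$gene_ids)
  expect_identical(st2$dropped$reason[st2$dropped$gene_id == "gene00003"],
                   "zero_variance")
  expect_error(pcc_matrix(tiny_matrix(v[1:2, ] * 0 + 0.1,
                                      tissues = sim$matrix$samples$tissue)),
               "fewer than 2")
})

test_that("neighbor ranks sort by |PCC| and mutual ranks are geometric means", {
  # 4 genes with known |pcc| from a: b 0.9, c 0.5, d 0.7
  ids <- c("a", "b", "c", "d")
  pc <- diag(4)
  pc[1, 2] <- pc[2, 1] <- 0.9
  pc[1, 3] <- pc[3, 1] <- -0.5
  pc[1, 4] <- pc[4, 1] <- 0.7
  pc[2, 3] <- pc[3, 2] <- 0.2
  pc[2, 4] <- pc[4, 2] <- 0.1
  pc[3, 4] <- pc[4, 3] <- 0.3
  dimnames(pc) <- list(ids, ids)
  st <- structure(list(gene_ids = ids, pcc = pc,
                       dropped = data.frame(gene_id = character(0),
                                            reason = character(0))),
                  class = "correlation_store")
  rk <- rank_neighbors(st)
  expect_identical(unname(rk$rank["a", c("b", "d", "c")]), c(1L, 2L, 3L))
  # rank[a,b] = 1 and rank[b,a] = 1 -> MR exactly 1
  expect_equal(rk$mr["a", "b"], 1.0)
  # MR is the geometric mean: rank 2 and 3 -> sqrt(6)
  expect_equal(rk$mr["a", "d"], sqrt(rk$rank["a", "d"] * rk$rank["d", "a"]))
  expect_equal(sqrt(2 * 8), 4.0)  # the geometric-mean form at ranks (2, 8)

  # each row is a permutation of 1..(n-1); MR symmetric and >= 1
  sim <- simulate_expression(sim_config(n_modules = 2, module_size = 10,
                                        n_background_genes = 30,
                                        n_silent_genes = 0, seed = 3))
  st2 <- pcc_matrix(sim$matrix)
  rk2 <- rank_neighbors(st2)
  for (i in seq_along(st2$gene_ids)) {
    expect_setequal(rk2$rank[i, -i], seq_len(length(st2$gene_ids) - 1L))
  }
  expect_equal(rk2$mr, t(rk2$mr))
  expect_true(all(rk2$mr >= 1, na.rm = TRUE))
  expect_equal(rk2$mr, oracle_mr(rk2$rank), tolerance = 1e-9)
})

test_that("ranks agree with the counting oracle on seeded data", {
  sim <- simulate_expression(sim_config(n_modules = 2, module_size = 15,
                                        n_background_genes = 20,
                                        n_silent_genes = 0, seed = 8))
  st <- pcc_matrix(sim$matrix)
  rk <- rank_neighbors(st)
  ref <- oracle_rank(st$pcc)
  expect_equal(unname(rk$rank), unname(ref))
})

test_that("edge selection reproduces the exhaustive rule scan", {
  sim <- simulate_expression(sim_config(n_modules = 2, module_size = 15,
                                        n_background_genes = 20,
                                        n_silent_genes = 0, seed = 13))
  st <- pcc_matrix(sim$matrix)
  rk <- rank_neighbors(st)
  for (params in list(network_params(),
                      network_params(pcc_cutoff = 0.5, top_k = 1,
                                     mr_cutoff = 5),
                      network_params(pcc_cutoff = 0.9, top_k = 0,
                                     mr_cutoff = 10))) {
    net <- select_edges(st, rk, params)
    ref <- oracle_edges(st$pcc, rk$mr, params$pcc_cutoff, params$top_k,
                        params$mr_cutoff)
    expect_identical(net$edges$gene_a, ref$gene_a)
    expect_identical(net$edges$gene_b, ref$gene_b)
    expect_equal(net$edges$pcc, ref$pcc, tolerance = 1e-12)
    expect_identical(net$edges$sign, ref$sign)
  }
})

test_that("edge admission examples: both cutoffs are a conjunction with two MR routes", {
  # pair with |pcc| = 0.9 and mr = 25 satisfies both stated cutoffs;
  # |pcc| = 0.5 with excellent mr = 2 still fails the PCC conjunct
  ids <- sprintf("g%02d", 1:6)
  set.seed(2)
  base <- matrix(runif(6 * 8), 6, 8, dimnames = list(ids, NULL))
  pc <- cor(t(base))
  st <- structure(list(gene_ids = ids, pcc = pc,
                       dropped = data.frame(gene_id = character(0),
                                            reason = character(0))),
                  class = "correlation_store")
  rk <- rank_neighbors(st)
  net <- select_edges(st, rk, network_params(pcc_cutoff = 0.7, top_k = 0,
                                             mr_cutoff = 30))
  in_net <- paste(net$edges$gene_a, net$edges$gene_b)
  for (i in 1:5) for (j in (i + 1):6) {
    key <- paste(ids[i], ids[j])
    if (abs(pc[i, j]) >= 0.7 && rk$mr[i, j] <= 30) {
      expect_true(key %in% in_net)
    }
    if (abs(pc[i, j]) < 0.7) expect_false(key %in% in_net)
  }
})

test_that("zero-noise planted modules yield complete, correctly signed cliques", {
  cfg <- sim_config(n_modules = 3, module_size = 8, n_background_genes = 0,
                    n_silent_genes = 4, frac_negative = 0.25, noise_sd = 0,
                    seed = 17)
  sim <- simulate_expression(cfg)
  st <- pcc_matrix(sim$matrix)
  net <- select_edges(st, rank_neighbors(st), network_params())
  truth <- sim$truth
  key <- paste(net$edges$gene_a, net$edges$gene_b)
  mods <- names(truth$module_of_gene)[
    !truth$module_of_gene %in% c("background", "silent")]
  for (i in seq_along(mods)) for (j in seq_along(mods)) {
    a <- mods[i]; b <- mods[j]
    if (a >= b || truth$module_of_gene[a] != truth$module_of_gene[b]) next
    k <- which(key == paste(a, b))
    expect_length(k, 1)
    same <- truth$sign_of_gene[a] == truth$sign_of_gene[b]
    expect_identical(net$edges$sign[k],
                     if (same) "positive" else "negative")
  }
})

test_that("edge sets are nested under tighter cutoffs", {
  sim <- simulate_expression(sim_config(n_modules = 3, module_size = 12,
                                        n_background_genes = 30,
                                        n_silent_genes = 0, seed = 23))
  st <- pcc_matrix(sim$matrix)
  rk <- rank_neighbors(st)
  key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  e_mr30 <- key(select_edges(st, rk, network_params(mr_cutoff = 30)))
  e_mr10 <- key(select_edges(st, rk, network_params(mr_cutoff = 10)))
  expect_true(all(e_mr10 %in% e_mr30))
  e_p07 <- key(select_edges(st, rk, network_params(pcc_cutoff = 0.7)))
  e_p08 <- key(select_edges(st, rk, network_params(pcc_cutoff = 0.8)))
  expect_true(all(e_p08 %in% e_p07))
})

test_that("sign subnetworks partition the edge set", {
  sim <- simulate_expression(sim_config(n_modules = 3, module_size = 10,
                                        n_background_genes = 40,
                                        n_silent_genes = 0,
                                        frac_negative = 0.3, seed = 31))
  st <- pcc_matrix(sim$matrix)
  net <- select_edges(st, rank_neighbors(st))
  pos <- positive_network(net)$edges
  neg <- negative_network(net)$edges
  expect_identical(nrow(pos) + nrow(neg), nrow(net$edges))
  expect_gt(nrow(neg), 0)
  expect_length(intersect(paste(pos$gene_a, pos$gene_b),
                          paste(neg$gene_a, neg$gene_b)), 0)
  expect_true(all(pos$pcc > 0) && all(neg$pcc < 0))
})

test_that("degree histograms conserve nodes and modular networks decay", {
  # star: one hub with 5 leaves
  ids <- c("hub", paste0("leaf", 1:5))
  edges <- data.frame(gene_a = pmin("hub", paste0("leaf", 1:5)),
                      gene_b = pmax("hub", paste0("leaf", 1:5)),
                      pcc = 0.9, mr = 1, sign = "positive",
                      stringsAsFactors = FALSE)
  star <- structure(list(nodes = c(ids, "lonely"), edges = edges,
                         params = NULL), class = "coexpression_network")
  dd <- degree_distribution(star)
  expect_identical(dd$histogram,
                   data.frame(degree = c(1L, 5L), n_nodes = c(5L, 1L)))
  expect_identical(dd$n_isolated, 1L)
  expect_identical(sum(dd$histogram$n_nodes) + dd$n_isolated,
                   length(star$nodes))

  # a modular network with a broad background: many low-degree nodes,
  # few hubs, so the log-log histogram decays
  sim <- simulate_expression(sim_config(n_modules = 6, module_size = 10,
                                        n_background_genes = 150,
                                        n_silent_genes = 0, seed = 5))
  st <- pcc_matrix(sim$matrix)
  net <- select_edges(st, rank_neighbors(st))
  dd2 <- degree_distribution(net)
  expect_lt(dd2$slope, 0)
  # recompute the fit from the histogram it returns
  fit <- stats::lm(log10(n_nodes) ~ log10(degree), data = dd2$histogram)
  expect_equal(dd2$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_identical(sum(dd2$histogram$n_nodes) + dd2$n_isolated,
                   length(net$nodes))

  empty <- structure(list(nodes = ids, edges = edges[0, ], params = NULL),
                     class = "coexpression_network")
  expect_error(degree_distribution(empty), "empty")
})

test_that("edge lists round-trip through the TSV dialect", {
  sim <- simulate_expression(sim_config(n_modules = 2, module_size = 8,
                                        n_background_genes = 10,
                                        n_silent_genes = 0, seed = 4))
  st <- pcc_matrix(sim$matrix)
  net <- select_edges(st, rank_neighbors(st))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_identical(back$edges$gene_a, net$edges$gene_a)
  expect_identical(back$edges$gene_b, net$edges$gene_b)
  expect_true(all(back$edges$gene_a < back$edges$gene_b))
  expect_equal(back$edges$pcc, net$edges$pcc, tolerance = 1e-10)
  expect_equal(back$edges$mr, net$edges$mr, tolerance = 1e-10)
})
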