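# Seeded synthetic expression data with planted co-expression structure.
# Each public operation draws from its own RNG stream keyed by
# (seed, operation name), so adding operations never perturbs existing
# fixtures.

op_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (abs(as.integer(seed)) + sum(utf8ToInt(op)) * 131L) %% 2147483647L
}

#' Configuration for the synthetic expression simulator
#'
#' Describes a multi-tissue RNA-seq design with planted co-expressed gene
#' modules: each module follows a latent per-tissue activity profile,
#' optionally with a fraction of members anti-correlated to it;
#' background genes follow independent profiles and silent genes stay
#' below the expression-call floor in every sample.
#'
#' @param n_tissues Number of tissues (default 10).
#' @param n_replicates Biological replicates per tissue (default 3).
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per module.
#' @param n_background_genes Genes with independent latent profiles.
#' @param n_silent_genes Genes drawn uniformly in \[0, 0.3\] FPKM, hence
#'   never called expressed at the 0.3 floor.
#' @param frac_negative Fraction of each module's genes whose profile is
#'   reflected about the module maximum, giving exact anti-correlation at
#'   zero noise.  Defaults to 0: planted modules are positively coherent
#'   programs unless signed structure is requested.
#' @param noise_sd Standard deviation of multiplicative log-normal
#'   replicate noise on the log2 scale (default 0.2).
#' @param expression_scale Mean FPKM magnitude of expressed genes
#'   (default 50).
#' @param n_deg_genes Number of genes planted as differentially expressed
#'   between two simulated cultivars (default 50).
#' @param seed Integer random seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_tissues = 10L, n_replicates = 3L,
                       n_modules = 20L, module_size = 25L,
                       n_background_genes = 100L, n_silent_genes = 50L,
                       frac_negative = 0, noise_sd = 0.2,
                       expression_scale = 50, n_deg_genes = 50L,
                       seed = 1L) {
  cfg <- list(n_tissues = as.integer(n_tissues),
              n_replicates = as.integer(n_replicates),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              n_background_genes = as.integer(n_background_genes),
              n_silent_genes = as.integer(n_silent_genes),
              frac_negative = as.numeric(frac_negative),
              noise_sd = as.numeric(noise_sd),
              expression_scale = as.numeric(expression_scale),
              n_deg_genes = as.integer(n_deg_genes),
              seed = as.integer(seed))
  counts <- c(cfg$n_tissues, cfg$n_replicates, cfg$n_modules,
              cfg$module_size, cfg$n_background_genes, cfg$n_silent_genes,
              cfg$n_deg_genes)
  if (any(counts < 0L)) stop("all counts in a sim_config must be >= 0")
  if (cfg$frac_negative < 0 || cfg$frac_negative > 1) {
    stop("frac_negative must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$expression_scale <= 0) stop("expression_scale must be > 0")
  structure(cfg, class = "sim_config")
}

# Draw module archetypes sequentially, rejecting candidates that correlate
# too strongly (|r| > 0.45) with an already accepted archetype.  Planted
# modules are meant to be distinct, recoverable expression programs, so
# archetype correlations are kept well below the default |PCC| >= 0.7
# edge cutoff, leaving margin for noise-induced fluctuation of gene-level
# correlations.
draw_archetypes <- function(n_modules, n_tissues, max_cor = 0.45,
                            max_tries = 5000L, max_restarts = 20L) {
  for (restart in seq_len(max_restarts)) {
    arch <- matrix(NA_real_, n_modules, n_tissues)
    failed <- FALSE
    for (m in seq_len(n_modules)) {
      ok <- FALSE
      for (i in seq_len(max_tries)) {
        cand <- stats::runif(n_tissues, 0.05, 1)
        if (m == 1L || n_tissues < 3L) {
          ok <- TRUE
        } else {
          prev <- t(arch[seq_len(m - 1L), , drop = FALSE])
          ok <- max(abs(suppressWarnings(stats::cor(cand, prev)))) <= max_cor
        }
        if (ok) break
      }
      if (!ok) { failed <- TRUE; break }
      arch[m, ] <- cand
    }
    if (!failed) return(arch)
  }
  stop("could not draw ", n_modules,
       " mutually distinct module archetypes over ", n_tissues,
       " tissues; reduce n_modules or increase n_tissues")
}

#' Simulate an FPKM expression matrix with planted modules
#'
#' Each planted module receives a random latent per-tissue activity
#' vector; a member gene's tissue mean is `expression_scale * latent`
#' (or `expression_scale * (max(latent) - latent)` for anti-correlated
#' members, which yields PCC exactly -1 at zero noise).  Replicate values
#' are the tissue mean times `2^e` with `e ~ Normal(0, noise_sd)`.
#' Background genes follow independent latent vectors and silent genes
#' are uniform in \[0, 0.3\].  Output is deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (class `sim_truth`): `module_of_gene` (named character:
#'   `"module01"`..., `"background"` or `"silent"`), `sign_of_gene`
#'   (named, +1/-1 for module genes, NA otherwise), `tissue_archetype`
#'   (module x tissue latent matrix) and `planted_deg` (data frame
#'   `gene_id`, `true_log2fc` between two simulated cultivars).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n_genes <- cfg$n_modules * cfg$module_size +
    cfg$n_background_genes + cfg$n_silent_genes
  if (cfg$n_tissues == 0L || n_genes == 0L) {
    stop("simulation needs at least one tissue and one gene")
  }
  if (cfg$n_replicates < 1L) stop("simulation needs at least one replicate")

  withr::with_seed(op_seed(cfg$seed, "simulate_expression"), {
    tissues <- sprintf("T%02d", seq_len(cfg$n_tissues))
    samples <- data.frame(
      sample_id = paste0(rep(tissues, each = cfg$n_replicates), "_R",
                         rep(seq_len(cfg$n_replicates), cfg$n_tissues)),
      tissue = rep(tissues, each = cfg$n_replicates),
      replicate = rep(seq_len(cfg$n_replicates), cfg$n_tissues),
      cultivar = "cv1",
      stringsAsFactors = FALSE)

    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    n_mod_genes <- cfg$n_modules * cfg$module_size
    module_ids <- sprintf("module%02d", seq_len(cfg$n_modules))
    module_of <- c(rep(module_ids, each = cfg$module_size),
                   rep("background", cfg$n_background_genes),
                   rep("silent", cfg$n_silent_genes))
    names(module_of) <- gene_ids

    n_neg <- round(cfg$frac_negative * cfg$module_size)
    sign_in_module <- rep(c(rep(1L, cfg$module_size - n_neg),
                            rep(-1L, n_neg)), cfg$n_modules)
    sign_of <- rep(NA_integer_, n_genes)
    sign_of[seq_len(n_mod_genes)] <- sign_in_module
    names(sign_of) <- gene_ids

    arch <- if (cfg$n_modules > 0L) {
      a <- draw_archetypes(cfg$n_modules, cfg$n_tissues)
      dimnames(a) <- list(module_ids, tissues)
      a
    } else {
      matrix(numeric(0), 0L, cfg$n_tissues, dimnames = list(NULL, tissues))
    }

    # gene x tissue matrix of mean FPKM
    means <- matrix(0, n_genes, cfg$n_tissues,
                    dimnames = list(gene_ids, tissues))
    for (m in seq_len(cfg$n_modules)) {
      rows <- (m - 1L) * cfg$module_size + seq_len(cfg$module_size)
      lat <- arch[m, ]
      for (r in rows) {
        prof <- if (sign_of[r] == 1L) lat else max(lat) - lat
        means[r, ] <- cfg$expression_scale * prof
      }
    }
    if (cfg$n_background_genes > 0L) {
      bg_rows <- n_mod_genes + seq_len(cfg$n_background_genes)
      means[bg_rows, ] <- cfg$expression_scale *
        matrix(stats::runif(cfg$n_background_genes * cfg$n_tissues, 0.05, 1),
               cfg$n_background_genes, cfg$n_tissues)
    }

    n_samples <- nrow(samples)
    tissue_of_sample <- match(samples$tissue, tissues)
    values <- means[, tissue_of_sample, drop = FALSE]
    colnames(values) <- samples$sample_id
    if (cfg$noise_sd > 0) {
      eps <- matrix(stats::rnorm(n_genes * n_samples, 0, cfg$noise_sd),
                    n_genes, n_samples)
      values <- values * 2^eps
    }
    if (cfg$n_silent_genes > 0L) {
      sil_rows <- n_mod_genes + cfg$n_background_genes +
        seq_len(cfg$n_silent_genes)
      values[sil_rows, ] <- matrix(
        stats::runif(cfg$n_silent_genes * n_samples, 0, 0.3),
        cfg$n_silent_genes, n_samples)
    }

    # planted DEGs between two notional cultivars, among non-silent genes
    n_cand <- n_mod_genes + cfg$n_background_genes
    n_deg <- min(cfg$n_deg_genes, n_cand)
    planted_deg <- if (n_deg > 0L) {
      idx <- sort(sample.int(n_cand, n_deg))
      data.frame(gene_id = gene_ids[idx],
                 true_log2fc = sample(c(-1, 1), n_deg, replace = TRUE) *
                   stats::runif(n_deg, 1.5, 4),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = character(0), true_log2fc = numeric(0))
    }

    truth <- structure(list(module_of_gene = module_of,
                            sign_of_gene = sign_of,
                            tissue_archetype = arch,
                            planted_deg = planted_deg,
                            config = cfg),
                       class = "sim_truth")
    list(matrix = expression_matrix(values, samples), truth = truth)
  })
}

#' Gene sets matched to the planted modules, plus random decoys
#'
#' Builds one gene set per planted module (exactly its member genes,
#' category `"planted"`) and `n_random_sets` decoy sets drawn uniformly
#' from the simulated gene universe (category `"random"`).
#'
#' @param truth A `sim_truth` from [simulate_expression()].
#' @param n_random_sets Number of random decoy sets (default 50).
#' @param random_set_size Size of each random set (default 25).
#' @param seed Integer seed for the decoy draw.
#' @return A [gene_set_collection()] over the full simulated universe.
#' @export
simulate_gene_sets <- function(truth, n_random_sets = 50L,
                               random_set_size = 25L, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  universe <- names(truth$module_of_gene)
  if (n_random_sets > 0L && random_set_size > length(universe)) {
    stop("random_set_size exceeds the size of the gene universe")
  }
  modules <- setdiff(unique(truth$module_of_gene), c("background", "silent"))
  sets <- lapply(modules, function(m) {
    names(truth$module_of_gene)[truth$module_of_gene == m]
  })
  names(sets) <- vapply(modules, paste0, character(1), "_set")
  categories <- rep("planted", length(sets))
  if (n_random_sets > 0L) {
    rand <- withr::with_seed(op_seed(seed, "simulate_gene_sets"), {
      lapply(seq_len(n_random_sets), function(i) {
        sort(sample(universe, random_set_size))
      })
    })
    names(rand) <- sprintf("random%03d_set", seq_len(n_random_sets))
    sets <- c(sets, rand)
    categories <- c(categories, rep("random", n_random_sets))
  }
  names(categories) <- names(sets)
  gene_set_collection(sets, universe, categories)
}

#' Simulate a differential-expression table consistent with planted truth
#'
#' Planted DEGs keep their true log2 fold change (|log2FC| >= 1.5) and
#' receive adjusted p-values below 0.01; all other non-silent genes get
#' |log2FC| < 0.5 with adjusted p-values uniform on (0.05, 1), so the
#' conventional `Padj < 0.05, |log2FC| > 1` rule recovers exactly the
#' planted set.
#'
#' @param truth A `sim_truth` from [simulate_expression()].
#' @param seed Integer seed.
#' @param fc_threshold,alpha Classification thresholds passed to
#'   [classify_deg()].
#' @return A data frame of class `deg_table` with columns `gene_id`,
#'   `log2fc`, `padj`, `class`.
#' @export
simulate_deg_table <- function(truth, seed = 1L, fc_threshold = 1,
                               alpha = 0.05) {
  stopifnot(inherits(truth, "sim_truth"))
  genes <- names(truth$module_of_gene)[truth$module_of_gene != "silent"]
  withr::with_seed(op_seed(seed, "simulate_deg_table"), {
    lfc <- stats::runif(length(genes), -0.49, 0.49)
    padj <- stats::runif(length(genes), 0.051, 0.999)
    names(lfc) <- names(padj) <- genes
    pd <- truth$planted_deg
    lfc[pd$gene_id] <- pd$true_log2fc
    padj[pd$gene_id] <- stats::runif(nrow(pd), 1e-8, 0.0099)
    deg_table(genes, unname(lfc), unname(padj),
              fc_threshold = fc_threshold, alpha = alpha)
  })
}

#' Write planted simulation truth as TSV
#'
#' @param truth A `sim_truth`.
#' @param path Output path; one row per gene with its module assignment,
#'   sign, and planted log2 fold change (NA when not a planted DEG).
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  genes <- names(truth$module_of_gene)
  fc <- truth$planted_deg$true_log2fc[match(genes, truth$planted_deg$gene_id)]
  df <- data.frame(gene_id = genes,
                   module = unname(truth$module_of_gene),
                   sign = unname(truth$sign_of_gene),
                   true_log2fc = fc,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
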