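# Independent reference implementations used as oracles.  These are
# deliberately naive: direct transcription of the defining formulas,
# sharing no code path with the package.

# Pearson correlation written out as the ratio of the centered
# cross-product sum to the product of root centered square sums.
oracle_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# All-pairs correlation by looping over every pair.
oracle_pcc_matrix <- function(values) {
  n <- nrow(values)
  out <- diag(n)
  dimnames(out) <- list(rownames(values), rownames(values))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        out[i, j] <- out[j, i] <- oracle_pcc(values[i, ], values[j, ])
      }
    }
  }
  out
}

# Asymmetric neighbor rank by counting: rank[a, b] is one plus the number
# of partners that beat b in a's list (higher |pcc|, or equal |pcc| with a
# lexicographically smaller id).
oracle_rank <- function(pcc_mat) {
  ids <- rownames(pcc_mat)
  n <- length(ids)
  a <- abs(pcc_mat)
  rk <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      others <- setdiff(seq_len(n), i)
      beats <- sum(a[i, others] > a[i, j] |
                     (a[i, others] == a[i, j] & ids[others] < ids[j]))
      rk[i, j] <- 1 + beats
    }
  }
  rk
}

oracle_mr <- function(rank_mat) sqrt(rank_mat * t(rank_mat))

# Edge selection by exhaustive pair scan; top-k membership computed by
# counting partners with strictly better (smaller) MR, ties broken by id.
oracle_edges <- function(pcc_mat, mr_mat, pcc_cutoff = 0.7, top_k = 3,
                         mr_cutoff = 30) {
  ids <- rownames(pcc_mat)
  n <- length(ids)
  in_top <- function(i, j) {
    if (top_k == 0) return(FALSE)
    others <- setdiff(seq_len(n), i)
    better <- sum(mr_mat[i, others] < mr_mat[i, j] |
                    (mr_mat[i, others] == mr_mat[i, j] &
                       ids[others] < ids[j]))
    better < top_k
  }
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (abs(pcc_mat[i, j]) < pcc_cutoff) next
      if (!(mr_mat[i, j] <= mr_cutoff || in_top(i, j) || in_top(j, i))) next
      a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, pcc = pcc_mat[i, j], mr = mr_mat[i, j],
        sign = if (pcc_mat[i, j] > 0) "positive" else "negative",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pcc = numeric(0), mr = numeric(0),
                      sign = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Step-up BH adjustment straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  q <- sorted * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# A tiny hand-built expression matrix: 2 tissues x 3 replicates.
tiny_matrix <- function(values, tissues = NULL) {
  n_samp <- ncol(values)
  if (is.null(tissues)) {
    tissues <- rep(sprintf("T%02d", seq_len(ceiling(n_samp / 3))),
                   each = 3)[seq_len(n_samp)]
  }
  meta <- data.frame(sample_id = colnames(values), tissue = tissues,
                     replicate = stats::ave(seq_len(n_samp), tissues,
                                            FUN = seq_along),
                     cultivar = "cv1", stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}

# Random non-negative matrix with named dims.
random_matrix <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rexp(n_genes * n_samples, rate = 0.05),
                n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  })
}
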