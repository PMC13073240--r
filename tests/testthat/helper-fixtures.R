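# shared fixture builders; everything is generated in code at test time

# small deterministic count matrix
toy_counts <- function(n_cells = 4, n_genes = 6, seed = 42, max_count = 9) {
  set.seed(seed)
  v <- matrix(rpois(n_cells * n_genes, 3), n_cells, n_genes)
  expression_matrix(v, layer = "counts",
                    cell_ids = sprintf("c%02d", seq_len(n_cells)),
                    gene_ids = sprintf("g%02d", seq_len(n_genes)))
}

# reduced-size simulation for unit tests (defaults stay with sim_config)
small_sim <- function(seed = 1, ...) {
  simulate_positional(sim_config(cells_per_compartment = 100L, n_genes = 400L,
                                 seed = seed, ...))
}

# linearly separable 3-class data: 2 informative genes + noise genes
separable_data <- function(n_per_class = 100, n_noise = 8, seed = 3) {
  set.seed(seed)
  classes <- c("cortex", "OM", "IM")
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4))
  n <- n_per_class * 3
  X <- matrix(rnorm(n * (2 + n_noise)), n, 2 + n_noise)
  lab <- rep(classes, each = n_per_class)
  for (k in 1:3) {
    rows <- which(lab == classes[k])
    X[rows, 1:2] <- X[rows, 1:2] + matrix(centers[k, ], length(rows), 2,
                                          byrow = TRUE)
  }
  ids <- sprintf("s%04d", seq_len(n))
  m <- expression_matrix(X, layer = "lognorm", cell_ids = ids,
                         gene_ids = sprintf("f%02d", seq_len(ncol(X))))
  list(m = m,
       ann = cell_annotation(ids, lab, label_set = classes),
       geneset = gene_set("sep", sprintf("f%02d", seq_len(ncol(X)))))
}

# signal-free data: standard normal features, random balanced labels
null_data <- function(n = 600, n_genes = 10, seed = 5) {
  set.seed(seed)
  classes <- c("cortex", "OM", "IM")
  X <- matrix(rnorm(n * n_genes), n, n_genes)
  ids <- sprintf("n%04d", seq_len(n))
  m <- expression_matrix(X, layer = "lognorm", cell_ids = ids,
                         gene_ids = sprintf("f%02d", seq_len(n_genes)))
  list(m = m,
       ann = cell_annotation(ids, sample(rep(classes, length.out = n)),
                             label_set = classes),
       geneset = gene_set("null", sprintf("f%02d", seq_len(n_genes))))
}

fast_cfg <- function(seed = 1, ...) {
  training_config(hidden_sizes = c(32L, 16L), max_epochs = 60L, seed = seed, ...)
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all group assignments
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  center <- nx * (n + 1) / 2
  mean(abs(w_all - center) >= abs(w_obs - center) - 1e-9)
}

# AUC by explicit pair counting, ties worth 1/2
auc_pair_oracle <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# independent brute-force re-computation of the dispersion-binning ranking
hvg_oracle <- function(vals, n_top, n_bins) {
  mu <- colMeans(vals)
  keep <- mu > 0
  genes <- colnames(vals)[keep]
  disp <- apply(vals[, keep, drop = FALSE], 2, var) / mu[keep]
  ord <- order(mu[keep], genes)
  bin <- integer(length(ord))
  bin[ord] <- floor((seq_along(ord) - 1) * n_bins / length(ord)) + 1L
  z <- numeric(length(disp))
  for (b in unique(bin)) {
    i <- bin == b
    if (sum(i) < 2 || sd(disp[i]) == 0) { z[i] <- 0 } else
      z[i] <- (disp[i] - mean(disp[i])) / sd(disp[i])
  }
  genes[order(-z, genes)][seq_len(n_top)]
}

# the external-validation protocol: QC + log-normalize both datasets,
# rank HVGs on the training dataset, train the gated MLP there, evaluate on
# the other batch
cross_batch_run <- function(seed, geneset = NULL, n_top = 100L) {
  sim <- simulate_positional(sim_config(seed = seed))
  lnA <- log_normalize(qc_filter(sim$datasets$ds1$matrix)$matrix)
  lnB <- log_normalize(qc_filter(sim$datasets$ds2$matrix)$matrix)
  annA <- align_annotation(sim$datasets$ds1$annotation, lnA)
  annB <- align_annotation(sim$datasets$ds2$annotation, lnB)
  if (is.null(geneset)) geneset <- hvg_rank(lnA, n_top = n_top)$geneset
  model <- train_position_model(lnA, annA, geneset,
                                training_config(seed = seed))
  list(report = evaluate(predict(model, lnB), annB), sim = sim,
       lnA = lnA, lnB = lnB, annA = annA, annB = annB, model = model)
}

# Benjamini-Hochberg step-up, written out directly
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m); out[o] <- pmin(adj, 1)
  out
}
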