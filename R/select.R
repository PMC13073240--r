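#' Recursive feature elimination over a linear multinomial model
#'
#' Iteratively fits an L2-regularized linear multinomial classifier on the
#' current genes and removes the \code{ceiling(step_frac * n_current)} genes
#' with the smallest aggregate coefficient magnitude (sum over classes of
#' absolute standardized coefficients) until \code{target_size} genes remain.
#' Ties are removed in lexicographic symbol order, so the procedure is
#' deterministic.
#'
#' @param m \code{ExpressionMatrix} (lognorm).
#' @param ann \code{CellAnnotation}.
#' @param geneset starting \code{GeneSet}.
#' @param target_size number of genes to retain (< |geneset|, or equal for a
#'   no-op).
#' @param step_frac fraction removed per iteration (default 0.1).
#' @param lambda ridge penalty of the base model.
#' @param name output set name.
#' @return a \code{GeneSet} with provenance \code{rfe}.
#' @export
rfe_select <- function(m, ann, geneset, target_size, step_frac = 0.1,
                       lambda = 0.01, name = "rfe") {
  ann <- align_annotation(ann, m)
  y <- droplevels(ann$compartment)
  if (target_size > length(geneset$genes))
    stop("target_size exceeds the gene set size")
  current <- intersect(geneset$genes, gene_ids(m))
  if (length(current) < target_size)
    stop("fewer genes present in the matrix than target_size")
  X_all <- m$values[, current, drop = FALSE]
  while (length(current) > target_size) {
    X <- X_all[, current, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    score <- stats::setNames(numeric(length(current)), current)
    live <- sds > 0
    if (sum(live) >= 2) {
      fit <- glmnet::glmnet(X[, live, drop = FALSE], y,
                            family = "multinomial", alpha = 0,
                            lambda = lambda, standardize = TRUE)
      cf <- glmnet::coef.glmnet(fit, s = lambda)
      agg <- Reduce(`+`, lapply(cf, function(b) abs(as.numeric(b[-1]))))
      score[colnames(X)[live]] <- agg * sds[live]  # standardized magnitude
    }
    k <- min(ceiling(step_frac * length(current)),
             length(current) - target_size)
    drop_genes <- current[order(score[current], current)][seq_len(k)]
    current <- setdiff(current, drop_genes)
  }
  ord <- geneset$genes[geneset$genes %in% current]
  gene_set(name, ord, provenance = "rfe")
}

# empirical mutual information (nats) between a discretized vector and labels
empirical_mi <- function(bins, labels) {
  joint <- table(bins, labels) / length(bins)
  pi_ <- rowSums(joint); qj <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pi_, qj)[nz]))
}

discretize_quantile <- function(x, n_bins) {
  u <- unique(x)
  if (length(u) <= n_bins) return(factor(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) return(factor(x > br[1]))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Mutual-information gene ranking
#'
#' Per gene, log-normalized expression is discretized into
#' \code{n_quantile_bins} equal-frequency bins (genes with few distinct
#' values keep their exact values) and the mutual information with the
#' compartment label is computed from the empirical joint distribution
#' (natural log, nats). The top \code{target_size} genes by MI are returned,
#' ties broken lexicographically.
#'
#' @param m,ann,geneset,target_size as \code{rfe_select}.
#' @param n_quantile_bins number of expression bins (default 8).
#' @param name output set name.
#' @return list with \code{geneset} (provenance \code{mir}) and \code{mi},
#'   the named per-gene MI vector.
#' @export
mi_rank <- function(m, ann, geneset, target_size, n_quantile_bins = 8L,
                    name = "mir") {
  ann <- align_annotation(ann, m)
  y <- droplevels(ann$compartment)
  genes <- intersect(geneset$genes, gene_ids(m))
  if (length(genes) < target_size)
    stop("fewer genes present in the matrix than target_size")
  mi <- vapply(genes, function(g)
    empirical_mi(discretize_quantile(m$values[, g], n_quantile_bins), y),
    numeric(1))
  top <- genes[order(-mi[genes], genes)][seq_len(target_size)]
  list(geneset = gene_set(name, top, provenance = "mir"),
       mi = mi)
}
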