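#' Training configuration for the position classifier
#'
#' Defaults: a gated-attention MLP with hidden layers 128 and 64 (ReLU),
#' dropout 0.2, softmax head, cross-entropy loss, Adam-style optimizer at
#' learning rate 1e-3, minibatch 64, at most 200 epochs with early stopping
#' on a 10\% stratified validation split (patience 10). All randomness is
#' funneled through one seeded generator so training is reproducible.
#'
#' @param hidden_sizes integer vector of hidden-layer widths (non-empty).
#' @param dropout dropout fraction in [0, 1).
#' @param learning_rate Adam step size.
#' @param max_epochs,early_stop_patience,batch_size training loop controls.
#' @param seed integer seed for all stochastic steps.
#' @param attention logical; FALSE trains a plain MLP without the input gate.
#' @param class_weighting "none" or "balanced" (inverse-frequency weights).
#' @param val_frac fraction held out internally for early stopping.
#' @return a \code{TrainingConfig} list.
#' @export
training_config <- function(hidden_sizes = c(128L, 64L), dropout = 0.2,
                            learning_rate = 1e-3, max_epochs = 200L,
                            early_stop_patience = 10L, batch_size = 64L,
                            seed = 1L, attention = TRUE,
                            class_weighting = c("none", "balanced"),
                            val_frac = 0.1) {
  class_weighting <- match.arg(class_weighting)
  hidden_sizes <- as.integer(hidden_sizes)
  if (!length(hidden_sizes)) stop("hidden_sizes must be non-empty")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(hidden_sizes = hidden_sizes, dropout = dropout,
                 learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 attention = isTRUE(attention), class_weighting = class_weighting,
                 val_frac = val_frac),
            class = "TrainingConfig")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# re-index a lognorm/zscore-ready matrix to a fixed gene order, zero-filling
# absent genes; errors below `min_coverage`, warns below `warn_coverage`
align_to_genes <- function(m, gene_order, min_coverage = 0.5,
                           warn_coverage = 0.8) {
  if (m$layer == "counts") m <- log_normalize(m)
  present <- intersect(gene_order, gene_ids(m))
  cov <- length(present) / length(gene_order)
  if (cov < min_coverage)
    stop(sprintf("matrix covers only %.0f%% of the model's %d genes (need >= %.0f%%)",
                 100 * cov, length(gene_order), 100 * min_coverage))
  if (cov < warn_coverage)
    warning(sprintf("matrix covers %.0f%% of the model's genes; absent genes zero-filled",
                    100 * cov))
  v <- matrix(0, nrow(m$values), length(gene_order),
              dimnames = list(cell_ids(m), gene_order))
  v[, present] <- m$values[, present]
  expression_matrix(v, layer = "lognorm")
}

#' Train the attention-gated MLP position classifier
#'
#' Subsets the matrix to the gene set (absent genes zero-filled),
#' log-normalizes raw counts, z-scores per gene storing the standardization
#' stats for prediction time, and trains the gated-attention MLP. Training is
#' deterministic given the data and config.
#'
#' @param m \code{ExpressionMatrix} (counts or lognorm) covering at least
#'   half the gene set.
#' @param ann \code{CellAnnotation} for the matrix cells; at least two
#'   compartments with >= 10 cells each.
#' @param geneset \code{GeneSet} of feature genes.
#' @param cfg \code{TrainingConfig}.
#' @return a \code{PositionModel}.
#' @export
train_position_model <- function(m, ann, geneset, cfg = training_config()) {
  ann <- align_annotation(ann, m)
  y <- droplevels(ann$compartment)
  tab <- table(y)
  if (length(tab) < 2) stop("training labels contain a single class")
  if (any(tab < 10))
    stop("compartment(s) with fewer than 10 cells: ",
         paste(names(tab)[tab < 10], collapse = ", "))
  Xl <- align_to_genes(m, geneset$genes)
  st <- standardize(Xl)
  class_order <- levels(y)
  weights <- NULL
  if (cfg$class_weighting == "balanced") {
    cw <- sum(tab) / (length(tab) * as.numeric(tab))
    weights <- stats::setNames(cw, names(tab))[class_order]
  }
  w <- with_seed(cfg$seed,
    mlp_train(st$matrix$values, as.integer(y), length(class_order), cfg,
              class_weights = weights))
  structure(list(gene_order = geneset$genes, class_order = class_order,
                 stats = st$stats, weights = w, config = cfg,
                 fingerprint = list(n_cells = nrow(m$values),
                                    label_histogram = as.list(tab),
                                    seed = cfg$seed)),
            class = "PositionModel")
}

#' @export
print.PositionModel <- function(x, ...) {
  cat(sprintf("PositionModel: %d genes -> {%s}; attention=%s, seed=%d\n",
              length(x$gene_order), paste(x$class_order, collapse = ", "),
              x$config$attention, x$config$seed))
  invisible(x)
}

#' Predict compartment membership for new cells
#'
#' Columns are aligned to the model's gene order by symbol (absent genes
#' zero-filled; error below 50\% coverage, warning below 80\%), standardized
#' with the training statistics, and passed through the network.
#'
#' @param object a \code{PositionModel}.
#' @param m \code{ExpressionMatrix} (counts or lognorm).
#' @param ... unused.
#' @return a \code{PredictionResult}: cell ids, an n_cells x n_classes
#'   probability matrix (rows sum to 1), and the argmax label per cell (ties
#'   broken by class order).
#' @export
predict.PositionModel <- function(object, m, ...) {
  Xl <- align_to_genes(m, object$gene_order)
  z <- standardize(Xl, stats = object$stats)$matrix$values
  probs <- mlp_forward(object$weights, z, object$config$hidden_sizes,
                       object$config$attention)$probs
  dimnames(probs) <- list(cell_ids(m), object$class_order)
  labels <- object$class_order[max.col(probs, ties.method = "first")]
  structure(list(cell_ids = cell_ids(m), probabilities = probs,
                 labels = stats::setNames(labels, cell_ids(m)),
                 class_order = object$class_order),
            class = "PredictionResult")
}

#' One-vs-rest ROC AUC by rank statistics
#'
#' Equivalent to counting concordant score pairs with ties worth 1/2 (the
#' Mann-Whitney statistic divided by n_pos * n_neg).
#'
#' @param scores numeric scores, higher = more positive.
#' @param positive logical vector, TRUE for the positive class.
#' @return AUC in [0, 1]; NA if either class is empty.
#' @export
auc_score <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate predictions against true compartment labels
#'
#' @param pred a \code{PredictionResult}.
#' @param ann \code{CellAnnotation} holding the true labels for the predicted
#'   cells; labels must lie within the model's class order.
#' @return an \code{EvaluationReport}: overall accuracy, per-class
#'   one-vs-rest AUC (from that class's probability column), confusion matrix
#'   (rows = true), and n_cells.
#' @export
evaluate <- function(pred, ann) {
  ids <- pred$cell_ids
  missing <- setdiff(ids, rownames(ann))
  if (length(missing)) stop("cells missing from annotation: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  truth <- as.character(ann[ids, "compartment"])
  bad <- setdiff(unique(truth), pred$class_order)
  if (length(bad)) stop("true label(s) outside model class order: ",
                        paste(bad, collapse = ", "))
  classes <- pred$class_order
  confusion <- table(factor(truth, levels = classes),
                     factor(pred$labels, levels = classes))
  acc <- sum(diag(confusion)) / length(ids)
  aucs <- vapply(classes, function(k)
    auc_score(pred$probabilities[, k], truth == k), numeric(1))
  structure(list(overall_accuracy = acc,
                 per_class_auc = aucs,
                 confusion = unclass(confusion),
                 n_cells = length(ids)),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: accuracy %.4f over %d cells\n",
              x$overall_accuracy, x$n_cells))
  cat("per-class AUC:", paste(sprintf("%s=%.3f", names(x$per_class_auc),
                                      x$per_class_auc), collapse = ", "), "\n")
  if (!is.null(x$repeats))
    cat(sprintf("repeats: n=%d, median %.4f, SEM %.4f\n",
                length(x$repeats$accuracies), x$repeats$median, x$repeats$sem))
  invisible(x)
}

# stratified split preserving per-class proportions; returns train indices
stratified_train_idx <- function(y, train_frac) {
  idx <- integer(0)
  for (k in levels(y)) {
    idx_k <- which(y == k)
    n_tr <- round(length(idx_k) * train_frac)
    if (n_tr < 1 || n_tr >= length(idx_k))
      stop("class '", k, "' too small to stratify at train_frac = ", train_frac)
    idx <- c(idx, sample(idx_k, n_tr))
  }
  sort(idx)
}

#' Repeated stratified holdout validation
#'
#' Runs \code{n_repeats} stratified random train/test splits (per-class
#' proportions preserved); repeat i uses seed \code{cfg$seed + i}. Each
#' repeat trains a fresh model on the training split and evaluates on the
#' held-out split. The report carries the per-repeat accuracy distribution
#' with its median and SEM (sd / sqrt(n_repeats)), the customary summary
#' for internal validation.
#'
#' @param m,ann,geneset,cfg as \code{train_position_model}.
#' @param n_repeats number of random splits (default 100).
#' @param train_frac training fraction per split (default 0.8).
#' @return an \code{EvaluationReport} with a \code{repeats} component;
#'   \code{overall_accuracy} is the median across repeats, the confusion
#'   matrix is summed across repeats, and per-class AUC is the per-class
#'   median.
#' @export
repeated_holdout <- function(m, ann, geneset, cfg = training_config(),
                             n_repeats = 100L, train_frac = 0.8) {
  ann <- align_annotation(ann, m)
  y <- droplevels(ann$compartment)
  accs <- numeric(n_repeats)
  auc_mat <- NULL
  conf_sum <- NULL
  last <- NULL
  for (i in seq_len(n_repeats)) {
    seed_i <- cfg$seed + i
    tr <- with_seed(seed_i, stratified_train_idx(y, train_frac))
    te <- setdiff(seq_along(y), tr)
    cfg_i <- cfg; cfg_i$seed <- seed_i
    model <- train_position_model(subset_matrix(m, cells = tr),
                                  ann[tr, , drop = FALSE], geneset, cfg_i)
    pred <- predict(model, subset_matrix(m, cells = te))
    rep_i <- evaluate(pred, ann[te, , drop = FALSE])
    accs[i] <- rep_i$overall_accuracy
    auc_mat <- rbind(auc_mat, rep_i$per_class_auc)
    conf_sum <- if (is.null(conf_sum)) rep_i$confusion else conf_sum + rep_i$confusion
    last <- rep_i
  }
  out <- last
  out$overall_accuracy <- stats::median(accs)
  out$per_class_auc <- apply(auc_mat, 2, stats::median, na.rm = TRUE)
  out$confusion <- conf_sum
  out$n_cells <- sum(conf_sum)
  out$repeats <- list(accuracies = accs, median = stats::median(accs),
                      sem = stats::sd(accs) / sqrt(n_repeats))
  out
}

#' Two-sample comparison of accuracy distributions
#'
#' Two-sided Student's t-test (equal variance); when a batch of comparisons
#' is submitted, Benjamini-Hochberg adjustment is applied across the batch.
#'
#' @param a either a numeric vector (first group) or, for a batch, a named
#'   list of \code{list(a = ..., b = ...)} pairs.
#' @param b numeric vector (second group) when \code{a} is numeric.
#' @return a data.frame with columns \code{t}, \code{p}, \code{p_adj}
#'   (one row per comparison).
#' @export
compare_accuracies <- function(a, b = NULL) {
  pairs <- if (is.numeric(a)) list(comparison = list(a = a, b = b)) else a
  one <- function(pr) {
    x <- pr$a; y <- pr$b
    stopifnot(length(x) >= 2, length(y) >= 2)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) return(c(t = 0, p = 1))
      return(c(t = ifelse(mean(x) > mean(y), Inf, -Inf), p = 0))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  }
  res <- t(vapply(pairs, one, numeric(2)))
  out <- data.frame(t = res[, "t"], p = res[, "p"],
                    p_adj = stats::p.adjust(res[, "p"], method = "BH"),
                    row.names = names(pairs))
  out
}
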