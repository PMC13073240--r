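# Seven-model baseline suite trained on the same standardized feature matrix
# and split protocol as the MLP. Each fitter returns a per-class score matrix
# on the test split (probabilities, vote fractions, or decision values for
# the SVM), which feeds the shared one-vs-rest AUC machinery.

BASELINE_NAMES <- c("logistic_regression", "knn", "naive_bayes",
                    "decision_tree", "random_forest", "gradient_boosting",
                    "linear_svm")

# k-nearest-neighbour with full per-class vote fractions (the stock knn
# routine reports only the winning class's vote share, which cannot feed
# one-vs-rest AUC)
knn_scores <- function(Xtr, ytr, Xte, k, classes) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  scores <- matrix(0, nrow(Xte), length(classes),
                   dimnames = list(NULL, classes))
  for (i in seq_len(nrow(Xte))) {
    nn <- order(d2[i, ])[seq_len(k)]
    tab <- table(factor(ytr[nn], levels = classes))
    scores[i, ] <- as.numeric(tab) / k
  }
  scores
}

fit_baseline <- function(name, Xtr, ytr, Xte, classes, seed) {
  df_tr <- data.frame(Xtr, check.names = FALSE); df_tr$.y <- ytr
  df_te <- data.frame(Xte, check.names = FALSE)
  K <- length(classes)
  scores <- switch(name,
    logistic_regression = {
      fit <- nnet::multinom(.y ~ ., data = df_tr, trace = FALSE,
                            MaxNWts = 100000, maxit = 200)
      p <- predict(fit, newdata = df_te, type = "probs")
      if (K == 2) p <- cbind(1 - p, p)
      colnames(p) <- classes
      p
    },
    knn = knn_scores(Xtr, ytr, Xte, k = min(15L, length(ytr)), classes),
    naive_bayes = {
      fit <- e1071::naiveBayes(.y ~ ., data = df_tr)
      predict(fit, newdata = df_te, type = "raw")[, classes, drop = FALSE]
    },
    decision_tree = {
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
      predict(fit, newdata = df_te, type = "prob")[, classes, drop = FALSE]
    },
    random_forest = {
      fit <- ranger::ranger(x = Xtr, y = ytr, probability = TRUE,
                            num.trees = 200, seed = seed, num.threads = 1)
      predict(fit, data = Xte, num.threads = 1)$predictions[, classes, drop = FALSE]
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(Xtr, label = as.integer(ytr) - 1L)
      fit <- xgboost::xgb.train(params = list(objective = "multi:softprob",
                                              num_class = K, max_depth = 4,
                                              eta = 0.3, nthread = 1),
                                dtrain, nrounds = 50)
      p <- predict(fit, xgboost::xgb.DMatrix(Xte))
      if (is.null(dim(p))) p <- matrix(p, ncol = K, byrow = TRUE)
      dimnames(p) <- list(NULL, classes)
      p
    },
    linear_svm = {
      # one-vs-rest linear SVMs; AUC uses the decision-function scores
      s <- sapply(classes, function(k) {
        yk <- factor(ifelse(ytr == k, "pos", "neg"), levels = c("pos", "neg"))
        fit <- e1071::svm(x = Xtr, y = yk, kernel = "linear", scale = FALSE)
        dv <- attr(predict(fit, Xte, decision.values = TRUE), "decision.values")
        drop(dv) * if (grepl("^pos", colnames(dv)[1])) 1 else -1
      })
      matrix(s, ncol = K, dimnames = list(NULL, classes))
    },
    stop("unknown baseline: ", name)
  )
  scores
}

#' Train and evaluate the seven-model baseline suite
#'
#' Fits logistic regression, k-nearest neighbours, Gaussian naive Bayes, a
#' decision tree, a random forest, gradient-boosted trees and a one-vs-rest
#' linear SVM on the same standardized gene-set features and the same
#' stratified split protocol as the MLP, and evaluates each with the shared
#' accuracy/AUC/confusion machinery (SVM AUC uses decision-function scores).
#'
#' @param m,ann,geneset as \code{train_position_model}.
#' @param seed integer seed controlling the split and any stochastic fitter.
#' @param train_frac training fraction of the stratified split (ignored when
#'   an external test set is supplied).
#' @param test_m,test_ann optional external validation matrix/annotation; if
#'   given, all of \code{m} trains and \code{test_m} evaluates.
#' @return named list of \code{EvaluationReport}, one per baseline.
#' @export
train_baselines <- function(m, ann, geneset, seed = 1L, train_frac = 0.8,
                            test_m = NULL, test_ann = NULL) {
  ann <- align_annotation(ann, m)
  y <- droplevels(ann$compartment)
  if (length(levels(y)) < 2) stop("training labels contain a single class")
  Xl <- align_to_genes(m, geneset$genes)
  st <- standardize(Xl)
  X <- st$matrix$values
  if (is.null(test_m)) {
    tr <- with_seed(seed, stratified_train_idx(y, train_frac))
    te <- setdiff(seq_along(y), tr)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    ytr <- droplevels(y[tr])
    ann_te <- ann[te, , drop = FALSE]
  } else {
    test_ann <- align_annotation(test_ann, test_m)
    Xtr <- X; ytr <- y
    Xte <- standardize(align_to_genes(test_m, geneset$genes),
                       stats = st$stats)$matrix$values
    ann_te <- test_ann
  }
  keep <- apply(Xtr, 2, stats::sd) > 0  # constant features break several fitters
  Xtr <- Xtr[, keep, drop = FALSE]; Xte <- Xte[, keep, drop = FALSE]
  classes <- levels(ytr)
  out <- list()
  for (name in BASELINE_NAMES) {
    scores <- with_seed(seed, fit_baseline(name, Xtr, ytr, Xte, classes, seed))
    labels <- classes[max.col(scores, ties.method = "first")]
    pred <- structure(list(cell_ids = rownames(Xte),
                           probabilities = structure(scores,
                             dimnames = list(rownames(Xte), classes)),
                           labels = stats::setNames(labels, rownames(Xte)),
                           class_order = classes),
                      class = "PredictionResult")
    out[[name]] <- evaluate(pred, ann_te)
  }
  out
}
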