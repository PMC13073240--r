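test_that("training is deterministic and learns separable structure", {
  d <- separable_data(n_per_class = 100, seed = 21)
  m1 <- train_position_model(d$m, d$ann, d$geneset, fast_cfg(seed = 21))
  m2 <- train_position_model(d$m, d$ann, d$geneset, fast_cfg(seed = 21))
  expect_identical(m1$weights, m2$weights)
  p1 <- predict(m1, d$m); p2 <- predict(m2, d$m)
  expect_identical(p1$probabilities, p2$probabilities)

  rep1 <- evaluate(p1, d$ann)
  expect_gte(rep1$overall_accuracy, 0.95)  # linearly separable sanity

  expect_error(train_position_model(
    d$m, cell_annotation(cell_ids(d$m), rep("cortex", nrow(d$m$values))),
    d$geneset, fast_cfg()), "single class")
  tiny_set <- gene_set("missing", c("f01", "zz1", "zz2", "zz3"))
  expect_error(train_position_model(d$m, d$ann, tiny_set, fast_cfg()),
               "covers only")
})

test_that("randomly permuted labels yield chance-level held-out accuracy", {
  accs <- sapply(1:5, function(s) {
    d <- separable_data(n_per_class = 100, seed = s + 30)
    set.seed(s)
    shuffled <- cell_annotation(cell_ids(d$m),
                                sample(as.character(d$ann$compartment)),
                                label_set = levels(d$ann$compartment))
    tr <- sort(unlist(lapply(split(seq_len(300), shuffled$compartment),
                             function(i) i[1:60])))
    te <- setdiff(seq_len(300), tr)
    model <- train_position_model(subset_matrix(d$m, cells = tr),
                                  shuffled[tr, , drop = FALSE],
                                  d$geneset, fast_cfg(seed = s))
    evaluate(predict(model, subset_matrix(d$m, cells = te)),
             shuffled[te, , drop = FALSE])$overall_accuracy
  })
  expect_gte(median(accs), 0.25)
  expect_lte(median(accs), 0.45)
})

test_that("prediction is symbol-aligned, zero-fill tolerant and NaN-free", {
  d <- separable_data(n_per_class = 60, seed = 23)
  model <- train_position_model(d$m, d$ann, d$geneset, fast_cfg(seed = 23))

  # shuffled gene column order gives the identical result
  perm <- sample(ncol(d$m$values))
  m_shuf <- expression_matrix(d$m$values[, perm], layer = "lognorm")
  expect_identical(predict(model, m_shuf)$probabilities,
                   predict(model, d$m)$probabilities)

  # all-zero cell: a valid probability vector, no NaN
  zero <- expression_matrix(matrix(0, 2, length(d$geneset$genes),
                                   dimnames = list(c("z1", "z2"),
                                                   d$geneset$genes)),
                            layer = "lognorm")
  pz <- predict(model, zero)
  expect_false(anyNA(pz$probabilities))
  expect_equal(unname(rowSums(pz$probabilities)), c(1, 1), tolerance = 1e-6)

  # probability rows sum to 1 for arbitrary finite input
  probe <- expression_matrix(matrix(rnorm(50 * 10, sd = 30), 50, 10,
                                    dimnames = list(sprintf("r%02d", 1:50),
                                                    d$geneset$genes)),
                             layer = "lognorm")
  pp <- predict(model, probe)
  expect_lt(max(abs(rowSums(pp$probabilities) - 1)), 1e-6)
  expect_false(anyNA(pp$probabilities))

  # coverage gate: below half the model's genes is an error
  few <- expression_matrix(matrix(rnorm(8), 2, 4,
                                  dimnames = list(c("a", "b"),
                                                  d$geneset$genes[1:4])),
                           layer = "lognorm")
  expect_error(predict(model, few), "covers only")
})

test_that("evaluate counts accuracy, confusion and one-vs-rest AUC correctly", {
  classes <- c("cortex", "OM", "IM")
  mk_pred <- function(labels, probs) {
    ids <- sprintf("c%02d", seq_along(labels))
    dimnames(probs) <- list(ids, classes)
    structure(list(cell_ids = ids, probabilities = probs,
                   labels = setNames(labels, ids), class_order = classes),
              class = "PredictionResult")
  }
  # perfect predictions
  truth <- rep(classes, each = 3)
  probs <- t(sapply(truth, function(k) (classes == k) * 0.8 + 0.1))
  pred <- mk_pred(truth, probs)
  ann <- cell_annotation(sprintf("c%02d", 1:9), truth)
  repp <- evaluate(pred, ann)
  expect_equal(repp$overall_accuracy, 1.0)
  expect_equal(unname(repp$per_class_auc), c(1, 1, 1))
  expect_equal(sum(diag(repp$confusion)), 9)

  # 6 of 9 correct
  wrong <- truth; wrong[c(1, 5, 9)] <- c("OM", "IM", "cortex")
  probs_w <- t(sapply(wrong, function(k) (classes == k) * 0.8 + 0.1))
  rep2 <- evaluate(mk_pred(wrong, probs_w), ann)
  expect_equal(rep2$overall_accuracy, 2 / 3, tolerance = 1e-12)
  expect_equal(unname(rowSums(rep2$confusion)), rep(3, 3))  # true-class counts
  expect_equal(sum(diag(rep2$confusion)) / sum(rep2$confusion),
               rep2$overall_accuracy)

  bad_ann <- cell_annotation(sprintf("c%02d", 1:9),
                             c(truth[-9], "medulla"))
  expect_error(evaluate(pred, bad_ann), "outside model class order")
})

test_that("AUC equals the tie-aware pair-counting oracle", {
  # worked case: scores .5/.5/.2/.7 for labels +/-/-/+ -> 0.875
  expect_equal(auc_score(c(0.5, 0.5, 0.2, 0.7), c(TRUE, FALSE, FALSE, TRUE)),
               0.875)
  expect_equal(auc_pair_oracle(c(0.5, 0.5, 0.2, 0.7),
                               c(TRUE, FALSE, FALSE, TRUE)), 0.875)

  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # heavy ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || !any(pos)) next
    expect_equal(auc_score(scores, pos), auc_pair_oracle(scores, pos))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:10) {
    scores <- rnorm(60)
    pos <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    expect_equal(auc_score(scores, pos),
                 as.numeric(pROC::auc(pROC::roc(response = pos,
                                                predictor = scores,
                                                quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("repeated holdout reports the accuracy distribution with median and SEM", {
  d <- separable_data(n_per_class = 60, seed = 25)
  rep1 <- repeated_holdout(d$m, d$ann, d$geneset, fast_cfg(seed = 25),
                           n_repeats = 3, train_frac = 0.8)
  expect_length(rep1$repeats$accuracies, 3)
  expect_equal(rep1$repeats$median, median(rep1$repeats$accuracies))
  expect_equal(rep1$repeats$sem, sd(rep1$repeats$accuracies) / sqrt(3))
  expect_equal(rep1$overall_accuracy, rep1$repeats$median)
  expect_equal(sum(rep1$confusion), rep1$n_cells)

  # n_repeats = 1 equals a single evaluate on that split
  r1 <- repeated_holdout(d$m, d$ann, d$geneset, fast_cfg(seed = 40),
                         n_repeats = 1, train_frac = 0.8)
  expect_equal(r1$repeats$accuracies, r1$overall_accuracy)

  tiny_ann <- cell_annotation(cell_ids(d$m),
                              c("A", rep(c("B", "C"), length.out = 179)))
  expect_error(repeated_holdout(d$m, tiny_ann, d$geneset, fast_cfg(),
                                n_repeats = 1), "too small to stratify")
})

test_that("the seven baselines run under one protocol and respect sanity bounds", {
  d <- separable_data(n_per_class = 80, seed = 27)
  reps <- train_baselines(d$m, d$ann, d$geneset, seed = 27)
  expect_setequal(names(reps),
                  c("logistic_regression", "knn", "naive_bayes",
                    "decision_tree", "random_forest", "gradient_boosting",
                    "linear_svm"))
  for (nm in names(reps))
    expect_gte(reps[[nm]]$overall_accuracy, 0.9)

  nd <- null_data(n = 600, seed = 28)
  reps0 <- train_baselines(nd$m, nd$ann, nd$geneset, seed = 28)
  for (nm in names(reps0)) {
    expect_gte(reps0[[nm]]$overall_accuracy, 0.25)
    expect_lte(reps0[[nm]]$overall_accuracy, 0.45)
  }
})

test_that("accuracy comparisons reproduce the Student t worked case", {
  same <- compare_accuracies(c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  res <- compare_accuracies(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(res$t, 3), -3.674)
  # closed form: t = -3 / sqrt(s_p^2 * 2/3) with pooled variance 1, df = 4
  t_oracle <- -3 / sqrt(2 / 3)
  expect_equal(res$t, t_oracle)
  expect_equal(res$p, 2 * pt(t_oracle, df = 4))
  expect_equal(res$p, 0.0214, tolerance = 1e-2)

  const <- compare_accuracies(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(const$p, 1)
})
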