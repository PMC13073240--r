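test_that("hvg_rank matches a brute-force dispersion oracle, set and order", {
  for (seed in c(1, 2, 3)) {
    m <- log_normalize(toy_counts(60, 45, seed = seed))
    res <- hvg_rank(m, n_top = 12, n_bins = 5)
    expect_identical(res$geneset$genes, hvg_oracle(m$values, 12, 5))
    # bin z-scores are centered within bins of >= 2 genes
    tab <- res$table
    for (b in unique(tab$bin_index)) {
      zb <- tab$dispersion_z[tab$bin_index == b]
      if (length(zb) >= 2 && sd(tab$dispersion[tab$bin_index == b]) > 0)
        expect_lt(abs(mean(zb)), 1e-9)
    }
  }
})

test_that("hvg_rank finds a planted bimodal gene and ignores flat genes", {
  # 6 genes x 40 cells of log-normalized expression: g03 bimodal
  # (high in half the cells), the rest flat with small noise
  set.seed(7)
  v <- matrix(2 + rnorm(240, sd = 0.1), 40, 6,
              dimnames = list(sprintf("c%02d", 1:40), sprintf("g%02d", 1:6)))
  v[1:20, 3] <- 5 + rnorm(20, sd = 0.1)
  m <- expression_matrix(v, layer = "lognorm")
  res <- hvg_rank(m, n_top = 2, n_bins = 1)
  expect_identical(res$geneset$genes[1], "g03")

  # constant-expression gene has dispersion 0 and never ranks
  v2 <- log1p(matrix(runif(40 * 6, 1, 5), 40, 6,
                     dimnames = dimnames(v)))
  v2[, 5] <- 2.5
  m2 <- expression_matrix(v2, layer = "lognorm")
  r2 <- hvg_rank(m2, n_top = 4, n_bins = 1)
  expect_false("g05" %in% r2$geneset$genes)

  # permuting cell order leaves the ranking unchanged
  perm <- sample(nrow(v))
  m3 <- expression_matrix(v[perm, ], layer = "lognorm")
  expect_identical(hvg_rank(m3, n_top = 4, n_bins = 3)$geneset$genes,
                   hvg_rank(m, n_top = 4, n_bins = 3)$geneset$genes)

  expect_error(hvg_rank(m, n_top = 100), "n_top")
  expect_error(hvg_rank(m, n_top = 2, n_bins = 0), "n_bins")
})

test_that("merge_union reproduces overlap arithmetic and keeps first-appearance order", {
  # two 100-gene sets sharing 63 genes -> 137-gene union
  shared <- sprintf("s%03d", 1:63)
  a <- gene_set("a", c(shared, sprintf("a%03d", 1:37)), provenance = "hvg")
  b <- gene_set("b", c(sprintf("b%03d", 1:37), shared), provenance = "hvg")
  u <- merge_union(list(a, b))
  expect_length(u, 137)
  expect_identical(u$provenance, "hvg")
  expect_identical(u$genes[1:100], a$genes)  # first-appearance order

  # four 100-gene sets overlapping down to a 251-gene union
  pool <- sprintf("p%03d", 1:251)
  set.seed(1)
  sets <- list(gene_set("d1", pool[1:100], provenance = "hvg"))
  covered <- pool[1:100]
  remaining <- setdiff(pool, covered)
  for (i in 2:4) {
    take_new <- if (i < 4) sample(remaining, 51) else remaining
    sets[[i]] <- gene_set(paste0("d", i),
                          c(take_new, sample(covered, 100 - length(take_new))),
                          provenance = "hvg")
    covered <- union(covered, take_new)
    remaining <- setdiff(pool, covered)
  }
  expect_length(merge_union(sets), 251)

  expect_identical(merge_union(list(a, a))$genes, a$genes)  # idempotence
  expect_error(merge_union(list()), "at least one")
})

test_that("overlap_report does exact set arithmetic", {
  a <- gene_set("a", sprintf("x%03d", 1:251))
  b <- gene_set("b", c(sprintf("x%03d", 1:53), sprintf("y%03d", 1:51)))
  ov <- overlap_report(a, b)
  expect_equal(ov$n_shared, 53)
  expect_equal(round(ov$frac_of_a, 3), 0.211)
  expect_equal(round(ov$frac_of_b, 3), 0.510)

  d <- gene_set("d", c("q1", "q2"))
  ovd <- overlap_report(a, d)
  expect_equal(unlist(ovd), c(n_shared = 0, n_only_a = 251, n_only_b = 2,
                              frac_of_a = 0, frac_of_b = 0))
  sub <- gene_set("sub", a$genes[1:10])
  expect_equal(overlap_report(sub, a)$frac_of_a, 1.0)
})

test_that("de_markers selects class-specific genes with Wilcoxon + BH", {
  # gene gA expressed only in compartment A
  set.seed(4)
  n <- 30
  lab <- rep(c("A", "B", "C"), each = 10)
  v <- matrix(rpois(n * 6, 3) + 1L, n, 6,
              dimnames = list(sprintf("c%02d", 1:n),
                              c("gA", sprintf("g%d", 1:5))))
  v[lab != "A", "gA"] <- 0L
  m <- log_normalize(expression_matrix(v, layer = "counts"))
  ann <- cell_annotation(rownames(v), lab)
  res <- de_markers(m, ann, min_logfc = 0.25, max_fdr = 0.05)
  expect_true("gA" %in% res$geneset$genes)
  rowA <- subset(res$table, gene == "gA" & compartment == "A")
  expect_gt(rowA$logfc, 0)
  expect_identical(res$geneset$provenance, "fam")

  small <- cell_annotation(rownames(v), c(rep("A", 2), rep("B", n - 2)))
  expect_error(de_markers(m, small), "fewer than 3 cells: A")
})

test_that("Wilcoxon p-values match exact enumeration for small groups", {
  # worked case: [1,2,3] vs [4,5,6], exact two-sided p = 0.1
  vals <- cbind(g = c(1, 2, 3, 4, 5, 6))
  m <- expression_matrix(vals, layer = "lognorm",
                         cell_ids = paste0("c", 1:6))
  ann <- cell_annotation(paste0("c", 1:6), rep(c("A", "B"), each = 3))
  de <- compartment_de(m, ann, target = "A")
  expect_equal(de$p, 0.1)
  expect_equal(wilcox_exact_oracle(1:3, 4:6), 0.1)

  # randomized small fixtures, untied, groups <= 8
  set.seed(8)
  for (i in 1:6) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- sample(100, nx + ny)  # distinct values, no ties
    mm <- expression_matrix(cbind(g = x), layer = "lognorm",
                            cell_ids = paste0("c", seq_along(x)))
    aa <- cell_annotation(paste0("c", seq_along(x)),
                          rep(c("A", "B"), c(nx, ny)))
    expect_equal(compartment_de(mm, aa, target = "A")$p,
                 wilcox_exact_oracle(x[1:nx], x[-(1:nx)]))
  }
})

test_that("BH adjustment follows the step-up formula", {
  batch <- list(a = list(a = c(1, 2, 3), b = c(2.1, 3.3, 4.0)),
                b = list(a = c(1, 2, 3), b = c(1.5, 2.5, 3.5)),
                c = list(a = c(0, 1, 2), b = c(4, 5, 6)),
                d = list(a = c(5, 6, 7), b = c(5.1, 6.1, 7.4)))
  res <- compare_accuracies(batch)
  expect_equal(res$p_adj, bh_oracle(res$p))
  # the canonical evenly-spaced case collapses to the maximum
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(unique(round(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), 10)),
               0.04)
})

test_that("RFE recovers planted informative genes and is order-invariant", {
  make_data <- function(seed) {
    set.seed(seed)
    n <- 150
    lab <- rep(c("A", "B", "C"), each = n / 3)
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(sprintf("c%03d", 1:n), sprintf("g%02d", 1:10)))
    centers <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
    for (k in 1:3) X[lab == c("A", "B", "C")[k], 1:3] <-
      X[lab == c("A", "B", "C")[k], 1:3] +
      matrix(centers[k, ], sum(lab == c("A", "B", "C")[k]), 3, byrow = TRUE)
    list(m = expression_matrix(X, layer = "lognorm"),
         ann = cell_annotation(rownames(X), lab))
  }
  hits <- sapply(1:20, function(s) {
    d <- make_data(s)
    gs <- rfe_select(d$m, d$ann, gene_set("all", sprintf("g%02d", 1:10)), 3)
    setequal(gs$genes, c("g01", "g02", "g03"))
  })
  expect_gte(sum(hits), 18)

  d <- make_data(99)
  full <- gene_set("all", sprintf("g%02d", 1:10))
  expect_identical(rfe_select(d$m, d$ann, full, 10)$genes, full$genes)

  # shuffling gene column order does not change the selected set
  perm <- sample(10)
  m2 <- expression_matrix(d$m$values[, perm], layer = "lognorm")
  expect_setequal(rfe_select(m2, d$ann, full, 3)$genes,
                  rfe_select(d$m, d$ann, full, 3)$genes)
})

test_that("mutual-information ranking behaves at the information-theoretic limits", {
  set.seed(10)
  n <- 600
  lab <- rep(c("A", "B", "C"), each = n / 3)
  perfect <- as.numeric(factor(lab))          # identical to the label encoding
  noise <- sample(perfect)                    # label-independent permutation
  X <- cbind(perfect = perfect, noise = noise,
             cont = rnorm(n))
  m <- expression_matrix(X, layer = "lognorm",
                         cell_ids = sprintf("c%03d", 1:n))
  ann <- cell_annotation(sprintf("c%03d", 1:n), lab)
  res <- mi_rank(m, ann, gene_set("all", colnames(X)), target_size = 3)
  expect_equal(unname(res$mi["perfect"]), log(3), tolerance = 1e-9)
  expect_lte(unname(res$mi["noise"]), 0.02)
  expect_true(all(res$mi >= 0))
  expect_identical(res$geneset$genes[1], "perfect")
  expect_identical(res$geneset$provenance, "mir")
})

test_that("random_set is seed-reproducible and uniform over the universe", {
  uni <- sprintf("u%03d", 1:40)
  expect_identical(random_set(uni, 10, seed = 5)$genes,
                   random_set(uni, 10, seed = 5)$genes)
  expect_setequal(random_set(uni, 40, seed = 1)$genes, uni)
  expect_error(random_set(uni, 41, seed = 1), "universe")

  # inclusion frequency ~ Binomial(n_seeds, n/|universe|) within 3 sigma
  counts <- table(factor(unlist(lapply(1:1000, function(s)
    random_set(uni, 10, seed = s)$genes)), levels = uni))
  p <- 10 / 40
  expect_true(all(abs(counts - 1000 * p) <= 3 * sqrt(1000 * p * (1 - p))))
})
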