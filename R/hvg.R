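#' Highly-variable-gene ranking by dispersion z-score within mean bins
#'
#' The mean/variability-plot style selector: per gene, the mean and the
#' dispersion (variance / mean) of log-normalized expression are computed;
#' genes with positive mean are split into \code{n_bins} equal-frequency
#' bins by mean, the dispersion is z-scored within each bin (sample sd;
#' single-gene or zero-sd bins get z = 0), and the \code{n_top} genes with
#' the highest dispersion z-score are returned in descending order, ties
#' broken lexicographically by symbol.
#'
#' @param m \code{ExpressionMatrix} with \code{layer = "lognorm"}.
#' @param n_top number of genes to keep (default 100).
#' @param n_bins number of equal-frequency mean bins (default 20).
#' @param name name for the resulting gene set.
#' @return list with \code{geneset} (\code{GeneSet}, provenance \code{hvg})
#'   and \code{table}, the per-gene dispersion table (gene, mean, dispersion,
#'   bin_index, dispersion_z).
#' @export
hvg_rank <- function(m, n_top = 100L, n_bins = 20L, name = "hvg") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("hvg_rank expects the lognorm layer, got ", m$layer)
  if (n_bins < 1) stop("n_bins must be >= 1")
  mu <- colMeans(m$values)
  v <- apply(m$values, 2, stats::var)
  eligible <- mu > 0
  if (sum(eligible) < n_top)
    stop(sprintf("only %d genes with nonzero mean; need at least n_top = %d",
                 sum(eligible), n_top))
  genes <- gene_ids(m)[eligible]
  mu_e <- mu[eligible]; disp <- v[eligible] / mu_e
  # equal-frequency bins on mean; stable order (mean, then symbol)
  ord <- order(mu_e, genes)
  bin <- integer(length(ord))
  bin[ord] <- floor((seq_along(ord) - 1) * n_bins / length(ord)) + 1L
  z <- numeric(length(disp))
  for (b in unique(bin)) {
    in_b <- bin == b
    if (sum(in_b) < 2) { z[in_b] <- 0; next }
    s <- stats::sd(disp[in_b])
    z[in_b] <- if (s > 0) (disp[in_b] - mean(disp[in_b])) / s else 0
  }
  tab <- data.frame(gene = genes, mean = mu_e, dispersion = disp,
                    bin_index = bin, dispersion_z = z,
                    stringsAsFactors = FALSE, row.names = NULL)
  top <- tab[order(-tab$dispersion_z, tab$gene), , drop = FALSE][seq_len(n_top), ]
  list(geneset = gene_set(name, top$gene, provenance = "hvg"), table = tab)
}

#' Union-merge gene sets preserving first-appearance order
#'
#' The cross-dataset merge step: top-ranked genes from several datasets are
#' combined into one candidate set, keeping the order in which symbols first
#' appear so downstream gene order is deterministic.
#'
#' @param sets non-empty list of \code{GeneSet}.
#' @param name name for the merged set.
#' @return a \code{GeneSet}; provenance \code{hvg} if every input is
#'   \code{hvg}, else \code{custom}.
#' @export
merge_union <- function(sets, name = "union") {
  if (!length(sets)) stop("merge_union needs at least one gene set")
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  genes <- unlist(lapply(sets, function(s) s$genes), use.names = FALSE)
  prov <- if (all(vapply(sets, function(s) s$provenance, character(1)) == "hvg"))
    "hvg" else "custom"
  gene_set(name, genes[!duplicated(genes)], provenance = prov)
}

#' Overlap accounting between two gene sets
#'
#' @param a,b \code{GeneSet}s.
#' @return list: \code{n_shared}, \code{n_only_a}, \code{n_only_b},
#'   \code{frac_of_a}, \code{frac_of_b} (shared / set size).
#' @export
overlap_report <- function(a, b) {
  shared <- intersect(a$genes, b$genes)
  list(n_shared = length(shared),
       n_only_a = length(setdiff(a$genes, b$genes)),
       n_only_b = length(setdiff(b$genes, a$genes)),
       frac_of_a = length(shared) / length(a$genes),
       frac_of_b = length(shared) / length(b$genes))
}

#' Uniform random gene set (negative control)
#'
#' @param universe character vector of candidate symbols.
#' @param n sample size (without replacement).
#' @param seed integer seed; the same seed reproduces the same set.
#' @param name set name.
#' @return a \code{GeneSet} with provenance \code{random}.
#' @export
random_set <- function(universe, n, seed, name = "random") {
  universe <- unique(as.character(universe))
  if (n > length(universe)) stop("n exceeds the universe size")
  genes <- with_seed(seed, sample(universe, n))
  gene_set(name, genes, provenance = "random")
}

#' Default gene universe for random controls
#'
#' Genes detected (count or expression > 0) in at least \code{min_frac} of
#' cells, to avoid trivially-zero genes in randomized controls.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param min_frac minimum detection fraction (default 0.01).
#' @return character vector of symbols.
#' @export
detected_universe <- function(m, min_frac = 0.01) {
  frac <- colMeans(m$values > 0)
  gene_ids(m)[frac >= min_frac]
}
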