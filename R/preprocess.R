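#' Quality-control filter on raw counts
#'
#' Keeps cells whose detected-gene count (number of genes with count > 0)
#' lies in \code{[min_genes, max_genes]} inclusive and whose mitochondrial
#' count fraction is at most \code{max_mito_frac}. Mitochondrial genes are
#' identified by a case-insensitive symbol prefix ("mt-"/"MT-" by default).
#' The gene axis is never touched.
#'
#' @param m \code{ExpressionMatrix} with \code{layer = "counts"}.
#' @param min_genes,max_genes detected-gene bounds (default 200-4000).
#' @param max_mito_frac maximum mitochondrial fraction kept (default 0.20;
#'   cells at exactly the threshold are kept).
#' @param mito_prefix symbol prefix marking mitochondrial genes.
#' @return list with \code{matrix} (filtered) and \code{report}, a data.frame
#'   of removed cells with a reason (\code{low_genes}, \code{high_genes},
#'   \code{high_mito}).
#' @export
qc_filter <- function(m, min_genes = 200L, max_genes = 4000L,
                      max_mito_frac = 0.20, mito_prefix = "mt-") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("qc_filter expects the counts layer, got ", m$layer)
  v <- m$values
  detected <- rowSums(v > 0)
  totals <- rowSums(v)
  is_mito <- startsWith(tolower(gene_ids(m)), tolower(mito_prefix))
  mito_frac <- if (any(is_mito))
    rowSums(v[, is_mito, drop = FALSE]) / pmax(totals, 1) else rep(0, nrow(v))
  reason <- rep(NA_character_, nrow(v))
  reason[detected > max_genes] <- "high_genes"
  reason[mito_frac > max_mito_frac & is.na(reason)] <- "high_mito"
  reason[detected < min_genes] <- "low_genes"
  keep <- is.na(reason)
  if (!any(keep)) stop("qc_filter removed every cell; downstream is undefined")
  report <- data.frame(cell_id = cell_ids(m)[!keep],
                       detected_genes = detected[!keep],
                       total_counts = totals[!keep],
                       mito_frac = mito_frac[!keep],
                       reason = reason[!keep],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(matrix = subset_matrix(m, cells = keep), report = report)
}

#' Library-size log-normalization
#'
#' \code{value' = ln(1 + count / cell_total * scale)}: each cell is scaled to
#' a common library size and shifted-log transformed, so doubling all of a
#' cell's counts leaves its normalized vector unchanged.
#'
#' @param m \code{ExpressionMatrix} with \code{layer = "counts"}; every cell
#'   must have total count > 0 (filter first).
#' @param scale target library size (default 1e4).
#' @return \code{ExpressionMatrix} with \code{layer = "lognorm"}.
#' @export
log_normalize <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("log_normalize expects the counts layer, got ", m$layer)
  totals <- rowSums(m$values)
  if (any(totals == 0))
    stop("zero-total cell(s): ", paste(utils::head(cell_ids(m)[totals == 0], 5),
                                       collapse = ", "), " (run qc_filter first)")
  v <- log1p(m$values / totals * scale)
  expression_matrix(v, layer = "lognorm")
}

#' Per-gene standardization (z-scoring) with reusable stats
#'
#' \code{z = (x - mean) / sd} clipped to \code{[-clip, clip]}; genes with
#' sd = 0 map to 0. When \code{stats} is omitted, per-gene mean and sample
#' (n-1) sd are computed from \code{m} and returned so prediction-time data
#' can be standardized with the training statistics.
#'
#' @param m \code{ExpressionMatrix} with \code{layer = "lognorm"}.
#' @param stats optional list(mean, sd), named by gene, covering all of
#'   \code{m}'s genes.
#' @param clip symmetric clipping bound (default 10).
#' @return list with \code{matrix} (\code{layer = "zscore"}) and \code{stats}.
#' @export
standardize <- function(m, stats = NULL, clip = 10) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  genes <- gene_ids(m)
  if (is.null(stats)) {
    mu <- colMeans(m$values)
    sdv <- apply(m$values, 2, stats::sd)
    stats <- list(mean = stats::setNames(mu, genes), sd = stats::setNames(sdv, genes))
  } else {
    if (!all(genes %in% names(stats$mean)))
      stop("standardization stats do not cover genes: ",
           paste(utils::head(setdiff(genes, names(stats$mean)), 5), collapse = ", "))
    stats <- list(mean = stats$mean[genes], sd = stats$sd[genes])
  }
  sd_safe <- ifelse(stats$sd > 0, stats$sd, 1)
  z <- sweep(sweep(m$values, 2, stats$mean, "-"), 2, sd_safe, "/")
  z[, stats$sd == 0] <- 0
  z <- pmin(pmax(z, -clip), clip)
  list(matrix = expression_matrix(z, layer = "zscore"), stats = stats)
}
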