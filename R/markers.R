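# Wilcoxon rank-sum marker machinery shared by the one-vs-rest marker
# selector and compartment-wise differential expression. p-values come from
# stats::wilcox.test (exact for small untied samples, normal approximation
# with continuity correction otherwise); log-fold-change is the difference
# of mean log-normalized expression (natural-log units).

rank_sum_table <- function(vals, in_group) {
  x <- vals[in_group, , drop = FALSE]
  y <- vals[!in_group, , drop = FALSE]
  p <- vapply(seq_len(ncol(vals)), function(j) {
    xv <- x[, j]; yv <- y[, j]
    if (all(xv == xv[1]) && all(yv == yv[1]) && xv[1] == yv[1]) return(1)
    suppressWarnings(stats::wilcox.test(xv, yv)$p.value)
  }, numeric(1))
  data.frame(gene = colnames(vals),
             logfc = colMeans(x) - colMeans(y),
             p = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-vs-rest differential-expression marker selection
#'
#' For each compartment, every gene is tested by two-sided Wilcoxon rank-sum
#' against all other compartments pooled; Benjamini-Hochberg adjustment is
#' applied across genes within the compartment. Genes with adjusted
#' p <= \code{max_fdr} and log-fold-change >= \code{min_logfc} are kept; the
#' final set is the union across compartments (optionally truncated per
#' class by adjusted p then |logfc|).
#'
#' @param m \code{ExpressionMatrix} with \code{layer = "lognorm"}.
#' @param ann \code{CellAnnotation}; at least two compartments with >= 3
#'   cells each.
#' @param min_logfc minimum mean-lognorm difference (natural log), default 0.25.
#' @param max_fdr maximum BH-adjusted p, default 0.05.
#' @param top_per_class optional per-compartment cap.
#' @param name name for the resulting gene set.
#' @return list with \code{geneset} (\code{GeneSet}, provenance \code{fam})
#'   and \code{table} (per-compartment marker statistics).
#' @export
de_markers <- function(m, ann, min_logfc = 0.25, max_fdr = 0.05,
                       top_per_class = NULL, name = "markers") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("de_markers expects the lognorm layer")
  ann <- align_annotation(ann, m)
  y <- droplevels(ann$compartment)
  tab <- table(y)
  if (length(tab) < 2) stop("need at least two compartments")
  if (any(tab < 3))
    stop("compartment(s) with fewer than 3 cells: ",
         paste(names(tab)[tab < 3], collapse = ", "))
  all_rows <- list(); picked <- character(0)
  for (k in levels(y)) {
    res <- rank_sum_table(m$values, y == k)
    res$compartment <- k
    all_rows[[k]] <- res
    hit <- res[res$p_adj <= max_fdr & res$logfc >= min_logfc, , drop = FALSE]
    hit <- hit[order(hit$p_adj, -abs(hit$logfc), hit$gene), , drop = FALSE]
    if (!is.null(top_per_class) && nrow(hit) > top_per_class)
      hit <- hit[seq_len(top_per_class), , drop = FALSE]
    picked <- c(picked, hit$gene)
  }
  if (!length(picked)) stop("no marker genes pass the thresholds")
  list(geneset = gene_set(name, picked[!duplicated(picked)], provenance = "fam"),
       table = do.call(rbind, all_rows))
}

#' Compartment-wise differential expression (target vs rest)
#'
#' Wilcoxon rank-sum of the target compartment against all other cells per
#' gene, BH adjustment across genes, log-fold-change as difference of mean
#' log-normalized expression. Output is sorted by adjusted p, then |logfc|
#' descending, then symbol, so the table is deterministic.
#'
#' @param m \code{ExpressionMatrix} with \code{layer = "lognorm"}.
#' @param ann \code{CellAnnotation} (or any data.frame with the key column).
#' @param compartment_key column holding the compartment labels (default
#'   \code{"compartment"}; use \code{"predicted_compartment"} after
#'   \code{assign_positions}).
#' @param target the compartment treated as foreground.
#' @return data.frame (gene, logfc, p, p_adj).
#' @export
compartment_de <- function(m, ann, compartment_key = "compartment", target) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("compartment_de expects the lognorm layer")
  ann <- align_annotation(ann, m)
  labels <- as.character(ann[[compartment_key]])
  if (!target %in% labels) stop("target label absent: ", target)
  res <- rank_sum_table(m$values, labels == target)
  res[order(res$p_adj, -abs(res$logfc), res$gene), , drop = FALSE]
}
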