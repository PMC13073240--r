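#' Assign predicted compartments to an annotation
#'
#' Runs the classifier and appends a \code{predicted_compartment} column plus
#' one probability column per class (\code{prob_<class>}) to the annotation;
#' existing covariates (including a true \code{compartment}, when present)
#' are preserved, so truth and prediction can coexist for evaluation.
#'
#' @param model a \code{PositionModel}.
#' @param m an \code{ExpressionMatrix} (non-empty).
#' @param ann \code{CellAnnotation} for the cells of \code{m}.
#' @return the annotation with prediction columns added.
#' @export
assign_positions <- function(model, m, ann) {
  if (!nrow(m$values)) stop("empty expression matrix")
  ann <- align_annotation(ann, m)
  pred <- predict(model, m)
  ann$predicted_compartment <- unname(pred$labels)
  for (k in model$class_order)
    ann[[paste0("prob_", k)]] <- unname(pred$probabilities[, k])
  ann
}

#' Compartment-resolved cell-count summaries
#'
#' In \code{fraction} mode, each group's counts are divided by the group
#' total (fractions sum to 1 per group; compartments with no cells report
#' 0). In \code{relative_to_baseline} mode, each compartment's count is
#' divided by that compartment's count in the declared baseline group — the
#' normalized-cell-count kinetics readout.
#'
#' @param ann annotation holding the compartment labels.
#' @param group_by covariate name(s) defining groups (e.g. timepoint).
#' @param normalize \code{"fraction"} or \code{"relative_to_baseline"}.
#' @param baseline baseline group value (required in baseline mode).
#' @param compartment_key label column; defaults to
#'   \code{predicted_compartment} when present, else \code{compartment}.
#' @return data.frame (group columns, compartment, count, value).
#' @export
compartment_fractions <- function(ann, group_by,
                                  normalize = c("fraction", "relative_to_baseline"),
                                  baseline = NULL, compartment_key = NULL) {
  normalize <- match.arg(normalize)
  if (is.null(compartment_key))
    compartment_key <- if ("predicted_compartment" %in% names(ann))
      "predicted_compartment" else "compartment"
  if (!compartment_key %in% names(ann))
    stop("no compartment column found (looked for ", compartment_key, ")")
  comp <- as.character(ann[[compartment_key]])
  comps <- sort(unique(comp))
  grp <- interaction(lapply(group_by, function(g) ann[[g]]), drop = TRUE,
                     sep = "|")
  counts <- table(grp, factor(comp, levels = comps))
  df <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(df) <- c("group", "compartment", "count")
  if (normalize == "fraction") {
    tot <- stats::ave(df$count, df$group, FUN = sum)
    df$value <- ifelse(tot > 0, df$count / tot, 0)
  } else {
    if (is.null(baseline)) stop("baseline group must be declared")
    if (!baseline %in% rownames(counts))
      stop("baseline group absent: ", baseline)
    base <- counts[baseline, ]
    zero <- names(base)[base == 0]
    if (length(zero))
      stop("baseline has zero cells in compartment(s): ",
           paste(zero, collapse = ", "))
    df$value <- df$count / as.numeric(base[df$compartment])
  }
  df
}

#' Per-cell module score of a gene set
#'
#' The mean, over the set's genes present in the matrix, of each gene's
#' z-scored log-normalized expression (sample sd; constant genes contribute
#' 0). Genes absent from the matrix are ignored, so the score is invariant
#' to padding the set with unmeasured symbols.
#'
#' @param m \code{ExpressionMatrix} with \code{layer = "lognorm"}.
#' @param gs a \code{GeneSet} with at least one gene present in \code{m}.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(m, gs) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("module_score expects the lognorm layer")
  present <- intersect(gs$genes, gene_ids(m))
  if (!length(present))
    stop("no gene of '", gs$name, "' present in the matrix")
  message(sprintf("module_score '%s': %d/%d genes present", gs$name,
                  length(present), length(gs$genes)))
  v <- m$values[, present, drop = FALSE]
  mu <- colMeans(v); sdv <- apply(v, 2, stats::sd)
  z <- sweep(sweep(v, 2, mu, "-"), 2, ifelse(sdv > 0, sdv, 1), "/")
  z[, sdv == 0] <- 0
  stats::setNames(rowMeans(z), cell_ids(m))
}

#' Group-wise summary of per-cell scores
#'
#' @param scores named per-cell numeric vector (e.g. from
#'   \code{module_score}).
#' @param ann annotation whose rownames cover the scored cells.
#' @param keys covariate name(s) defining groups.
#' @return data.frame (group, n, mean_score, low_confidence flag for n < 10).
#' @export
score_summary <- function(scores, ann, keys) {
  ann <- ann[names(scores), , drop = FALSE]
  grp <- interaction(lapply(keys, function(g) ann[[g]]), drop = TRUE, sep = "|")
  agg <- tapply(scores, grp, mean)
  n <- as.integer(table(grp)[names(agg)])
  data.frame(group = names(agg), n = n, mean_score = as.numeric(agg),
             low_confidence = n < 10, stringsAsFactors = FALSE,
             row.names = NULL)
}
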